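#' Pipeline run configuration
#'
#' All tunables of an end-to-end run in one validated list: synthesis
#' (subjects, epochs, stage contrast, sampling rate, artifact rate),
#' preprocessing (filter spec, artifact threshold), derivations,
#' features, classifier (trees, mode), post-processing windows and the
#' actigraphy threshold. A serialized hash of the configuration is
#' stored with every output.
#'
#' @param n_subjects,n_epochs Cohort size.
#' @param contrast Stage-separability of the synthetic cohort.
#' @param fs Sampling rate for synthesis (Hz).
#' @param artifact_rate Injected artifacts per hour.
#' @param filter A [filter_spec()].
#' @param artifact_window_s,artifact_mult Artifact-mask parameters.
#' @param derivations Names of staging derivations.
#' @param ntree,mtry,mode Classifier settings ([train_stager()]).
#' @param onset_run,smooth_window Post-processing windows (epochs).
#' @param actigraphy_threshold Counts threshold for actigraphy scoring.
#' @param seed Root seed; every stage's randomness derives from it.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(n_subjects = 4, n_epochs = 120, contrast = 1,
                       fs = 128, artifact_rate = 0,
                       filter = filter_spec(bandpass_hi = 64,
                                            resample_to = 128),
                       artifact_window_s = 1, artifact_mult = 10,
                       derivations = c("FB(L)", "FB(R)", "L-R"),
                       ntree = 100, mtry = "all", mode = "ceegrid",
                       onset_run = 10, smooth_window = 5,
                       actigraphy_threshold = 20, seed = 1) {
  known <- names(ceegrid_derivations())
  bad <- setdiff(derivations, known)
  if (length(bad))
    stopf("unknown derivation name(s) in config: %s",
          paste(bad, collapse = ", "))
  if (!mode %in% c("ceegrid", "ceegrid+eog", "ceegrid-star", "psg"))
    stopf("unknown mode '%s'", mode)
  cfg <- list(n_subjects = n_subjects, n_epochs = n_epochs,
              contrast = contrast, fs = fs, artifact_rate = artifact_rate,
              filter = unclass(filter),
              artifact_window_s = artifact_window_s,
              artifact_mult = artifact_mult, derivations = derivations,
              ntree = ntree, mtry = mtry, mode = mode,
              onset_run = onset_run, smooth_window = smooth_window,
              actigraphy_threshold = actigraphy_threshold, seed = seed)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  # stable content hash without extra dependencies
  key <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(key)) *
                        (seq_len(nchar(key)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Extract staging features from one night
#'
#' The per-subject front half of the pipeline: derive the staging
#' channels, standardize them (band-pass + notch at the configured
#' rates), artifact-mask the derivation signals, and compute the epoch
#' feature matrix. Derivation before filtering is exact (both are
#' linear) and avoids filtering channels that are never used.
#'
#' @param night A `synthetic_night` (or a list with `recording` and
#'   optionally `true_hypnogram`).
#' @param cfg A [run_config()].
#' @return A `feature_matrix`.
#' @export
night_features <- function(night, cfg = run_config()) {
  rec <- night$recording
  derivs <- ceegrid_derivations()[cfg$derivations]
  sigs <- lapply(derivs, function(d) apply_derivation(rec, d))
  names(sigs) <- names(derivs)
  drec <- recording(do.call(rbind, sigs), rec$fs, names(sigs))
  drec <- standardize(drec, do.call(filter_spec, cfg$filter))
  msk <- artifact_mask(drec, cfg$artifact_window_s, cfg$artifact_mult)
  sigs <- stats::setNames(
    lapply(seq_along(derivs), function(i) drec$data[i, ]), names(derivs))
  feature_matrix(sigs, drec$fs, mask = msk, epoch_s = 30)
}

#' Run the full pipeline on a synthetic cohort
#'
#' synthesize -> preprocess -> derive -> featurize -> LOSO staging ->
#' post-process -> evaluate, with every stage output persisted under
#' `out_dir` (CSV/JSON) together with the configuration and its hash.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip persistence.
#' @param verbose Log per-stage progress.
#' @return A list of class `"pipeline_run"`: `config`, `features`,
#'   `truth`, `loso` (raw), `post` (post-processed hypnograms),
#'   `report` (EEG vs truth), `actigraphy_report`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("synthesizing %d subjects x %d epochs (contrast %.2f)",
      cfg$n_subjects, cfg$n_epochs, cfg$contrast)
  nights <- synth_cohort(cfg$n_subjects, cfg$n_epochs, seed = cfg$seed,
                         contrast = cfg$contrast, fs = cfg$fs,
                         artifact_rate = cfg$artifact_rate)
  truth <- lapply(nights, `[[`, "true_hypnogram")
  say("extracting features")
  feats <- lapply(seq_along(nights), function(i) {
    fm <- night_features(nights[[i]], cfg)
    say("  subject %d: %d epochs, %d forced-wake", i, nrow(fm$x),
        sum(fm$forced_wake))
    fm
  })
  say("LOSO staging (%d trees, mode %s)", cfg$ntree, cfg$mode)
  lr <- loso(feats, truth, ntree = cfg$ntree, mtry = cfg$mtry,
             seed = cfg$seed, mode = cfg$mode)
  say("post-processing and evaluating")
  post <- lapply(lr$scored, postprocess_hypnogram,
                 run_epochs = cfg$onset_run, window = cfg$smooth_window)
  report <- agreement_report(truth, post)
  act <- lapply(nights, function(n)
    score_actigraphy(n$activity_counts, cfg$actigraphy_threshold))
  act_report <- agreement_report(
    lapply(truth, function(h) {
      sw <- collapse_sleep_wake(h)
      hypnogram(sw$labels[seq_len(2 * floor(length(sw$labels) / 2))])
    }),
    lapply(act, function(h) hypnogram(h$labels)))
  run <- structure(list(config = cfg, hash = config_hash(cfg),
                        features = feats, truth = truth, loso = lr,
                        post = post, report = report,
                        actigraphy_report = act_report),
                   class = "pipeline_run")
  if (!is.null(out_dir)) persist_run(run, out_dir, verbose = verbose)
  run
}

persist_run <- function(run, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(c(unclass(run$config), hash = run$hash),
                   file.path(out_dir, "config.yaml"))
  for (i in seq_along(run$truth)) {
    write_hypnogram(run$truth[[i]],
                    file.path(out_dir, sprintf("subject%02d_truth.csv", i)))
    write_hypnogram(run$post[[i]],
                    file.path(out_dir, sprintf("subject%02d_scored.csv", i)))
    write_feature_matrix(run$features[[i]],
                         file.path(out_dir,
                                   sprintf("subject%02d_features.csv", i)))
  }
  utils::write.csv(run$loso$metrics,
                   file.path(out_dir, "loso_metrics.csv"),
                   row.names = FALSE)
  summary <- list(
    hash = run$hash,
    mean_kappa = mean(run$loso$metrics$kappa),
    mean_kappa_sw = mean(run$loso$metrics$kappa_sw),
    mean_accuracy = mean(run$loso$metrics$accuracy),
    occupancy_truth = as.list(run$report$occupancy_ref),
    occupancy_scored = as.list(run$report$occupancy_test))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (verbose) message("run written to ", out_dir)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d subjects, hash %s\n",
              x$config$n_subjects, x$hash))
  print(x$loso)
  invisible(x)
}
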