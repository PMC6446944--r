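# The benchmark cohort used by the acceptance suite: 10 subjects x 480
# epochs (4 h) of disrupted sleep at the default (high) stage contrast,
# pinned seed. Built lazily once per test run and shared between the
# staging and post-processing checks.

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (!is.null(.cohort_cache$run)) return(.cohort_cache$run)
  cfg <- run_config(n_subjects = 10, n_epochs = 480, contrast = 1,
                    ntree = 100, seed = 101)
  nights <- synth_cohort(cfg$n_subjects, cfg$n_epochs, seed = cfg$seed,
                         contrast = cfg$contrast, fs = cfg$fs)
  truth <- lapply(nights, `[[`, "true_hypnogram")
  feats <- lapply(nights, night_features, cfg = cfg)
  raw <- loso(feats, truth, ntree = cfg$ntree, seed = cfg$seed)
  post <- lapply(raw$scored, postprocess_hypnogram)
  .cohort_cache$run <- list(cfg = cfg, truth = truth, feats = feats,
                            raw = raw, post = post)
  .cohort_cache$run
}

# single-epoch non-wake islands: non-W epochs whose neighbours both
# carry a different label
count_islands <- function(labels) {
  n <- length(labels)
  if (n < 3) return(0L)
  mid <- 2:(n - 1)
  sum(labels[mid] != "W" &
        labels[mid] != labels[mid - 1] &
        labels[mid] != labels[mid + 1])
}
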