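#' Train the bagged-tree sleep stager
#'
#' Fits an ensemble of 100 decision trees by bagging: each tree is grown
#' on a bootstrap resample of the training set at its original size (with
#' replacement), splits optimize the Gini criterion, and trees grow until
#' every leaf is pure. By default all features are candidates at every
#' split (plain bagging); `mtry = "sqrt"` selects the common
#' random-subspace variant instead. Missing feature values are imputed
#' with the per-feature training median (forced-wake rows are excluded
#' from training).
#'
#' @param features A `feature_matrix`, or a plain numeric matrix of
#'   epoch features, or a list of either (one per subject).
#' @param labels A `hypnogram`, character vector, or list matching
#'   `features`.
#' @param ntree Number of trees (default 100).
#' @param mtry `"all"` (bagging, default) or `"sqrt"`.
#' @param seed Integer seed; same seed, same model.
#' @param mode Label describing the scoring mode (free text, e.g.
#'   "ceegrid", "ceegrid+eog", "ceegrid-star", "psg").
#' @return A `"staging_model"`: the forest, training medians, class list,
#'   mode and seed.
#' @export
train_stager <- function(features, labels, ntree = 100, mtry = "all",
                         seed = 1, mode = "ceegrid") {
  xs <- gather_features(features)
  ys <- gather_labels(labels)
  if (nrow(xs$x) != length(ys))
    stopf("features (%d rows) and labels (%d) disagree", nrow(xs$x),
          length(ys))
  keep <- !xs$forced_wake
  x <- xs$x[keep, , drop = FALSE]
  y <- ys[keep]
  present <- intersect(sleep_stages(), unique(y))
  if (length(present) < 2)
    stopf("training set must contain at least 2 classes (found %d)",
          length(present))
  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  medians[!is.finite(medians)] <- 0
  x <- impute_columns(x, medians)
  m <- if (identical(mtry, "all")) ncol(x) else
    max(1L, floor(sqrt(ncol(x))))
  yf <- factor(y, levels = present)
  forest <- with_seed(seed, randomForest::randomForest(
    x = x, y = yf, ntree = ntree, mtry = m, replace = TRUE,
    sampsize = nrow(x), nodesize = 1))
  structure(list(forest = forest, medians = medians, classes = present,
                 columns = colnames(x), ntree = ntree, mode = mode,
                 seed = seed),
            class = "staging_model")
}

#' @export
print.staging_model <- function(x, ...) {
  cat(sprintf("<staging_model> %d bagged trees, %d features, mode '%s'\n",
              x$ntree, length(x$columns), x$mode))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

impute_columns <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- medians[j]
  }
  x
}

gather_features <- function(features) {
  if (inherits(features, "feature_matrix"))
    return(list(x = features$x, forced_wake = features$forced_wake))
  if (is.matrix(features))
    return(list(x = features,
                forced_wake = rowSums(is.finite(features)) == 0))
  parts <- lapply(features, gather_features)
  list(x = do.call(rbind, lapply(parts, `[[`, "x")),
       forced_wake = unlist(lapply(parts, `[[`, "forced_wake")))
}

gather_labels <- function(labels) {
  if (inherits(labels, "hypnogram")) return(labels$labels)
  if (is.character(labels) || is.factor(labels))
    return(as.character(labels))
  unlist(lapply(labels, gather_labels))
}

#' Score a night with a trained stager
#'
#' Per-epoch class probabilities are the fraction of trees voting for
#' each stage; the label is the most probable stage (ties broken in the
#' fixed order W, N1, N2, N3, REM). Missing features are imputed with the
#' training medians. Epochs whose features are entirely missing (fully
#' rejected epochs) bypass the forest and are scored wake with a
#' degenerate probability row (W = 1).
#'
#' @param model A `staging_model`.
#' @param features A `feature_matrix` (or numeric matrix) for one night.
#' @return A `hypnogram` with probabilities and forced-wake flags (a
#'   "scored night").
#' @export
predict_stager <- function(model, features) {
  xs <- gather_features(features)
  if (!identical(colnames(xs$x), model$columns))
    stopf("feature columns do not match the trained model")
  n <- nrow(xs$x)
  probs <- matrix(0, n, 5, dimnames = list(NULL, sleep_stages()))
  run <- !xs$forced_wake
  if (any(run)) {
    x <- impute_columns(xs$x[run, , drop = FALSE], model$medians)
    p <- stats::predict(model$forest, x, type = "prob")
    probs[run, colnames(p)] <- p
  }
  probs[!run, "W"] <- 1
  labels <- sleep_stages()[max.col(probs, ties.method = "first")]
  labels[!run] <- "W"
  hypnogram(labels, probabilities = probs, forced_wake = xs$forced_wake)
}

#' Leave-one-subject-out validation
#'
#' For each subject, a stager is trained on all other subjects and
#' applied to the held-out one; per-subject accuracy and Cohen's kappa
#' (five-stage and collapsed sleep-wake) are reported against the
#' reference labels. In the "ceegrid-star" mode the caller simply passes
#' the alternative label source as `labels`; training and testing both
#' use it.
#'
#' @param features List of per-subject `feature_matrix` objects.
#' @param labels List of per-subject `hypnogram`s (or label vectors).
#' @param ntree,mtry,seed,mode Passed to [train_stager()].
#' @param postprocess If TRUE, apply the three hypnogram post-processing
#'   rules to each scored night before computing metrics.
#' @return A list of class `"loso_result"`: `scored` (per-subject scored
#'   hypnograms), `metrics` (data.frame with accuracy/kappa per subject),
#'   and the config used.
#' @export
loso <- function(features, labels, ntree = 100, mtry = "all", seed = 1,
                 mode = "ceegrid", postprocess = FALSE) {
  n_sub <- length(features)
  if (n_sub < 2) stopf("leave-one-subject-out needs >= 2 subjects")
  if (length(labels) != n_sub)
    stopf("need one label set per subject")
  seeds <- split_seed(seed, n_sub)
  scored <- vector("list", n_sub)
  rows <- list()
  for (i in seq_len(n_sub)) {
    ref <- gather_labels(labels[[i]])
    n_valid <- sum(!gather_features(features[[i]])$forced_wake)
    if (n_valid == 0) {
      warning(sprintf("subject %d has no valid epochs; skipped", i))
      next
    }
    model <- train_stager(features[-i], labels[-i], ntree = ntree,
                          mtry = mtry, seed = seeds[i], mode = mode)
    sc <- predict_stager(model, features[[i]])
    if (postprocess) sc <- postprocess_hypnogram(sc)
    scored[[i]] <- sc
    ka5 <- kappa_accuracy(hypnogram(ref), sc)
    ka2 <- kappa_accuracy(collapse_sleep_wake(hypnogram(ref)),
                          collapse_sleep_wake(sc))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = i, accuracy = ka5$accuracy, kappa = ka5$kappa,
      accuracy_sw = ka2$accuracy, kappa_sw = ka2$kappa)
  }
  structure(list(scored = scored, metrics = do.call(rbind, rows),
                 mode = mode, ntree = ntree, seed = seed),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<loso_result> %d subjects, mode '%s', %d trees\n",
              nrow(m), x$mode, x$ntree))
  cat(sprintf("  five-stage: mean accuracy %.3f, mean kappa %.3f\n",
              mean(m$accuracy), mean(m$kappa)))
  cat(sprintf("  sleep-wake: mean accuracy %.3f, mean kappa %.3f\n",
              mean(m$accuracy_sw), mean(m$kappa_sw)))
  invisible(x)
}
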