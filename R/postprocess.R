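#' Persistent-sleep onset
#'
#' Sleep onset must be followed by 5 min (10 epochs) of consecutive
#' sleep (latency to persistent sleep): the onset is the first epoch that
#' starts a run of at least `run_epochs` consecutive non-wake epochs.
#'
#' @param h A `hypnogram`.
#' @param run_epochs Required run length (default 10 epochs = 5 min).
#' @return 1-based epoch index, or `NA` if no qualifying run exists.
#' @export
find_onset <- function(h, run_epochs = 10) {
  runs <- true_runs(is_sleep(h$labels))
  ok <- runs$length >= run_epochs
  if (!any(ok)) return(NA_integer_)
  runs$start[which(ok)[1]]
}

#' Final wake-up epoch
#'
#' Wake-up must be preceded by 5 min of sleep: the returned index is the
#' end of the last run of at least `run_epochs` consecutive non-wake
#' epochs. Mirror image of [find_onset()]:
#' `find_wakeup(h) == n + 1 - find_onset(reverse(h))`.
#'
#' @inheritParams find_onset
#' @return 1-based epoch index of the last persistent-sleep epoch, or
#'   `NA`.
#' @export
find_wakeup <- function(h, run_epochs = 10) {
  runs <- true_runs(is_sleep(h$labels))
  ok <- runs$length >= run_epochs
  if (!any(ok)) return(NA_integer_)
  runs$end[utils::tail(which(ok), 1)]
}

#' Smooth a scored hypnogram's probabilities
#'
#' Between sleep onset and final wake-up, each class-probability series
#' is smoothed with a centred moving average of `window` epochs (the
#' window shrinks to the available neighbours at the run edges) and each
#' epoch is relabelled with its most probable class - except that epochs
#' already labelled wake stay wake, preserving brief mid-night arousals
#' (smoothing never removes wake; it may introduce it where the smoothed
#' wake probability dominates). Epochs before onset and after wake-up
#' are forced to wake.
#'
#' @param h A `hypnogram` carrying class probabilities.
#' @param bounds Optional list/vector with `onset` and `wakeup` epoch
#'   indices; computed with the default 10-epoch rule when missing.
#' @param window Moving-average length in epochs (odd; default 5).
#' @return A smoothed `hypnogram` (probabilities preserved as smoothed).
#' @export
smooth_hypnogram <- function(h, bounds = NULL, window = 5) {
  if (is.null(h$probabilities))
    stopf("smoothing requires class probabilities")
  if (window %% 2 != 1) stopf("window must be odd")
  if (is.null(bounds))
    bounds <- list(onset = find_onset(h), wakeup = find_wakeup(h))
  onset <- bounds$onset %||% bounds[["onset"]]
  wakeup <- bounds$wakeup %||% bounds[["wakeup"]]
  n <- length(h$labels)
  labels <- h$labels
  probs <- h$probabilities
  if (is.na(onset) || is.na(wakeup)) {
    # no persistent sleep: the whole night is scored wake
    return(hypnogram(rep("W", n), epoch_s = h$epoch_s,
                     probabilities = probs, forced_wake = h$forced_wake))
  }
  half <- (window - 1) / 2
  idx <- onset:wakeup
  sm <- probs
  for (e in idx) {
    a <- max(onset, e - half)
    b <- min(wakeup, e + half)
    sm[e, ] <- colMeans(probs[a:b, , drop = FALSE])
  }
  # label = most probable class after smoothing; epochs already scored
  # wake are retained regardless (brief mid-night arousals survive)
  new_lab <- labels
  cls <- colnames(probs)
  new_lab[idx] <- cls[max.col(sm[idx, , drop = FALSE], ties.method = "first")]
  new_lab[idx][labels[idx] == "W"] <- "W"
  if (onset > 1) new_lab[1:(onset - 1)] <- "W"
  if (wakeup < n) new_lab[(wakeup + 1):n] <- "W"
  hypnogram(new_lab, epoch_s = h$epoch_s, probabilities = sm,
            forced_wake = h$forced_wake)
}

#' Full hypnogram post-processing
#'
#' The three rules in order: persistent-sleep onset, final wake-up,
#' probability smoothing with wake retention. Hypnograms without
#' probabilities (e.g. actigraphy-based) receive only the first two
#' rules (epochs outside [onset, wakeup] forced to wake).
#'
#' @param h A `hypnogram` (with probabilities for the smoothing step).
#' @param run_epochs Persistent-sleep run length (default 10).
#' @param window Smoothing window in epochs (default 5).
#' @return A post-processed `hypnogram`.
#' @export
postprocess_hypnogram <- function(h, run_epochs = 10, window = 5) {
  onset <- find_onset(h, run_epochs)
  wakeup <- find_wakeup(h, run_epochs)
  if (!is.null(h$probabilities))
    return(smooth_hypnogram(h, list(onset = onset, wakeup = wakeup),
                            window))
  n <- length(h$labels)
  labels <- h$labels
  if (is.na(onset) || is.na(wakeup)) {
    labels[] <- "W"
  } else {
    if (onset > 1) labels[1:(onset - 1)] <- "W"
    if (wakeup < n) labels[(wakeup + 1):n] <- "W"
  }
  hypnogram(labels, epoch_s = h$epoch_s, forced_wake = h$forced_wake)
}
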