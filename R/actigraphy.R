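#' Smooth actigraphy counts
#'
#' Weighted smoothing of 60-s epoch activity counts: each epoch keeps its
#' own count plus 20% of its immediate neighbours and 4% of the
#' second-order neighbours (out-of-range neighbours contribute 0):
#' `s_t = a_t + 0.2 (a_{t-1} + a_{t+1}) + 0.04 (a_{t-2} + a_{t+2})`.
#'
#' @param counts Non-negative activity counts per 60-s epoch.
#' @return Smoothed numeric series, same length.
#' @examples
#' smooth_counts(c(0, 0, 10, 0, 0))
#' @export
smooth_counts <- function(counts) {
  if (length(counts) < 1) stopf("need at least one epoch")
  if (any(counts < 0)) stopf("activity counts must be non-negative")
  n <- length(counts)
  lag <- function(k) {
    out <- rep(0, n)
    if (abs(k) >= n) return(out)
    if (k > 0) out[(k + 1):n] <- counts[1:(n - k)]
    else out[1:(n + k)] <- counts[(1 - k):n]
    out
  }
  counts + 0.2 * (lag(1) + lag(-1)) + 0.04 * (lag(2) + lag(-2))
}

#' Threshold smoothed counts into sleep-wake
#'
#' Epochs strictly below the threshold are scored sleeping ("S"); at or
#' above it, wake ("W").
#'
#' @param smoothed Smoothed activity series (60-s epochs).
#' @param threshold Non-negative threshold (default 20 counts, the
#'   device convention's medium setting; the value is not asserted by any
#'   reference and is always explicit in reports).
#' @return A `hypnogram` over \{W, S\} at 60-s epochs.
#' @export
threshold_score <- function(smoothed, threshold = 20) {
  if (threshold < 0) stopf("threshold must be >= 0")
  hypnogram(ifelse(smoothed < threshold, "S", "W"), epoch_s = 60)
}

#' Split 60-s epochs into 30-s epochs
#'
#' Each 60-s label is duplicated into two 30-s epochs inheriting the
#' parent's score.
#'
#' @param h60 A `hypnogram` at 60-s epochs.
#' @return A `hypnogram` at 30-s epochs, twice the length.
#' @export
to_30s <- function(h60) {
  if (h60$epoch_s != 60) stopf("expected 60-s epochs")
  if (length(h60$labels) == 0) stopf("hypnogram must have at least one epoch")
  hypnogram(rep(h60$labels, each = 2), epoch_s = 30)
}

#' Actigraphy sleep-wake scoring pipeline
#'
#' Smooth, threshold, convert to 30-s epochs, then apply the first two
#' hypnogram post-processing rules (persistent-sleep onset and final
#' wake-up) for a fair comparison with EEG-based scorers.
#'
#' @param counts Activity counts per 60-s epoch.
#' @param threshold Scoring threshold (see [threshold_score()]).
#' @param postprocess Apply onset/wake-up rules (default TRUE).
#' @return A sleep-wake `hypnogram` at 30-s epochs.
#' @export
score_actigraphy <- function(counts, threshold = 20, postprocess = TRUE) {
  h <- to_30s(threshold_score(smooth_counts(counts), threshold))
  if (postprocess) h <- postprocess_hypnogram(h)
  h
}
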