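#' Multichannel EEG recording
#'
#' A light container for a multichannel signal: a channels x samples numeric
#' matrix in microvolts, a sampling rate, channel labels, and a start offset
#' relative to the session start. Samples that were padded to align
#' recordings (always at the head) are stored as `NA` and tracked per
#' channel; all downstream steps treat `NA` samples as missing data.
#'
#' @param data Numeric matrix, channels x samples (rows are channels).
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of channel names (defaults to rownames).
#' @param start_offset_s Start time of the first stored sample, in seconds
#'   relative to the session start.
#' @return An object of class `"recording"`.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 256), 2), fs = 128,
#'                  labels = c("L1", "L2"))
#' n_epochs(rec, epoch_s = 1)
#' @export
recording <- function(data, fs, labels = NULL, start_offset_s = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (!is.numeric(data)) stopf("recording data must be numeric")
  if (ncol(data) < 1L) stopf("recording must contain at least one sample")
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stopf("need one label per channel (%d labels, %d channels)",
          length(labels), nrow(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("fs must be a positive scalar (Hz)")
  # padding is only legal at the head: NA runs must be prefixes
  pad <- head_pad_lengths(data)
  bad <- vapply(seq_len(nrow(data)), function(i) {
    anyNA(data[i, (pad[i] + 1L):ncol(data)])
  }, logical(1))
  if (any(bad))
    stopf("NA samples are only allowed as head padding (channel %s)",
          labels[which(bad)[1]])
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 start_offset_s = start_offset_s),
            class = "recording")
}

head_pad_lengths <- function(data) {
  vapply(seq_len(nrow(data)), function(i) {
    x <- data[i, ]
    if (!is.na(x[1])) return(0L)
    r <- rle(is.na(x))
    r$lengths[1]
  }, integer(1))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs / 60))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n")
  npad <- sum(is.na(x$data))
  if (npad > 0) cat(sprintf("  %d padded (NA) samples\n", npad))
  invisible(x)
}

#' @rdname recording
#' @param rec A `recording`.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Number of whole epochs in a recording
#' @param rec A `recording`.
#' @param epoch_s Epoch length in seconds (default 30).
#' @return Integer count of complete epochs.
#' @export
n_epochs <- function(rec, epoch_s = 30) {
  as.integer(floor(duration_s(rec) / epoch_s))
}

# Extract channel rows by label, erroring on absentees.
channel_data <- function(rec, labels) {
  miss <- setdiff(labels, rec$labels)
  if (length(miss))
    stopf("channel(s) not in recording: %s", paste(miss, collapse = ", "))
  rec$data[labels, , drop = FALSE]
}

#' Shift a recording in time by padding its head with NA samples
#'
#' Used to construct alignment test cases and to apply an estimated lag.
#' @param rec A `recording`.
#' @param lag_s Non-negative delay in seconds.
#' @return A `recording` delayed by `lag_s` (same length, tail truncated).
#' @export
delay_recording <- function(rec, lag_s) {
  k <- round(lag_s * rec$fs)
  if (k == 0) return(rec)
  if (k < 0) stopf("lag_s must be non-negative")
  n <- ncol(rec$data)
  shifted <- cbind(matrix(NA_real_, nrow(rec$data), k),
                   rec$data[, seq_len(n - k), drop = FALSE])
  recording(shifted, rec$fs, rec$labels, rec$start_offset_s)
}
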