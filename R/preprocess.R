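#' Filtering and resampling specification
#'
#' Defaults follow standard sleep-EEG conditioning: resample to 256 Hz,
#' 0.5-100 Hz band-pass, 50-Hz notch. When the input sampling rate cannot
#' support the upper band edge, the effective edge becomes the input
#' Nyquist frequency (e.g. 64 Hz for a 128-Hz recording).
#'
#' @param bandpass_lo,bandpass_hi Pass-band edges in Hz.
#' @param notch Notch (mains) frequency in Hz; `NA` disables.
#' @param resample_to Target sampling rate in Hz.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(bandpass_lo = 0.5, bandpass_hi = 100, notch = 50,
                        resample_to = 256) {
  if (bandpass_lo <= 0 || bandpass_lo >= bandpass_hi)
    stopf("need 0 < bandpass_lo < bandpass_hi")
  if (bandpass_hi > resample_to / 2)
    stopf("bandpass_hi must be <= resample_to/2")
  structure(list(bandpass_lo = bandpass_lo, bandpass_hi = bandpass_hi,
                 notch = notch, resample_to = resample_to),
            class = "filter_spec")
}

# Second-order IIR notch (biquad), standard audio-EQ design.
design_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filter of one channel, NA head padding preserved.
filtfilt_na <- function(x, b, a) {
  valid <- !is.na(x)
  if (!any(valid)) return(x)
  x[valid] <- signal::filtfilt(signal::Arma(b = b, a = a), x[valid])
  x
}

resample_channel <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  r <- gcd_int(round(fs_out), round(fs_in))
  p <- round(fs_out) / r
  q <- round(fs_in) / r
  valid <- !is.na(x)
  pad <- sum(!valid & cumsum(valid) == 0)
  y <- signal::resample(x[valid], p, q)
  n_pad_out <- round(pad * fs_out / fs_in)
  c(rep(NA_real_, n_pad_out), y)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Standardize a recording
#'
#' Anti-aliased resampling to the target rate, zero-phase 4th-order
#' Butterworth band-pass, and a zero-phase notch filter. If the original
#' sampling rate's Nyquist frequency is below the requested upper band
#' edge, the effective upper edge is the original Nyquist (the information
#' above it never existed). Head padding (NA) survives untouched; the
#' valid segment is filtered on its own.
#'
#' @param rec A `recording`.
#' @param spec A [filter_spec()].
#' @param notch_q Notch quality factor (default 30).
#' @return A standardized `recording` at `spec$resample_to` Hz, with
#'   attributes `effective_band` (the applied pass band).
#' @examples
#' rec <- recording(matrix(rnorm(512), 1), fs = 128)
#' out <- standardize(rec, filter_spec())
#' attr(out, "effective_band")
#' @export
standardize <- function(rec, spec = filter_spec(), notch_q = 30) {
  if (ncol(rec$data) < 8) stopf("recording too short to standardize")
  if (rec$fs < 2 * spec$bandpass_lo)
    stopf("sampling rate too low for the requested high-pass edge")
  hi <- min(spec$bandpass_hi, rec$fs / 2)
  fs_out <- spec$resample_to
  ys <- lapply(seq_len(nrow(rec$data)), function(i)
    resample_channel(rec$data[i, ], rec$fs, fs_out))
  n_out <- min(lengths(ys))
  data <- do.call(rbind, lapply(ys, function(y) y[seq_len(n_out)]))
  # clamp edge just under Nyquist so the band-pass design is valid
  hi_design <- min(hi, 0.999 * fs_out / 2)
  bp <- signal::butter(2, c(spec$bandpass_lo, hi_design) / (fs_out / 2),
                       type = "pass")
  nt <- if (!is.null(spec$notch) && !is.na(spec$notch) &&
            spec$notch < fs_out / 2)
    design_notch(spec$notch, fs_out, notch_q) else NULL
  for (i in seq_len(nrow(data))) {
    data[i, ] <- filtfilt_na(data[i, ], bp$b, bp$a)
    if (!is.null(nt)) data[i, ] <- filtfilt_na(data[i, ], nt$b, nt$a)
  }
  out <- recording(data, fs_out, rec$labels, rec$start_offset_s)
  attr(out, "effective_band") <- c(lo = spec$bandpass_lo, hi = hi)
  attr(out, "standardized") <- TRUE
  out
}

# 1-s-window log-power envelope averaged over channels (NA-safe).
log_power_envelope <- function(rec, window_s = 1) {
  n <- ncol(rec$data)
  w <- round(window_s * rec$fs)
  n_win <- floor(n / w)
  idx <- rep(seq_len(n_win), each = w)
  pow <- vapply(seq_len(n_win), function(k) {
    seg <- rec$data[, ((k - 1) * w + 1):(k * w), drop = FALSE]
    mean(seg^2, na.rm = TRUE)
  }, numeric(1))
  log(pow + 1e-12)
}

#' Estimate the time lag between two recordings
#'
#' Cross-correlates the 1-s-window log-power envelopes (mean over
#' channels) of two standardized recordings. Movement artifacts and slow
#' wave activity dominate these envelopes, so the correlation peak marks
#' the true offset. A positive lag means `b` starts `lag_s` seconds after
#' `a` (i.e. `b` is `a` delayed).
#'
#' @param a,b Standardized `recording`s with >= 10 min overlap.
#' @param max_lag_s Search range in seconds (default 120).
#' @param min_corr Minimum acceptable peak correlation (default 0.2);
#'   below it an alignment-failure error is raised.
#' @return Scalar lag in seconds (at 1-s resolution), with attribute
#'   `"correlation"`.
#' @export
align_recordings <- function(a, b, max_lag_s = 120, min_corr = 0.2) {
  ea <- log_power_envelope(a)
  eb <- log_power_envelope(b)
  if (min(length(ea), length(eb)) < 600)
    stopf("alignment needs at least 10 min of overlapping data")
  lags <- -round(max_lag_s):round(max_lag_s)
  cors <- vapply(lags, function(L) {
    # positive L: b delayed by L, so b[t] lines up with a[t - L]
    if (L >= 0) {
      n <- min(length(ea) - L, length(eb) - L)
      if (n < 30) return(NA_real_)
      suppressWarnings(stats::cor(ea[1:n], eb[(L + 1):(L + n)],
                                  use = "complete.obs"))
    } else {
      n <- min(length(eb), length(ea) + L)
      if (n < 30) return(NA_real_)
      suppressWarnings(stats::cor(ea[(-L + 1):(-L + n)], eb[1:n],
                                  use = "complete.obs"))
    }
  }, numeric(1))
  if (all(is.na(cors))) stopf("alignment failed: no valid overlap")
  best <- which.max(cors)
  if (cors[best] < min_corr)
    stopf("alignment failed: peak envelope correlation %.3f < %.3f",
          cors[best], min_corr)
  structure(lags[best], correlation = cors[best])
}

#' Artifact mask from short-window power thresholding
#'
#' Splits each channel (or derivation signal) into `window_s`-long
#' windows and rejects a window when its mean power exceeds
#' `threshold_mult` times that channel's median window power over the
#' whole recording. Windows containing padded/missing samples are always
#' rejected. All-constant channels produce no rejections.
#'
#' @param rec A `recording` (each row treated as one derivation).
#' @param window_s Window length in seconds, in (0, 30]; must divide 30.
#' @param threshold_mult Power multiple above the median that triggers
#'   rejection (> 1; default 10).
#' @return An `"artifact_mask"`: logical windows x channels matrix (TRUE =
#'   rejected) with attributes `window_s` and `fs`.
#' @export
artifact_mask <- function(rec, window_s = 1, threshold_mult = 10) {
  if (window_s <= 0 || window_s > 30 || (30 / window_s) %% 1 != 0)
    stopf("window_s must divide 30 s")
  if (threshold_mult <= 1) stopf("threshold_mult must be > 1")
  w <- round(window_s * rec$fs)
  n_win <- floor(ncol(rec$data) / w)
  mask <- matrix(FALSE, n_win, nrow(rec$data),
                 dimnames = list(NULL, rec$labels))
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, seq_len(n_win * w)]
    m <- matrix(x, nrow = w)
    pow <- colMeans(m^2)
    has_na <- colSums(is.na(m)) > 0
    med <- stats::median(pow, na.rm = TRUE)
    rej <- if (is.na(med) || med == 0) rep(FALSE, n_win) else
      !is.na(pow) & pow > threshold_mult * med
    mask[, i] <- rej | has_na
  }
  structure(mask, window_s = window_s, fs = rec$fs, class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d windows x %d channel(s), window = %gs\n",
              nrow(x), ncol(x), attr(x, "window_s")))
  cat(sprintf("  rejected: %.2f%%\n", 100 * mean(x)))
  invisible(x)
}

# Expand a window-resolution mask column to sample resolution.
mask_to_samples <- function(mask, col, n_samples) {
  w <- round(attr(mask, "window_s") * attr(mask, "fs"))
  out <- rep(FALSE, n_samples)
  m <- rep(mask[, col], each = w)
  out[seq_len(min(length(m), n_samples))] <- m[seq_len(min(length(m), n_samples))]
  out
}

#' Maximal run of 30-s epochs covered by both recordings
#'
#' Returns the longest run of whole epochs in which every sample of both
#' (time-aligned) recordings is present (non-padded). Epochs before a late
#' start or after an early truncation are dropped.
#'
#' @param a,b Aligned `recording`s on a common timeline (same fs).
#' @param epoch_s Epoch length in seconds (default 30).
#' @return Integer vector `c(first, last)` of 1-based epoch indices, with
#'   attribute `"n_epochs"`.
#' @export
intersect_epochs <- function(a, b, epoch_s = 30) {
  if (a$fs != b$fs) stopf("recordings must share a sampling rate")
  n <- min(ncol(a$data), ncol(b$data))
  valid <- colSums(is.na(a$data[, seq_len(n), drop = FALSE])) == 0 &
    colSums(is.na(b$data[, seq_len(n), drop = FALSE])) == 0
  w <- round(epoch_s * a$fs)
  n_ep <- floor(n / w)
  if (n_ep < 1) stopf("no overlapping epochs between recordings")
  ep_ok <- vapply(seq_len(n_ep), function(e)
    all(valid[((e - 1) * w + 1):(e * w)]), logical(1))
  if (!any(ep_ok)) stopf("no overlapping epochs between recordings")
  runs <- true_runs(ep_ok)
  best <- runs[which.max(runs$length), ]
  structure(c(first = best$start, last = best$end), n_epochs = best$length)
}
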