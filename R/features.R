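#' Feature-extraction options
#'
#' Every interpretation knob of the 33-feature set in one place, with the
#' package defaults: EOG proxy band 0.5-30 Hz, EMG proxy band 32-80 Hz,
#' slow/rapid eye-movement sub-bands 0.5-2 / 2-6 Hz, Welch sub-window 2 s
#' with 50% overlap, spectral features restricted to 1-32 Hz, spectral
#' edge percentile 95, spindle CWT 11-16 Hz in 0.5-Hz steps with a
#' 7-cycle Morlet, spindle envelope threshold 3 x epoch median, spindle
#' duration bounds 0.5-3 s.
#'
#' @param ... Overrides for any default listed above.
#' @return A list of class `"feature_opts"`.
#' @export
feature_opts <- function(...) {
  opts <- list(
    eog_band = c(0.5, 30), emg_band = c(32, 80),
    sem_band = c(0.5, 2), rem_band = c(2, 6),
    welch_s = 2, welch_overlap = 0.5,
    total_band = c(1, 32), sef_pct = 0.95,
    spindle_freqs = seq(11, 16, by = 0.5), spindle_cycles = 7,
    spindle_k = 3, spindle_dur = c(0.5, 3),
    emg_window_s = 1)
  dots <- list(...)
  opts[names(dots)] <- dots
  structure(opts, class = "feature_opts")
}

feature_labels <- function() paste0("F", 1:33)

# memoised IIR designs (filter design is deterministic in its key)
.filter_cache <- new.env(parent = emptyenv())

# ---- spectral helpers -------------------------------------------------

# Welch PSD: averaged modified periodograms, Hann window, 50% overlap.
# Returns density on the one-sided frequency grid.
welch_psd <- function(x, fs, win_s = 2, overlap = 0.5) {
  n <- length(x)
  w <- min(round(win_s * fs), n)
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, n - w + 1L, by = step)
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + w - 1L)]
    (seg - mean(seg)) * han
  }, numeric(w))
  spec <- Mod(stats::mvfft(segs))^2
  psd <- rowMeans(spec) / (fs * sum(han^2))
  nf <- floor(w / 2) + 1L
  list(freq = (seq_len(nf) - 1) * fs / w, psd = psd[seq_len(nf)])
}

# Periodograms of consecutive non-overlapping windows (one batched FFT).
# Returns list(freq, psd = freqs x windows matrix).
subwindow_periodograms <- function(x, fs, w) {
  n_win <- floor(length(x) / w)
  m <- matrix(x[seq_len(n_win * w)], nrow = w)
  m <- sweep(m, 2, colMeans(m))
  spec <- Mod(stats::mvfft(m))^2 / (fs * w)
  nf <- floor(w / 2) + 1L
  list(freq = (seq_len(nf) - 1) * fs / w,
       psd = spec[seq_len(nf), , drop = FALSE])
}

raw_periodogram <- function(x, fs) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2 / (fs * n)
  nf <- floor(n / 2) + 1L
  list(freq = (seq_len(nf) - 1) * fs / n, psd = spec[seq_len(nf)])
}

band_power_from_psd <- function(p, band) {
  sel <- p$freq >= band[1] & p$freq < band[2]
  sum(p$psd[sel])
}

# Hilbert envelope via FFT (analytic signal magnitude).
hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Complex Morlet CWT magnitudes at the given centre frequencies.
# Returns samples x frequencies matrix.
morlet_cwt_mag <- function(x, fs, freqs, n_cycles = 7) {
  n <- length(x)
  X <- stats::fft(x)
  f_axis <- (seq_len(n) - 1) * fs / n
  pos <- f_axis <= fs / 2
  out <- matrix(0, n, length(freqs))
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f0)
    win <- numeric(n)
    win[pos] <- exp(-2 * pi^2 * sigma_t^2 * (f_axis[pos] - f0)^2)
    out[, k] <- Mod(stats::fft(X * win, inverse = TRUE) / n)
  }
  out
}

# ---- operator groups --------------------------------------------------

#' EOG and EMG proxy signals
#'
#' Zero-phase band-pass filtered copies of an (ear-EEG) epoch standing in
#' for dedicated electro-oculogram and electromyogram channels. When the
#' sampling rate cannot represent the EMG band's upper edge, the edge is
#' clipped to the Nyquist frequency and flagged.
#'
#' @param x Epoch signal (finite values).
#' @param fs Sampling rate (Hz).
#' @param opts A [feature_opts()].
#' @return List with `eog`, `emg` signals and `emg_clipped` flag.
#' @export
band_proxies <- function(x, fs, opts = feature_opts()) {
  bp <- function(band) {
    hi <- min(band[2], 0.99 * fs / 2)
    key <- sprintf("bp_%g_%g_%g", band[1], hi, fs)
    flt <- .filter_cache[[key]]
    if (is.null(flt)) {
      flt <- signal::butter(2, c(band[1], hi) / (fs / 2), type = "pass")
      .filter_cache[[key]] <- flt
    }
    signal::filtfilt(flt, x)
  }
  clipped <- opts$emg_band[2] > fs / 2
  list(eog = bp(opts$eog_band), emg = bp(opts$emg_band),
       emg_clipped = clipped)
}

#' Time-domain features F1-F7
#'
#' F1 skewness, F2 excess kurtosis, F3 zero-crossing rate (per second),
#' F4 Hjorth mobility, F5 Hjorth complexity, F6 75th percentile of the
#' absolute signal, F7 Pearson correlation with the partner derivation's
#' epoch signal. Constant signals leave F1/F2/F4/F5 undefined (`NA`).
#'
#' @param x Epoch signal.
#' @param fs Sampling rate (Hz).
#' @param partner Partner epoch signal for F7 (or `NULL` -> `NA`).
#' @return Named numeric vector F1..F7.
#' @export
time_domain <- function(x, fs, partner = NULL) {
  n <- length(x)
  out <- stats::setNames(rep(NA_real_, 7), paste0("F", 1:7))
  if (n < 2 * fs) return(out)
  s <- stats::sd(x)
  if (s > 0) {
    z <- (x - mean(x)) / s
    out["F1"] <- mean(z^3)
    out["F2"] <- mean(z^4) - 3
  }
  sgn <- sign(x)
  sgn <- sgn[sgn != 0]
  out["F3"] <- sum(diff(sgn) != 0) / (n / fs)
  v0 <- stats::var(x)
  if (v0 > 0) {
    d1 <- diff(x); d2 <- diff(d1)
    mob <- sqrt(stats::var(d1) / v0)
    out["F4"] <- mob
    if (stats::var(d1) > 0)
      out["F5"] <- sqrt(stats::var(d2) / stats::var(d1)) / mob
  }
  out["F6"] <- stats::quantile(abs(x), 0.75, names = FALSE)
  if (!is.null(partner)) {
    m <- min(n, length(partner))
    if (m >= 2 && stats::sd(x[1:m]) > 0 && stats::sd(partner[1:m]) > 0)
      out["F7"] <- stats::cor(x[1:m], partner[1:m])
  }
  out
}

#' EMG-proxy features F8-F10
#'
#' F8 mean power of the EMG proxy, F9 minimum 1-s sub-window power, F10
#' relative burst amplitude: 95th percentile of the Hilbert envelope over
#' its median (undefined for a silent proxy).
#'
#' @param emg EMG-proxy epoch signal.
#' @param fs Sampling rate (Hz).
#' @param opts A [feature_opts()].
#' @return Named numeric vector F8..F10.
#' @export
emg_features <- function(emg, fs, opts = feature_opts()) {
  out <- stats::setNames(rep(NA_real_, 3), paste0("F", 8:10))
  out["F8"] <- mean(emg^2)
  w <- round(opts$emg_window_s * fs)
  n_win <- floor(length(emg) / w)
  if (n_win >= 1) {
    m <- matrix(emg[seq_len(n_win * w)], nrow = w)
    out["F9"] <- min(colMeans(m^2))
  }
  env <- hilbert_env(emg)
  med <- stats::median(env)
  if (med > 0)
    out["F10"] <- stats::quantile(env, 0.95, names = FALSE) / med
  out
}

#' EOG-proxy features F11-F12
#'
#' Integrated power of the EOG proxy in the slow (0.5-2 Hz) and rapid
#' (2-6 Hz) eye-movement sub-bands.
#'
#' @param eog EOG-proxy epoch signal.
#' @param fs Sampling rate (Hz).
#' @param opts A [feature_opts()].
#' @return Named numeric vector F11..F12.
#' @export
eog_features <- function(eog, fs, opts = feature_opts()) {
  p <- raw_periodogram(eog, fs)
  c(F11 = band_power_from_psd(p, opts$sem_band),
    F12 = band_power_from_psd(p, opts$rem_band))
}

#' Spectral features F13-F28
#'
#' From a Welch PSD (2-s Hann windows, 50% overlap): relative band powers
#' in alpha/beta/theta/delta (F13-F16, normalized by total 1-32 Hz
#' power), the six band-power ratios a/d, d/b, d/t, t/a, t/b, a/b
#' (F17-F22), the slow/fast ratio (t+d)/(a+b) (F23), 95% spectral edge
#' frequency (F24), median power frequency (F25), mean absolute spectral
#' edge difference between consecutive 2-s sub-windows (F26), peak power
#' frequency (F27) and normalized spectral entropy (F28). All within the
#' 1-32 Hz analysis band; zero total power leaves everything `NA`.
#'
#' @param x Epoch signal.
#' @param fs Sampling rate (Hz).
#' @param bands A [band_spec()].
#' @param opts A [feature_opts()].
#' @return Named numeric vector F13..F28.
#' @export
spectral_features <- function(x, fs, bands = band_spec(),
                              opts = feature_opts()) {
  out <- stats::setNames(rep(NA_real_, 16), paste0("F", 13:28))
  if (length(x) < 4 * fs) return(out)
  p <- welch_psd(x, fs, opts$welch_s, opts$welch_overlap)
  tot_sel <- p$freq >= opts$total_band[1] & p$freq < opts$total_band[2]
  tot <- sum(p$psd[tot_sel])
  if (!is.finite(tot) || tot <= 0) return(out)
  bp <- vapply(bands, function(b) band_power_from_psd(p, b), numeric(1))
  a <- bp[["alpha"]]; b <- bp[["beta"]]; th <- bp[["theta"]]; d <- bp[["delta"]]
  out[c("F13", "F14", "F15", "F16")] <- c(a, b, th, d) / tot
  rat <- function(u, v) if (v > 0) u / v else NA_real_
  out["F17"] <- rat(a, d);  out["F18"] <- rat(d, b)
  out["F19"] <- rat(d, th); out["F20"] <- rat(th, a)
  out["F21"] <- rat(th, b); out["F22"] <- rat(a, b)
  out["F23"] <- rat(th + d, a + b)
  fr <- p$freq[tot_sel]; ps <- p$psd[tot_sel]
  cum <- cumsum(ps) / sum(ps)
  out["F24"] <- fr[which(cum >= opts$sef_pct)[1]]
  out["F25"] <- fr[which(cum >= 0.5)[1]]
  out["F27"] <- fr[which.max(ps)]
  pr <- ps / sum(ps)
  pr <- pr[pr > 0]
  out["F28"] <- -sum(pr * log(pr)) / log(sum(tot_sel))
  # F26: SEF95 variability across consecutive non-overlapping sub-windows
  w <- round(opts$welch_s * fs)
  if (floor(length(x) / w) >= 2) {
    pp <- subwindow_periodograms(x, fs, w)
    sel <- pp$freq >= opts$total_band[1] & pp$freq < opts$total_band[2]
    sefs <- apply(pp$psd[sel, , drop = FALSE], 2, function(ps) {
      tot <- sum(ps)
      if (tot <= 0) return(NA_real_)
      pp$freq[sel][which(cumsum(ps) / tot >= opts$sef_pct)[1]]
    })
    out["F26"] <- mean(abs(diff(sefs)), na.rm = TRUE)
  }
  out
}

#' Sleep-spindle proxy features F29-F33
#'
#' Based on a complex Morlet CWT at 11-16 Hz (0.5-Hz steps): the sigma
#' envelope is the maximum CWT magnitude across centre frequencies per
#' sample. F29 fraction of samples above 3 x the epoch-median envelope,
#' F30 frequency stationarity (1 - normalized variance of 2-s sub-window
#' peak frequencies), F31 minimum Pearson correlation between adjacent
#' 2-s sub-window periodograms, F32 largest CWT envelope value, F33
#' duration (s) of the longest supra-threshold run lasting between 0.5
#' and 3 s (0 if none).
#'
#' @param x Epoch signal.
#' @param fs Sampling rate (Hz).
#' @param opts A [feature_opts()].
#' @return Named numeric vector F29..F33.
#' @export
spindle_features <- function(x, fs, opts = feature_opts()) {
  out <- stats::setNames(rep(NA_real_, 5), paste0("F", 29:33))
  if (length(x) < 4 * fs) return(out)
  mag <- morlet_cwt_mag(x, fs, opts$spindle_freqs, opts$spindle_cycles)
  env <- do.call(pmax, as.data.frame(mag))
  out["F32"] <- max(env)
  med <- stats::median(env)
  if (med == 0) {
    out[c("F29", "F33")] <- 0
    # flat zero signal: stationarity/similarity undefined
    return(out)
  }
  above <- env > opts$spindle_k * med
  out["F29"] <- mean(above)
  runs <- true_runs(above)
  if (nrow(runs)) {
    dur <- runs$length / fs
    ok <- dur >= opts$spindle_dur[1] & dur <= opts$spindle_dur[2]
    out["F33"] <- if (any(ok)) max(dur[ok]) else 0
  } else out["F33"] <- 0
  # per-sub-window CWT peak frequency -> stationarity
  w <- round(opts$welch_s * fs)
  n_win <- floor(length(x) / w)
  if (n_win >= 2) {
    pf <- vapply(seq_len(n_win), function(k) {
      sub <- mag[((k - 1) * w + 1):(k * w), , drop = FALSE]
      opts$spindle_freqs[which.max(colMeans(sub))]
    }, numeric(1))
    span <- diff(range(opts$spindle_freqs))
    out["F30"] <- max(0, min(1, 1 - stats::var(pf) / (span / 2)^2))
    pp <- subwindow_periodograms(x, fs, w)$psd
    sims <- vapply(seq_len(ncol(pp) - 1), function(k) {
      if (stats::sd(pp[, k]) == 0 || stats::sd(pp[, k + 1]) == 0)
        return(NA_real_)
      stats::cor(pp[, k], pp[, k + 1])
    }, numeric(1))
    if (!all(is.na(sims))) out["F31"] <- min(sims, na.rm = TRUE)
  }
  out
}

#' All 33 features for one epoch of one derivation
#'
#' @param x Epoch signal (finite values; pass only the valid part).
#' @param fs Sampling rate (Hz).
#' @param partner Partner epoch signal for F7.
#' @param bands A [band_spec()].
#' @param opts A [feature_opts()].
#' @return Named numeric vector F1..F33.
#' @export
epoch_features <- function(x, fs, partner = NULL, bands = band_spec(),
                           opts = feature_opts()) {
  out <- stats::setNames(rep(NA_real_, 33), feature_labels())
  if (length(x) < 2 * fs || !all(is.finite(x))) return(out)
  out[1:7] <- time_domain(x, fs, partner)
  pr <- band_proxies(x, fs, opts)
  out[8:10] <- emg_features(pr$emg, fs, opts)
  out[11:12] <- eog_features(pr$eog, fs, opts)
  out[13:28] <- spectral_features(x, fs, bands, opts)
  out[29:33] <- spindle_features(x, fs, opts)
  out
}

default_partner_map <- function(deriv_names) {
  std <- c("FB(L)" = "FB(R)", "FB(R)" = "FB(L)", "L-R" = "FB(L)",
           "EOG" = "L-R")
  out <- character(0)
  for (nm in deriv_names) {
    if (nm %in% names(std) && std[[nm]] %in% deriv_names) {
      out[nm] <- std[[nm]]
    } else {
      others <- setdiff(deriv_names, nm)
      out[nm] <- if (length(others)) others[1] else NA_character_
    }
  }
  out
}

#' Epoch-by-feature matrix for a set of derivation signals
#'
#' Computes the 33 features per derivation per 30-s epoch, honouring the
#' artifact mask: features use only the valid part of an epoch; an epoch
#' fully rejected in every derivation gets an all-`NA` row and a
#' forced-wake flag (it will be scored as wake downstream).
#'
#' @param signals Named list of derivation signals (equal length), e.g.
#'   the output of [apply_derivation()] for FB(L), FB(R), L-R.
#' @param fs Sampling rate (Hz).
#' @param mask Optional `artifact_mask` with one column per derivation
#'   name (computed on the derivation signals).
#' @param partner_map Named character vector: F7 partner per derivation.
#'   Defaults pair FB(L) with FB(R), L-R with FB(L), EOG with L-R.
#' @param epoch_s Epoch length in seconds (default 30).
#' @param bands A [band_spec()].
#' @param opts A [feature_opts()].
#' @return A `"feature_matrix"`: list with `x` (epochs x n_deriv*33,
#'   columns `<derivation>/<F-label>`), `fraction_used` (epochs x
#'   derivations), `forced_wake` (logical per epoch), `fs`, `epoch_s`.
#' @export
feature_matrix <- function(signals, fs, mask = NULL,
                           partner_map = default_partner_map(names(signals)),
                           epoch_s = 30, bands = band_spec(),
                           opts = feature_opts()) {
  dn <- names(signals)
  if (is.null(dn) || any(dn == ""))
    stopf("signals must be a named list of derivation signals")
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1) stopf("derivation signals must share a length")
  w <- round(epoch_s * fs)
  n_ep <- floor(n / w)
  if (n_ep < 1) stopf("no whole epochs in the signals")
  # sample-resolution validity per derivation
  valid <- vapply(dn, function(nm) {
    v <- !is.na(signals[[nm]])
    if (!is.null(mask)) {
      if (round(attr(mask, "window_s") * attr(mask, "fs")) *
          nrow(mask) < n_ep * w)
        stopf("artifact mask is shorter than the recording")
      if (nm %in% colnames(mask))
        v <- v & !mask_to_samples(mask, nm, n)
    }
    v
  }, logical(n))
  xmat <- matrix(NA_real_, n_ep, length(dn) * 33,
                 dimnames = list(NULL, paste(rep(dn, each = 33),
                                             feature_labels(), sep = "/")))
  frac <- matrix(0, n_ep, length(dn), dimnames = list(NULL, dn))
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1) * w + 1):(e * w)
    for (j in seq_along(dn)) {
      nm <- dn[j]
      ok <- valid[idx, nm]
      frac[e, j] <- mean(ok)
      if (!any(ok)) next
      xs <- signals[[nm]][idx][ok]
      partner <- NULL
      pn <- partner_map[[nm]]
      if (!is.na(pn) && pn %in% dn) {
        ok2 <- ok & valid[idx, pn]
        if (sum(ok2) >= 2) {
          # correlate on the samples valid in both derivations
          xs7 <- signals[[nm]][idx][ok2]
          partner <- signals[[pn]][idx][ok2]
        }
      }
      f <- epoch_features(xs, fs, partner = NULL, bands = bands, opts = opts)
      if (!is.null(partner) && stats::sd(xs7) > 0 && stats::sd(partner) > 0)
        f["F7"] <- stats::cor(xs7, partner)
      xmat[e, ((j - 1) * 33 + 1):(j * 33)] <- f
    }
  }
  structure(list(x = xmat, fraction_used = frac,
                 forced_wake = rowSums(frac) == 0,
                 fs = fs, epoch_s = epoch_s, derivations = dn),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d derivations x 33)\n",
              nrow(x$x), ncol(x$x), length(x$derivations)))
  cat(sprintf("  forced-wake epochs: %d\n", sum(x$forced_wake)))
  invisible(x)
}

#' Write a feature matrix as CSV
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(epoch_index = seq_len(nrow(fm$x)), fm$x,
                   check.names = FALSE)
  df$forced_wake <- fm$forced_wake
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
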