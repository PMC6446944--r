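#' Default stage-transition matrix for disrupted sleep
#'
#' First-order Markov transition probabilities between the five stages,
#' tuned to emulate an extended nocturnal sleep opportunity: long sleep
#' latencies, frequent nocturnal wake, low sleep efficiency (roughly 40%
#' wake occupancy at stationarity), N2 as the dominant sleep stage, and
#' consolidated N3/REM bouts.
#'
#' @return 5x5 row-stochastic matrix with dimnames over the stage set.
#' @export
default_transition_matrix <- function() {
  s <- sleep_stages()
  m <- matrix(0, 5, 5, dimnames = list(s, s))
  m["W", ]   <- c(0.88, 0.08, 0.04, 0,    0)
  m["N1", ]  <- c(0.16, 0.50, 0.30, 0,    0.04)
  m["N2", ]  <- c(0.07, 0.03, 0.79, 0.07, 0.04)
  m["N3", ]  <- c(0.03, 0,    0.12, 0.85, 0)
  m["REM", ] <- c(0.09, 0.03, 0.07, 0,    0.81)
  m
}

#' Sample a hypnogram from a stage-transition model
#'
#' Draws a first-order Markov chain over the five sleep stages. With the
#' default matrix the night starts awake and shows the disrupted structure
#' of an ad-libitum 12-h sleep opportunity.
#'
#' @param n_epochs Number of 30-s epochs (>= 1).
#' @param transition 5x5 row-stochastic matrix, rows/cols named with the
#'   stages; rows must sum to 1.
#' @param seed Integer seed; same seed gives a bit-identical hypnogram.
#' @param start Initial stage (default "W": subjects go to bed awake).
#' @return A `hypnogram`.
#' @examples
#' h <- sample_hypnogram(120, seed = 1)
#' mean(h$labels == "W")
#' @export
sample_hypnogram <- function(n_epochs, transition = default_transition_matrix(),
                             seed = 1, start = "W") {
  if (n_epochs < 1) stopf("n_epochs must be >= 1")
  s <- sleep_stages()
  transition <- as.matrix(transition)
  if (!identical(dim(transition), c(5L, 5L)))
    stopf("transition matrix must be 5x5 over %s", paste(s, collapse = "/"))
  if (is.null(rownames(transition))) dimnames(transition) <- list(s, s)
  transition <- transition[s, s]
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stopf("transition matrix rows must be non-negative and sum to 1")
  if (!start %in% s) stopf("unknown start stage '%s'", start)
  labels <- character(n_epochs)
  with_seed(seed, {
    cur <- start
    for (i in seq_len(n_epochs)) {
      labels[i] <- cur
      cur <- sample(s, 1L, prob = transition[cur, ])
    }
  })
  hypnogram(labels)
}

#' Stage-dependent spectral models
#'
#' One model per stage describing the signal properties that sleep-staging
#' features detect: relative power spectral density per classical EEG band
#' (delta 1-4, theta 4-8, alpha 8-16, beta 16-32 Hz), the spindle event
#' rate (N2), slow-wave amplitude (N3), eye-movement event rate (W/REM),
#' and the relative EMG-band (32-80 Hz) level (high in wake, near-absent
#' in REM atonia).
#'
#' `contrast` scales the inter-stage differences: 1 is the default (well
#' separated stages), 0 collapses every stage onto the across-stage mean
#' model, making the stages indistinguishable.
#'
#' @param contrast Non-negative separability dial (default 1).
#' @return Named list of per-stage models, each a list with elements
#'   `band_gains`, `spindle_rate`, `slow_wave_amp`, `eog_event_rate`,
#'   `emg_level`.
#' @export
stage_spectrum_models <- function(contrast = 1) {
  if (contrast < 0) stopf("contrast must be >= 0")
  base <- list(
    W   = list(band_gains = c(delta = 0.5, theta = 0.4, alpha = 1.6, beta = 0.8),
               spindle_rate = 0, slow_wave_amp = 0, eog_event_rate = 4,
               emg_level = 1.5),
    N1  = list(band_gains = c(delta = 0.8, theta = 1.3, alpha = 0.45, beta = 0.3),
               spindle_rate = 0, slow_wave_amp = 0, eog_event_rate = 1,
               emg_level = 0.5),
    N2  = list(band_gains = c(delta = 1.3, theta = 0.8, alpha = 0.4, beta = 0.2),
               spindle_rate = 4, slow_wave_amp = 0, eog_event_rate = 0,
               emg_level = 0.3),
    N3  = list(band_gains = c(delta = 3.5, theta = 0.6, alpha = 0.3, beta = 0.15),
               spindle_rate = 0.5, slow_wave_amp = 2.5, eog_event_rate = 0,
               emg_level = 0.2),
    REM = list(band_gains = c(delta = 0.7, theta = 1.0, alpha = 0.5, beta = 0.55),
               spindle_rate = 0, slow_wave_amp = 0, eog_event_rate = 10,
               emg_level = 0.05))
  if (contrast == 1) return(base)
  # pull every parameter toward the across-stage mean
  fields <- c("spindle_rate", "slow_wave_amp", "eog_event_rate", "emg_level")
  mean_gain <- Reduce(`+`, lapply(base, `[[`, "band_gains")) / 5
  mean_f <- vapply(fields, function(f)
    mean(vapply(base, `[[`, numeric(1), f)), numeric(1))
  lapply(base, function(m) {
    m$band_gains <- mean_gain + contrast * (m$band_gains - mean_gain)
    for (f in fields)
      m[[f]] <- max(0, mean_f[[f]] + contrast * (m[[f]] - mean_f[[f]]))
    m
  })
}

#' Default around-the-ear electrode layout
#'
#' Eight already-referenced signal electrodes per ear, labelled L1-L8 and
#' R1-R8 so that the pooled derivations (front-back electrodes 1,8 vs 4,5;
#' top-bottom electrodes 2,3 vs 6,7; left vs right ear averages) are
#' addressable by electrode number.
#' @return Character vector of 16 labels.
#' @export
ceegrid_layout <- function() {
  c(paste0("L", 1:8), paste0("R", 1:8))
}

band_edges_hz <- function() {
  c(delta_lo = 1, delta_hi = 4, theta_hi = 8, alpha_hi = 16, beta_hi = 32)
}

# Amplitude-shaping profile for one epoch's noise: flat power density per
# band (so relative PSD ordering equals band_gains ordering), small floor
# outside 0.5-80 Hz, EMG band 32-80 Hz scaled by emg_level.
shape_profile <- function(freqs, band_gains, emg_level) {
  g <- rep(0.02, length(freqs))
  g[freqs >= 0.5 & freqs < 1]  <- sqrt(band_gains[["delta"]])
  g[freqs >= 1  & freqs < 4]   <- sqrt(band_gains[["delta"]])
  g[freqs >= 4  & freqs < 8]   <- sqrt(band_gains[["theta"]])
  g[freqs >= 8  & freqs < 16]  <- sqrt(band_gains[["alpha"]])
  g[freqs >= 16 & freqs < 32]  <- sqrt(band_gains[["beta"]])
  g[freqs >= 32 & freqs <= 80] <- 0.5 * sqrt(emg_level)
  g
}

# One epoch of coloured noise via inverse-FFT shaping of white noise.
coloured_noise <- function(n, fs, band_gains, emg_level) {
  z <- stats::fft(stats::rnorm(n))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)       # two-sided -> folded frequency
  g <- shape_profile(freqs, band_gains, emg_level)
  Re(stats::fft(z * g, inverse = TRUE)) / n
}

# Hann-windowed sinusoidal burst (spindles) or smooth deflection (EOG).
burst <- function(n_total, start, dur, fs, freq, amp) {
  len <- max(2L, round(dur * fs))
  idx <- start:min(start + len - 1L, n_total)
  t <- (seq_along(idx) - 1) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
  out <- numeric(n_total)
  out[idx] <- amp * w * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi))
  out
}

eog_deflection <- function(n_total, start, dur, fs, amp) {
  len <- max(2L, round(dur * fs))
  idx <- start:min(start + len - 1L, n_total)
  u <- seq(-3, 3, length.out = length(idx))
  out <- numeric(n_total)
  out[idx] <- amp * sign(stats::runif(1) - 0.5) * exp(-u^2 / 2)
  out
}

#' Synthesize a multichannel sleep recording from a hypnogram
#'
#' Per epoch, each channel is coloured noise whose band-wise power density
#' follows the stage's `band_gains`, plus stage events shared across
#' channels through a common source: spindle bursts (11-16 Hz) in N2,
#' high-amplitude 0.5-2 Hz waves in N3, smooth eye-movement deflections in
#' REM/W, and an independent broadband 32-80 Hz component scaled by
#' `emg_level`. Epochs are joined with a 0.5-s raised-cosine cross-fade.
#' Scalp reference channels (if requested) carry the same common source
#' with less channel noise, emulating a simultaneously recorded PSG.
#'
#' @param hyp A `hypnogram` (the ground truth).
#' @param models Per-stage models from [stage_spectrum_models()].
#' @param fs Sampling rate in Hz (>= 128).
#' @param channel_layout Ear-electrode labels (default [ceegrid_layout()]).
#' @param seed Integer seed.
#' @param amplitude Global amplitude scale in microvolts (the ear montage
#'   has no asserted physical amplitude; this dial sets it).
#' @param scalp_labels Optional labels of scalp reference channels to
#'   append (e.g. `c("C4:M1")`).
#' @param source_weight Coupling of each ear channel to the common source.
#' @param noise_scale Relative per-channel independent noise level.
#' @return A `synthetic_night`: list with `recording`, `true_hypnogram`,
#'   `activity_counts` (60-s epochs), `artifact_intervals` (empty
#'   data.frame), and `seed`.
#' @examples
#' night <- synthesize_recording(sample_hypnogram(20, seed = 1), seed = 1)
#' night$recording
#' @export
synthesize_recording <- function(hyp, models = stage_spectrum_models(),
                                 fs = 128, channel_layout = ceegrid_layout(),
                                 seed = 1, amplitude = 30,
                                 scalp_labels = character(0),
                                 source_weight = 1, noise_scale = 0.6) {
  if (fs < 128) stopf("fs must be >= 128 Hz")
  miss <- setdiff(unique(hyp$labels), names(models))
  if (length(miss))
    stopf("no spectral model for stage(s): %s", paste(miss, collapse = ", "))
  epoch_s <- hyp$epoch_s
  n_ep <- length(hyp$labels)
  n <- round(epoch_s * fs)
  nf <- round(0.5 * fs)                     # cross-fade length
  all_labels <- c(channel_layout, scalp_labels)
  n_ear <- length(channel_layout)
  n_ch <- length(all_labels)
  data <- matrix(0, n_ch, n_ep * n, dimnames = list(all_labels, NULL))
  fade_in <- (0.5 - 0.5 * cos(pi * seq_len(nf) / nf))
  with_seed(seed, {
    ch_w <- stats::runif(n_ear, 0.7, 1.3)   # fixed per-channel couplings
    prev_tail <- NULL
    for (e in seq_len(n_ep)) {
      m <- models[[hyp$labels[e]]]
      # common cortical source: coloured noise + stage events
      src <- coloured_noise(n + nf, fs, m$band_gains, 0)
      if (m$slow_wave_amp > 0) {
        f_sw <- stats::runif(1, 0.6, 1.5)
        src <- src + m$slow_wave_amp *
          sin(2 * pi * f_sw * seq_len(n + nf) / fs + stats::runif(1, 0, 2 * pi))
      }
      n_sp <- stats::rpois(1, m$spindle_rate * epoch_s / 60)
      for (k in seq_len(n_sp)) {
        src <- src + burst(n + nf, sample.int(n, 1),
                           stats::runif(1, 0.6, 1.4), fs,
                           stats::runif(1, 11, 16),
                           stats::runif(1, 2, 3.5))
      }
      n_eog <- stats::rpois(1, m$eog_event_rate * epoch_s / 60)
      eog <- numeric(n + nf)
      for (k in seq_len(n_eog)) {
        # slow ocular deflections: energy concentrated below ~1 Hz
        eog <- eog + eog_deflection(n + nf, sample.int(n, 1),
                                    stats::runif(1, 1.5, 2.5), fs,
                                    stats::runif(1, 2, 3))
      }
      # assemble channels: coupling * (source + eog) + independent noise
      seg <- matrix(0, n_ch, n + nf)
      zero_model <- all(m$band_gains == 0) && m$emg_level == 0 &&
        m$slow_wave_amp == 0 && m$spindle_rate == 0 && m$eog_event_rate == 0
      for (c in seq_len(n_ear)) {
        noise <- if (zero_model) numeric(n + nf) else
          coloured_noise(n + nf, fs, m$band_gains, m$emg_level)
        seg[c, ] <- source_weight * ch_w[c] * (src + eog) + noise_scale * noise
      }
      for (c in seq_len(length(scalp_labels))) {
        noise <- if (zero_model) numeric(n + nf) else
          coloured_noise(n + nf, fs, m$band_gains, 0.3)
        seg[n_ear + c, ] <- src + eog + 0.25 * noise
      }
      if (zero_model) seg[] <- 0
      # overlap-add with raised-cosine cross-fade into the previous tail
      a <- (e - 1L) * n + 1L
      if (!is.null(prev_tail)) {
        seg[, seq_len(nf)] <- seg[, seq_len(nf), drop = FALSE] *
          rep(fade_in, each = n_ch) +
          prev_tail * rep(1 - fade_in, each = n_ch)
      }
      data[, a:(a + n - 1L)] <- seg[, seq_len(n)]
      prev_tail <- seg[, n + seq_len(nf), drop = FALSE]
    }
    data <- data * amplitude / 3
    counts <- sample_activity_counts(hyp)
  })
  structure(list(
    recording = recording(data, fs, all_labels),
    true_hypnogram = hyp,
    activity_counts = counts,
    artifact_intervals = data.frame(start_s = numeric(0), end_s = numeric(0)),
    seed = seed), class = "synthetic_night")
}

# Poisson activity counts at 60-s epochs: high rate when either half-epoch
# is wake, near zero during sleep. Called inside synthesize_recording's
# seeded block.
sample_activity_counts <- function(hyp, wake_rate = 60, sleep_rate = 0.5) {
  lab <- hyp$labels
  n60 <- floor(length(lab) * hyp$epoch_s / 60)
  per60 <- 60 / hyp$epoch_s
  rate <- vapply(seq_len(n60), function(i) {
    idx <- ((i - 1) * per60 + 1):(i * per60)
    if (any(lab[idx] == "W")) wake_rate else sleep_rate
  }, numeric(1))
  stats::rpois(n60, rate)
}

#' @export
print.synthetic_night <- function(x, ...) {
  cat("<synthetic_night>\n")
  print(x$recording)
  print(x$true_hypnogram)
  cat(sprintf("  %d artifact interval(s), %d activity-count epochs\n",
              nrow(x$artifact_intervals), length(x$activity_counts)))
  invisible(x)
}

#' Inject high-amplitude movement artifacts into a synthetic night
#'
#' Places Poisson-distributed 1-10-s windows in which a random subset of
#' ear channels is multiplied by `amp_scale`, records the ground-truth
#' intervals, and raises the activity counts of overlapping 60-s epochs
#' (movement shows up in actigraphy too).
#'
#' @param night A `synthetic_night`.
#' @param rate_per_hour Expected artifact events per hour (0 = no-op).
#' @param amp_scale Multiplicative amplitude factor (> 1).
#' @param seed Integer seed.
#' @param min_channels Minimum number of channels hit per event.
#' @return The modified `synthetic_night` with `artifact_intervals` filled.
#' @export
inject_artifacts <- function(night, rate_per_hour, amp_scale = 20, seed = 1,
                             min_channels = 4) {
  if (amp_scale <= 1) stopf("amp_scale must be > 1")
  if (rate_per_hour == 0) return(night)
  rec <- night$recording
  ear <- intersect(ceegrid_layout(), rec$labels)
  if (!length(ear)) ear <- rec$labels
  dur_h <- duration_s(rec) / 3600
  with_seed(seed, {
    n_ev <- stats::rpois(1, rate_per_hour * dur_h)
    iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
    for (k in seq_len(n_ev)) {
      dur <- stats::runif(1, 1, 10)
      start <- stats::runif(1, 0, duration_s(rec) - dur)
      n_hit <- sample(min_channels:length(ear), 1)
      hit <- sample(ear, n_hit)
      a <- max(1L, round(start * rec$fs))
      b <- min(ncol(rec$data), round((start + dur) * rec$fs))
      rec$data[hit, a:b] <- rec$data[hit, a:b] * amp_scale
      iv <- rbind(iv, data.frame(start_s = start, end_s = start + dur))
    }
    # movement raises actigraphy counts in overlapping 60-s epochs
    if (nrow(iv)) {
      counts <- night$activity_counts
      for (k in seq_len(nrow(iv))) {
        e60 <- unique(pmin(length(counts),
                           (floor(iv$start_s[k] / 60):floor(iv$end_s[k] / 60)) + 1L))
        counts[e60] <- counts[e60] + stats::rpois(length(e60), 40)
      }
      night$activity_counts <- counts
    }
  })
  night$recording <- rec
  night$artifact_intervals <- night$artifact_intervals[0, ]
  if (n_ev > 0) night$artifact_intervals <- iv[order(iv$start_s), ]
  night
}

#' Generate a synthetic multi-subject cohort
#'
#' Convenience wrapper: one disrupted-sleep night per subject, with
#' per-subject seeds split from a root seed.
#'
#' @param n_subjects Number of subjects.
#' @param n_epochs 30-s epochs per subject night.
#' @param seed Root seed.
#' @param contrast Stage-separability dial (see [stage_spectrum_models()]).
#' @param fs Sampling rate (Hz).
#' @param artifact_rate Artifact events per hour (0 disables injection).
#' @param scalp_labels Scalp reference channels to include.
#' @param ... Passed to [synthesize_recording()].
#' @return List of `synthetic_night` objects.
#' @export
synth_cohort <- function(n_subjects, n_epochs = 480, seed = 1, contrast = 1,
                         fs = 128, artifact_rate = 0,
                         scalp_labels = character(0), ...) {
  seeds <- split_seed(seed, 3L * n_subjects)
  models <- stage_spectrum_models(contrast)
  lapply(seq_len(n_subjects), function(i) {
    h <- sample_hypnogram(n_epochs, seed = seeds[3 * i - 2])
    night <- synthesize_recording(h, models, fs = fs, seed = seeds[3 * i - 1],
                                  scalp_labels = scalp_labels, ...)
    if (artifact_rate > 0)
      night <- inject_artifacts(night, artifact_rate, seed = seeds[3 * i])
    night
  })
}

#' Write the ground-truth sidecar files for a synthetic night
#'
#' CSV for hypnogram (`epoch_index,stage`) and actigraphy counts
#' (`epoch_index,count`), JSON for artifact intervals.
#' @param night A `synthetic_night`.
#' @param dir Output directory (created if absent).
#' @param stem File-name stem.
#' @return Invisibly, the vector of files written.
#' @export
write_night_sidecars <- function(night, dir, stem = "night") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hyp_f <- file.path(dir, paste0(stem, "_hypnogram.csv"))
  act_f <- file.path(dir, paste0(stem, "_activity.csv"))
  art_f <- file.path(dir, paste0(stem, "_artifacts.json"))
  write_hypnogram(night$true_hypnogram, hyp_f)
  utils::write.csv(data.frame(epoch_index = seq_along(night$activity_counts),
                              count = night$activity_counts),
                   act_f, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(night$artifact_intervals, art_f, digits = NA)
  invisible(c(hyp_f, act_f, art_f))
}
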