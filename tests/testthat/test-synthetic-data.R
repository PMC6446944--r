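test_that("hypnogram sampling respects the transition model and seed", {
  # absorbing wake state
  eye <- diag(5)
  dimnames(eye) <- list(sleep_stages(), sleep_stages())
  h <- sample_hypnogram(50, eye, seed = 3, start = "W")
  expect_true(all(h$labels == "W"))

  # determinism
  expect_identical(sample_hypnogram(200, seed = 7)$labels,
                   sample_hypnogram(200, seed = 7)$labels)

  # non-stochastic matrix rejected
  bad <- default_transition_matrix()
  bad[1, 1] <- 2
  expect_error(sample_hypnogram(10, bad), "sum to 1")
})

test_that("default disrupted-sleep matrix yields realistic wake occupancy", {
  # stationary wake occupancy of the default matrix by eigen-decomposition
  m <- default_transition_matrix()
  e <- eigen(t(m))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  expect_equal((v / sum(v))[1], 0.388, tolerance = 0.01)

  # Monte-Carlo wake fraction across seeds stays in the disrupted band
  fracs <- vapply(1:100, function(s)
    mean(sample_hypnogram(1440, seed = s)$labels == "W"), numeric(1))
  expect_true(all(fracs > 0.25 & fracs < 0.55))
})

test_that("synthesized spectra track the stage models", {
  models <- stage_spectrum_models()
  # isolate the coloured-noise shaping: gains in -> band powers out
  # (event processes carry their own spectra and are tested separately)
  no_events <- lapply(models, function(m) {
    m$spindle_rate <- 0; m$slow_wave_amp <- 0; m$eog_event_rate <- 0
    m
  })
  fs <- 128
  rel_density <- function(stage, n_ep = 12, seed = 5) {
    h <- hypnogram(rep(stage, n_ep))
    night <- synthesize_recording(h, no_events, fs = fs, seed = seed,
                                  channel_layout = paste0("L", 1:8))
    x <- night$recording$data[1, ]
    p <- oracle_welch(x, fs)
    bands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 16),
                  beta = c(16, 32))
    vapply(bands, function(b)
      oracle_band_power(p, b[1], b[2]) / diff(b), numeric(1))
  }
  for (stage in c("W", "N2", "N3", "REM")) {
    d <- rel_density(stage)
    expect_identical(order(d), order(models[[stage]]$band_gains),
                     label = sprintf("band-density ordering for %s", stage))
  }

  # delta dominance in N3 versus beta (periodogram oracle)
  d3 <- rel_density("N3")
  expect_gt(d3[["delta"]] / d3[["beta"]], 5)

  # EMG-band power tracks emg_level: W night > N3 night
  emg_pow <- function(stage) {
    h <- hypnogram(rep(stage, 8))
    night <- synthesize_recording(h, models, fs = fs, seed = 9,
                                  channel_layout = paste0("L", 1:4))
    x <- night$recording$data[1, ]
    p <- oracle_welch(x, fs)
    oracle_band_power(p, 32, 64)
  }
  expect_gt(emg_pow("W"), emg_pow("N3"))

  # all-zero model gives an all-zero signal
  zero <- lapply(stage_spectrum_models(), function(m) {
    m$band_gains[] <- 0
    m$spindle_rate <- 0; m$slow_wave_amp <- 0
    m$eog_event_rate <- 0; m$emg_level <- 0
    m
  })
  night <- synthesize_recording(hypnogram(rep("N2", 3)), zero, fs = fs,
                                seed = 1, channel_layout = c("L1", "L2"))
  expect_true(all(night$recording$data == 0))

  # missing stage model errors
  expect_error(
    synthesize_recording(hypnogram(c("W", "REM")),
                         stage_spectrum_models()["W"], seed = 1),
    "no spectral model")
})

test_that("same seed reproduces the whole night bit-identically", {
  h <- sample_hypnogram(10, seed = 4)
  n1 <- synthesize_recording(h, seed = 11)
  n2 <- synthesize_recording(h, seed = 11)
  expect_identical(n1$recording$data, n2$recording$data)
  expect_identical(n1$activity_counts, n2$activity_counts)
  n3 <- synthesize_recording(h, seed = 12)
  expect_false(identical(n1$recording$data, n3$recording$data))
})

test_that("artifact injection marks what it modifies", {
  h <- sample_hypnogram(60, seed = 2)
  night <- synthesize_recording(h, seed = 21)

  # rate 0 is a no-op
  same <- inject_artifacts(night, 0, amp_scale = 20, seed = 1)
  expect_identical(same$recording$data, night$recording$data)
  expect_equal(nrow(same$artifact_intervals), 0)

  withart <- inject_artifacts(night, rate_per_hour = 8, amp_scale = 20,
                              seed = 5)
  iv <- withart$artifact_intervals
  expect_gt(nrow(iv), 0)

  # injected intervals have short-window power far above the night median
  fs <- night$recording$fs
  win_pow <- function(rec, ch) {
    x <- rec$data[ch, ]
    colMeans(matrix(x[1:(floor(length(x) / fs) * fs)], nrow = fs)^2)
  }
  for (ch in c(1, 8, 16)) {
    p0 <- win_pow(night$recording, ch)
    p1 <- win_pow(withart$recording, ch)
    changed <- which(p1 > 2 * p0)
    if (!length(changed)) next        # channel not in the hit subset
    expect_true(all(p1[changed] > 10 * median(p1)))
  }

  # determinism of placement
  again <- inject_artifacts(night, 8, amp_scale = 20, seed = 5)
  expect_identical(again$artifact_intervals, withart$artifact_intervals)

  # activity counts raised in overlapping 60-s epochs
  e60 <- unique(floor(iv$start_s / 60)) + 1
  expect_true(mean(withart$activity_counts[e60] >=
                     night$activity_counts[e60]) == 1)
  expect_gt(sum(withart$activity_counts[e60] - night$activity_counts[e60]), 0)
})

test_that("activity counts separate wake from sleep epochs", {
  h <- hypnogram(rep(c("W", "W", "N2", "N2", "N2", "N2"), each = 20))
  night <- synthesize_recording(h, seed = 31,
                                channel_layout = c("L1", "L2"))
  counts <- night$activity_counts
  wake60 <- rep(h$labels[seq(1, length(h$labels), by = 2)] == "W",
                length.out = length(counts))
  expect_gt(min(counts[wake60]), max(counts[!wake60]))
})

test_that("raising stage contrast raises downstream staging performance", {
  # separability dial: LOSO kappa grows with inter-stage spectral contrast
  kap <- vapply(c(0.05, 0.2, 0.6), function(ct) {
    run <- run_pipeline(run_config(n_subjects = 3, n_epochs = 60,
                                   contrast = ct, ntree = 20, seed = 31))
    mean(run$loso$metrics$kappa)
  }, numeric(1))
  expect_true(all(diff(kap) > 0))
})
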