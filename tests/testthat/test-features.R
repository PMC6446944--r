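test_that("time-domain features match closed-form values", {
  fs <- fs_test
  s10 <- sine_epoch(10)
  f <- time_domain(s10, fs)
  # 2 zero crossings per cycle, 10 cycles/s (one fewer at the boundary)
  expect_equal(f[["F3"]], 20, tolerance = 0.01)
  expect_equal(f[["F1"]], 0, tolerance = 1e-9)   # symmetric signal

  # white noise: mobility -> sqrt(2) since var(diff) = 2 sigma^2
  wn <- noise_epoch(1, dur = 60)
  f <- time_domain(wn, fs)
  expect_equal(f[["F4"]], sqrt(2), tolerance = 0.05)

  # direct-oracle agreement on fixed noise
  x <- noise_epoch(2)
  f <- time_domain(x, fs)
  z <- (x - mean(x)) / sd(x)
  expect_equal(f[["F1"]], mean(z^3), tolerance = 1e-12)
  expect_equal(f[["F2"]], mean(z^4) - 3, tolerance = 1e-12)
  expect_equal(f[["F4"]], sqrt(var(diff(x)) / var(x)), tolerance = 1e-12)
  expect_equal(f[["F6"]], quantile(abs(x), 0.75, names = FALSE))

  # constant signal: F4/F5 undefined
  f <- time_domain(rep(2, 30 * fs), fs)
  expect_true(is.na(f[["F4"]]) && is.na(f[["F5"]]))

  # partner correlation
  y <- 0.5 * x + noise_epoch(3)
  f <- time_domain(x, fs, partner = y)
  expect_equal(f[["F7"]], cor(x, y))
})

test_that("band proxies isolate their bands", {
  fs <- fs_test
  s10 <- sine_epoch(10)
  pr <- band_proxies(s10, fs)
  # 10 Hz passes the EOG band, attenuated >= 40 dB in the EMG band
  expect_gt(mean(pr$eog^2), 0.4 * mean(s10^2))
  expect_lt(mean(pr$emg^2), 1e-4 * mean(pr$eog^2))
  expect_true(pr$emg_clipped)           # fs 128 < 2 x 80 Hz

  s50 <- sine_epoch(50)
  pr50 <- band_proxies(s50, fs)
  expect_lt(mean(pr50$eog^2), 0.01 * mean(s50^2))  # outside 0.5-30
  expect_gt(mean(pr50$emg^2), 0.4 * mean(s50^2))

  pr256 <- band_proxies(sine_epoch(10, fs = 256), 256)
  expect_false(pr256$emg_clipped)
})

test_that("EMG features measure power, troughs and bursts", {
  fs <- fs_test
  set.seed(4)
  emg <- rnorm(30 * fs)
  f <- emg_features(emg, fs)
  expect_equal(f[["F8"]], mean(emg^2), tolerance = 1e-12)
  # stationary noise: minimum 1-s window power close to the mean
  expect_gt(f[["F9"]] / f[["F8"]], 0.6)
  expect_lte(f[["F9"]], f[["F8"]])

  # one 2-s burst x10 in quiet background: strong burst ratio
  burst <- rnorm(30 * fs, sd = 0.1)
  burst[(10 * fs):(12 * fs)] <- burst[(10 * fs):(12 * fs)] * 10
  f <- emg_features(burst, fs)
  expect_gt(f[["F10"]], 5)

  # amplitude doubling: F8 quadruples, F10 unchanged
  f1 <- emg_features(emg, fs); f2 <- emg_features(2 * emg, fs)
  expect_equal(f2[["F8"]], 4 * f1[["F8"]], tolerance = 1e-9)
  expect_equal(f2[["F10"]], f1[["F10"]], tolerance = 1e-9)

  # silent proxy: burst ratio undefined
  expect_true(is.na(emg_features(numeric(30 * fs), fs)[["F10"]]))
})

test_that("EOG features split slow and rapid eye-movement bands", {
  fs <- fs_test
  f1 <- eog_features(sine_epoch(1), fs)
  expect_gt(f1[["F11"]] / f1[["F12"]], 100)
  f4 <- eog_features(sine_epoch(4), fs)
  expect_gt(f4[["F12"]] / f4[["F11"]], 100)
  f0 <- eog_features(numeric(30 * fs), fs)
  expect_equal(unname(f0), c(0, 0))
})

test_that("spectral features match the brute-force periodogram oracle", {
  fs <- fs_test
  s2 <- sine_epoch(2)
  f <- spectral_features(s2, fs)
  expect_gte(f[["F16"]], 0.99)         # delta fraction
  expect_equal(f[["F27"]], 2)          # peak frequency
  expect_gt(f[["F19"]], 50)            # delta/theta

  wn <- noise_epoch(6)
  f <- spectral_features(wn, fs)
  expect_gte(f[["F28"]], 0.95)         # near-flat PSD entropy

  # oracle agreement: band powers and derived ratios on fixed noise
  p <- oracle_welch(wn, fs)
  tot <- oracle_band_power(p, 1, 32)
  expect_equal(f[["F13"]], oracle_band_power(p, 8, 16) / tot,
               tolerance = 1e-9)
  expect_equal(f[["F14"]], oracle_band_power(p, 16, 32) / tot,
               tolerance = 1e-9)
  expect_equal(f[["F15"]], oracle_band_power(p, 4, 8) / tot,
               tolerance = 1e-9)
  expect_equal(f[["F16"]], oracle_band_power(p, 1, 4) / tot,
               tolerance = 1e-9)
  expect_equal(f[["F17"]],
               oracle_band_power(p, 8, 16) / oracle_band_power(p, 1, 4),
               tolerance = 1e-9)
  expect_equal(f[["F23"]],
               (oracle_band_power(p, 4, 8) + oracle_band_power(p, 1, 4)) /
                 (oracle_band_power(p, 8, 16) + oracle_band_power(p, 16, 32)),
               tolerance = 1e-9)
  # spectral edge / median frequency from the oracle PSD
  sel <- p$freq >= 1 & p$freq < 32
  cum <- cumsum(p$psd[sel]) / sum(p$psd[sel])
  expect_equal(f[["F24"]], p$freq[sel][which(cum >= 0.95)[1]])
  expect_equal(f[["F25"]], p$freq[sel][which(cum >= 0.5)[1]])
  expect_equal(f[["F27"]], p$freq[sel][which.max(p$psd[sel])])
  pr <- p$psd[sel] / sum(p$psd[sel])
  expect_equal(f[["F28"]], -sum(pr * log(pr)) / log(sum(sel)),
               tolerance = 1e-9)

  # relative band powers sum to 1
  expect_equal(sum(f[c("F13", "F14", "F15", "F16")]), 1, tolerance = 1e-9)

  # zero signal: all missing
  expect_true(all(is.na(spectral_features(numeric(30 * fs), fs))))
})

test_that("spindle features detect bursts and stationarity", {
  fs <- fs_test
  set.seed(9)
  bg <- rnorm(30 * fs, sd = 0.5)
  x <- bg
  idx <- (15 * fs):(16 * fs)           # one 1-s 13-Hz burst at 5x background
  x[idx] <- x[idx] + 2.5 * sin(2 * pi * 13 * seq_along(idx) / fs)
  f <- spindle_features(x, fs)
  expect_gt(f[["F29"]], 0)
  expect_gte(f[["F33"]], 0.5)
  expect_lte(f[["F33"]], 1.5)
  expect_gt(f[["F32"]], spindle_features(bg, fs)[["F32"]])

  # stationary noise is more frequency-stationary than a chirp
  f_noise <- spindle_features(noise_epoch(10), fs)
  f_chirp <- spindle_features(chirp_epoch(), fs)
  expect_gt(f_noise[["F30"]], f_chirp[["F30"]])

  # zero signal
  f0 <- spindle_features(numeric(30 * fs), fs)
  expect_equal(f0[["F29"]], 0)
  expect_equal(f0[["F32"]], 0)
})

test_that("feature scaling behaves as documented", {
  fs <- fs_test
  x <- noise_epoch(20) + sine_epoch(11, amp = 0.5)
  f1 <- epoch_features(x, fs)
  f2 <- epoch_features(2 * x, fs)
  scale_free <- c(paste0("F", 1:5), paste0("F", 13:23), "F28", "F29",
                  "F30", "F31")
  for (lab in scale_free)
    expect_equal(f2[[lab]], f1[[lab]], tolerance = 1e-9, label = lab)
  for (lab in c("F6", "F32"))         # linear in amplitude
    expect_equal(f2[[lab]], 2 * f1[[lab]], tolerance = 1e-9, label = lab)
  for (lab in c("F8", "F9", "F11", "F12"))  # quadratic (power)
    expect_equal(f2[[lab]], 4 * f1[[lab]], tolerance = 1e-9, label = lab)
})

test_that("feature matrix applies masks, partners and the forced-wake rule", {
  fs <- fs_test
  set.seed(30)
  n_ep <- 4
  sigs <- list("FB(L)" = rnorm(n_ep * 30 * fs),
               "FB(R)" = rnorm(n_ep * 30 * fs),
               "L-R" = rnorm(n_ep * 30 * fs))
  # mask: epoch 2 of FB(L) 40% rejected; epoch 3 fully rejected everywhere
  m <- matrix(FALSE, n_ep * 30, 3,
              dimnames = list(NULL, names(sigs)))
  m[31:42, 1] <- TRUE                  # 12 of 30 windows in epoch 2
  m[61:90, ] <- TRUE                   # all of epoch 3
  mask <- structure(m, window_s = 1, fs = fs, class = "artifact_mask")
  fm <- feature_matrix(sigs, fs, mask = mask)

  expect_equal(dim(fm$x), c(4, 99))
  expect_equal(unname(fm$fraction_used[2, "FB(L)"]), 0.6)
  expect_equal(fm$fraction_used[1, ], c("FB(L)" = 1, "FB(R)" = 1, "L-R" = 1))
  # fully rejected epoch: NaN row + forced wake
  expect_true(all(is.na(fm$x[3, ])))
  expect_identical(fm$forced_wake, c(FALSE, FALSE, TRUE, FALSE))
  # partially rejected epoch still yields features
  expect_true(all(is.finite(fm$x[2, "FB(L)/F1"])))

  # F7 pairing: FB(L) partner is FB(R)
  e1 <- 1:(30 * fs)
  expect_equal(unname(fm$x[1, "FB(L)/F7"]),
               cor(sigs[["FB(L)"]][e1], sigs[["FB(R)"]][e1]))
  expect_equal(unname(fm$x[1, "L-R/F7"]),
               cor(sigs[["L-R"]][e1], sigs[["FB(L)"]][e1]))

  # no mask: everything used
  fm2 <- feature_matrix(sigs, fs)
  expect_true(all(fm2$fraction_used == 1))

  expect_error(feature_matrix(list(a = 1:10, b = 1:5), fs),
               "share a length")
})

test_that("features separate stages on synthetic nights", {
  models <- stage_spectrum_models()
  fs <- 128
  mean_feat <- function(stage, lab, n_ep = 30) {
    night <- synthesize_recording(hypnogram(rep(stage, n_ep)), models,
                                  fs = fs, seed = 77,
                                  channel_layout = ceegrid_layout())
    fm <- night_features(night, run_config())
    mean(fm$x[, lab], na.rm = TRUE)
  }
  # delta fraction orders N3 > N2 > W
  d_n3 <- mean_feat("N3", "FB(L)/F16")
  d_n2 <- mean_feat("N2", "FB(L)/F16")
  d_w <- mean_feat("W", "FB(L)/F16")
  expect_gt(d_n3, d_n2)
  expect_gt(d_n2, d_w)
  # EMG power W > REM
  expect_gt(mean_feat("W", "FB(L)/F8"), mean_feat("REM", "FB(L)/F8"))
  # spindle fraction N2 above all other stages
  sp <- vapply(c("N2", "W", "N1", "N3", "REM"), mean_feat,
               numeric(1), lab = "FB(L)/F29")
  expect_true(all(sp["N2"] > sp[-1]))
})
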