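# Deterministic signal builders shared across tests.

fs_test <- 128

sine_epoch <- function(freq, fs = fs_test, dur = 30, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs + phase)
}

noise_epoch <- function(seed, fs = fs_test, dur = 30, sd = 1) {
  set.seed(seed)
  rnorm(dur * fs, sd = sd)
}

chirp_epoch <- function(f0 = 2, f1 = 20, fs = fs_test, dur = 30) {
  t <- (0:(dur * fs - 1)) / fs
  sin(2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2))
}

# independent brute-force Welch PSD: plain loop, 2-s Hann, 50% overlap
oracle_welch <- function(x, fs, win_s = 2) {
  w <- round(win_s * fs)
  step <- w / 2
  starts <- seq(1, length(x) - w + 1, by = step)
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + w - 1)]
    seg <- (seg - mean(seg)) * han
    acc <- acc + Mod(fft(seg))^2
  }
  psd <- acc / length(starts) / (fs * sum(han^2))
  nf <- floor(w / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / w, psd = psd[seq_len(nf)])
}

oracle_band_power <- function(p, lo, hi) sum(p$psd[p$freq >= lo & p$freq < hi])
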