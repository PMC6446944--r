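#' Electrode derivation
#'
#' A named, weighted electrode combination: the uniform average of the
#' `plus` set minus the uniform average of the `minus` set.
#'
#' @param name Derivation name (e.g. `"FB(L)"`, `"L-R"`, `"L2-L6"`).
#' @param plus,minus Disjoint, non-empty electrode label sets.
#' @return An object of class `"derivation"`.
#' @export
derivation <- function(name, plus, minus) {
  if (!length(plus) || !length(minus))
    stopf("derivation '%s': plus/minus sets must be non-empty", name)
  if (length(intersect(plus, minus)))
    stopf("derivation '%s': plus/minus sets must be disjoint", name)
  structure(list(name = name, plus = plus, minus = minus),
            class = "derivation")
}

#' @export
print.derivation <- function(x, ...) {
  cat(sprintf("<derivation> %s: mean(%s) - mean(%s)\n", x$name,
              paste(x$plus, collapse = ","), paste(x$minus, collapse = ",")))
  invisible(x)
}

#' Standard around-the-ear derivations
#'
#' The pooled derivations defined on the 8-per-ear layout: left-vs-right
#' ear average (`L-R`), front-vs-back electrodes 1,8 vs 4,5 (`FB(L)`,
#' `FB(R)`), and top-vs-bottom electrodes 2,3 vs 6,7 (`TB(L)`, `TB(R)`).
#' `staging_derivations()` returns the three used for automatic staging:
#' FB(L), FB(R) and L-R.
#'
#' @param exclude Electrode labels to drop (e.g. high-impedance channels);
#'   a derivation whose plus or minus set empties becomes unavailable and
#'   is omitted with a warning.
#' @return Named list of `derivation`s.
#' @export
ceegrid_derivations <- function(exclude = character(0)) {
  keep <- function(x) setdiff(x, exclude)
  specs <- list(
    "L-R"   = list(p = paste0("L", 1:8), m = paste0("R", 1:8)),
    "FB(L)" = list(p = c("L1", "L8"), m = c("L4", "L5")),
    "FB(R)" = list(p = c("R1", "R8"), m = c("R4", "R5")),
    "TB(L)" = list(p = c("L2", "L3"), m = c("L6", "L7")),
    "TB(R)" = list(p = c("R2", "R3"), m = c("R6", "R7")))
  out <- list()
  for (nm in names(specs)) {
    p <- keep(specs[[nm]]$p); m <- keep(specs[[nm]]$m)
    if (!length(p) || !length(m)) {
      warning(sprintf("derivation %s unavailable after exclusions", nm))
      next
    }
    out[[nm]] <- derivation(nm, p, m)
  }
  out
}

#' @rdname ceegrid_derivations
#' @export
staging_derivations <- function(exclude = character(0)) {
  ceegrid_derivations(exclude)[c("FB(L)", "FB(R)", "L-R")]
}

#' All intra-ear single-electrode pairs
#'
#' The 28 unordered electrode pairs within each ear (56 in total),
#' candidate single-electrode derivations for exploratory ranking.
#' @param exclude Electrode labels to drop.
#' @return Named list of `derivation`s.
#' @export
single_pair_derivations <- function(exclude = character(0)) {
  out <- list()
  for (side in c("L", "R")) {
    els <- setdiff(paste0(side, 1:8), exclude)
    if (length(els) < 2) next
    cmb <- utils::combn(els, 2)
    for (k in seq_len(ncol(cmb))) {
      nm <- paste0(cmb[1, k], "-", cmb[2, k])
      out[[nm]] <- derivation(nm, cmb[1, k], cmb[2, k])
    }
  }
  out
}

#' Apply a derivation to a recording
#'
#' Sample-wise `mean(plus channels) - mean(minus channels)`. When an
#' artifact mask is supplied, samples in which more than half of either
#' electrode set is rejected are set to `NA` (missing).
#'
#' @param rec A `recording` containing all member electrodes.
#' @param d A `derivation`.
#' @param mask Optional `artifact_mask` computed on `rec` (per electrode).
#' @return Numeric signal vector (length = samples of `rec`).
#' @export
apply_derivation <- function(rec, d, mask = NULL) {
  p <- channel_data(rec, d$plus)
  m <- channel_data(rec, d$minus)
  out <- colMeans(p) - colMeans(m)
  if (!is.null(mask)) {
    n <- length(out)
    bad_frac <- function(set) {
      cols <- intersect(set, colnames(mask))
      if (!length(cols)) return(rep(0, n))
      rowMeans(vapply(cols, function(cc) mask_to_samples(mask, cc, n),
                      logical(n)))
    }
    out[bad_frac(d$plus) > 0.5 | bad_frac(d$minus) > 0.5] <- NA_real_
  }
  out
}

#' Fraction of good-quality data for a derivation
#'
#' The reliability weight g: the fraction of short windows not rejected
#' by the artifact mask. With no mask (or an empty one), g = 1.
#'
#' @param d A `derivation`.
#' @param mask An `artifact_mask` whose columns cover the derivation's
#'   electrodes (or a single pre-computed derivation column).
#' @return Scalar in \[0, 1\].
#' @export
reliability <- function(d, mask = NULL) {
  if (is.null(mask) || nrow(mask) == 0) return(1)
  cols <- intersect(c(d$plus, d$minus), colnames(mask))
  if (!length(cols)) {
    if (d$name %in% colnames(mask)) cols <- d$name else return(1)
  }
  # a window is unusable when > half of either set is rejected
  sub <- mask[, cols, drop = FALSE]
  bad_p <- rowMeans(sub[, intersect(d$plus, cols), drop = FALSE]) > 0.5
  bad_m <- rowMeans(sub[, intersect(d$minus, cols), drop = FALSE]) > 0.5
  if (!length(intersect(d$plus, cols))) bad_p <- rep(FALSE, nrow(sub))
  if (!length(intersect(d$minus, cols))) bad_m <- rep(FALSE, nrow(sub))
  if (d$name %in% cols) return(mean(!sub[, d$name]))
  mean(!(bad_p | bad_m))
}

#' Frequency-band specification
#'
#' Named, ordered, non-overlapping band edges in Hz. Defaults: delta 1-4,
#' theta 4-8, alpha 8-16, beta 16-32.
#' @param bands Named list of `c(lo, hi)` pairs.
#' @return An object of class `"band_spec"` (named list).
#' @export
band_spec <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                   alpha = c(8, 16), beta = c(16, 32))) {
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2])) stopf("band lo must be < hi")
  o <- order(edges[, 1])
  if (any(edges[o, 2][-length(bands)] > edges[o, 1][-1] + 1e-9))
    stopf("bands must not overlap")
  structure(bands, class = "band_spec")
}

#' Integrated band power per 30-s epoch
#'
#' Sum of the raw periodogram within a band, for each whole epoch of a
#' signal. Epochs with missing samples use only the valid samples; epochs
#' with fewer than 2 s of valid data yield `NA`.
#'
#' @param x Numeric signal (may contain NA).
#' @param fs Sampling rate (Hz).
#' @param band `c(lo, hi)` in Hz.
#' @param epoch_s Epoch length in seconds.
#' @return Numeric vector, one value per whole epoch.
#' @export
epoch_band_power <- function(x, fs, band, epoch_s = 30) {
  n <- round(epoch_s * fs)
  n_ep <- floor(length(x) / n)
  vapply(seq_len(n_ep), function(e) {
    seg <- x[((e - 1) * n + 1):(e * n)]
    seg <- seg[!is.na(seg)]
    if (length(seg) < 2 * fs) return(NA_real_)
    spec <- Mod(stats::fft(seg - mean(seg)))^2 / length(seg)
    freqs <- (seq_along(seg) - 1) * fs / length(seg)
    sum(spec[freqs >= band[1] & freqs < band[2]])
  }, numeric(1))
}

#' Correlation index of a derivation against scalp channels
#'
#' `ci = g * sum_j corr(P(d), P(s_j))`: the Pearson correlation, across
#' epochs, of the derivation's integrated band power with each scalp
#' channel's, summed over scalp channels and weighted by the derivation's
#' data-quality fraction g. Zero-variance series contribute 0 (flagged).
#'
#' @param d_power Epoch band-power series of the derivation.
#' @param scalp_powers List (or matrix columns) of epoch band-power series
#'   of the scalp channels.
#' @param g Reliability weight in \[0, 1\].
#' @param normalize If TRUE, average over scalp channels instead of
#'   summing.
#' @return List with `ci`, `raw` (unweighted sum), `g`, and
#'   `n_zero_variance`.
#' @export
correlation_index <- function(d_power, scalp_powers, g = 1,
                              normalize = FALSE) {
  if (!is.list(scalp_powers)) scalp_powers <- list(scalp_powers)
  if (any(vapply(scalp_powers, length, integer(1)) != length(d_power)))
    stopf("power series must share a length")
  if (length(d_power) < 3) stopf("need at least 3 epochs")
  zero <- 0L
  terms <- vapply(scalp_powers, function(s) {
    ok <- !is.na(d_power) & !is.na(s)
    if (sum(ok) < 3 || stats::sd(d_power[ok]) == 0 || stats::sd(s[ok]) == 0) {
      zero <<- zero + 1L
      return(0)
    }
    stats::cor(d_power[ok], s[ok])
  }, numeric(1))
  raw <- sum(terms)
  if (normalize) raw <- raw / length(terms)
  list(ci = g * raw, raw = raw, g = g, n_zero_variance = zero)
}

#' Rank candidate derivations by correlation index
#'
#' Computes, per frequency band, the correlation index of every candidate
#' derivation against all scalp channels of a simultaneously recorded
#' reference, and sorts descending (ties broken by name order).
#'
#' @param rec Ear-EEG `recording` (standardized, epoch-aligned with
#'   `scalp_rec`).
#' @param scalp_rec Scalp reference `recording`.
#' @param candidates List of `derivation`s; defaults to the pooled set
#'   plus all intra-ear single pairs.
#' @param bands A [band_spec()].
#' @param mask Optional `artifact_mask` on `rec` electrodes.
#' @param epoch_s Epoch length (s).
#' @return `data.frame` with columns derivation, band, raw_corr, g, ci,
#'   sorted by band then ci descending.
#' @export
rank_derivations <- function(rec, scalp_rec,
                             candidates = c(ceegrid_derivations(),
                                            single_pair_derivations()),
                             bands = band_spec(), mask = NULL,
                             epoch_s = 30) {
  scalp_pow <- lapply(names(bands), function(bn) {
    lapply(seq_len(nrow(scalp_rec$data)), function(i)
      epoch_band_power(scalp_rec$data[i, ], scalp_rec$fs, bands[[bn]],
                       epoch_s))
  })
  names(scalp_pow) <- names(bands)
  rows <- list()
  for (d in candidates) {
    sig <- apply_derivation(rec, d, mask)
    g <- reliability(d, mask)
    for (bn in names(bands)) {
      dp <- epoch_band_power(sig, rec$fs, bands[[bn]], epoch_s)
      ci <- correlation_index(dp, scalp_pow[[bn]], g)
      rows[[length(rows) + 1L]] <- data.frame(
        derivation = d$name, band = bn, raw_corr = ci$raw, g = g,
        ci = ci$ci)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$band, -out$ci, out$derivation), ]
  rownames(out) <- NULL
  out
}
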