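#' Whole-night sleep statistics
#'
#' Standard summary statistics of a hypnogram: total sleep time (all
#' epochs scored as sleep), sleep efficiency (total sleep over recording
#' duration), wake after sleep onset (wake epochs between the first
#' sleep epoch and the end of the last sleep epoch; wake after the final
#' awakening is excluded), sleep onset latency (time from the start of
#' the recording to the first sleep epoch) and REM latency (time from
#' sleep onset to the first REM epoch, `NA` if no REM occurs).
#'
#' @param h A `hypnogram` (five-stage or sleep-wake).
#' @return A list of class `"sleep_stats"`, all times in minutes,
#'   efficiency as a fraction.
#' @examples
#' sleep_stats(hypnogram(c("W", "W", "N2", "N2", "W", "N2", "W", "W")))
#' @export
sleep_stats <- function(h) {
  lab <- h$labels
  ep_min <- h$epoch_s / 60
  n <- length(lab)
  sleep <- is_sleep(lab)
  dur <- n * ep_min
  total <- sum(sleep) * ep_min
  first <- if (any(sleep)) which(sleep)[1] else NA_integer_
  last <- if (any(sleep)) utils::tail(which(sleep), 1) else NA_integer_
  waso <- if (!is.na(first))
    sum(!sleep[first:last]) * ep_min else 0
  sol <- if (!is.na(first)) (first - 1) * ep_min else dur
  rem <- which(lab == "REM")
  rem_lat <- if (length(rem) && !is.na(first))
    (rem[1] - first) * ep_min else NA_real_
  structure(list(total_sleep_min = total,
                 sleep_efficiency = total / dur,
                 waso_min = waso, sol_min = sol,
                 rem_latency_min = rem_lat,
                 duration_min = dur),
            class = "sleep_stats")
}

#' @export
print.sleep_stats <- function(x, ...) {
  cat(sprintf(paste0("<sleep_stats> TST %.1f min, efficiency %.3f, ",
                     "WASO %.1f min, SOL %.1f min, REM latency %s\n"),
              x$total_sleep_min, x$sleep_efficiency, x$waso_min, x$sol_min,
              if (is.na(x$rem_latency_min)) "NA" else
                sprintf("%.1f min", x$rem_latency_min)))
  invisible(x)
}

#' Accuracy and Cohen's kappa between two hypnograms
#'
#' Accuracy is the fraction of equal epochs; kappa is chance-corrected
#' agreement, `(p_o - p_e) / (1 - p_e)` with the expected agreement from
#' the product of the scorers' marginals. If one scorer is constant,
#' `p_o == p_e` and kappa is 0 by convention (also when both agree
#' perfectly on a single class).
#'
#' @param a,b `hypnogram`s (or label vectors) of equal length.
#' @param classes Label vocabulary (defaults to the union observed).
#' @return List with `accuracy`, `kappa`, and the confusion `table`.
#' @export
kappa_accuracy <- function(a, b, classes = NULL) {
  la <- gather_labels(a)
  lb <- gather_labels(b)
  if (length(la) != length(lb)) stopf("hypnograms must have equal length")
  if (length(la) == 0) stopf("cannot compare empty hypnograms")
  if (is.null(classes)) classes <- union(la, lb)
  tab <- table(factor(la, classes), factor(lb, classes))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  list(accuracy = po, kappa = kappa, table = tab)
}

#' Pooled stage-occupancy percentages
#'
#' Percentage of epochs scored as each stage, pooling all subjects'
#' epochs before averaging (subjects with longer nights weigh more).
#' "pooled_sleep" is everything that is not wake.
#'
#' @param h A `hypnogram` or list of `hypnogram`s.
#' @param classes Stage vocabulary (default the five stages).
#' @return Named numeric vector of percentages (summing to 100), plus a
#'   `pooled_sleep` entry.
#' @export
occupancy <- function(h, classes = sleep_stages()) {
  lab <- gather_labels(h)
  pct <- 100 * as.numeric(table(factor(lab, classes))) / length(lab)
  names(pct) <- classes
  c(pct, pooled_sleep = 100 - unname(pct["W"]))
}

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1) in the McGraw & Wong nomenclature: a two-way model in which
#' both subject and rater are crossed, agreement is absolute (systematic
#' rater offsets count against it), for single measurements. Computed
#' from the two-way ANOVA mean squares.
#'
#' @param x n x k matrix: n subjects rated by k raters/methods.
#' @return Scalar ICC(A,1) in \[-1, 1\].
#' @export
icc_a1 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 raters")
  mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - mu)^2) / (n - 1)            # rows (subjects)
  msc <- n * sum((col_m - mu)^2) / (k - 1)            # columns (raters)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) return(1)
  (msr - mse) / denom
}

#' Compare a sleep statistic between two scoring methods
#'
#' Per-subject paired comparison: two-tailed paired t-test (undefined,
#' with a flag, when the differences have zero variance), ICC(A,1), and
#' the r-squared of the least-squares fit of `b` on `a`. r-squared
#' measures covariation only; ICC(A,1) additionally penalizes systematic
#' offsets, so `b = a + shift` gives r2 = 1 but ICC < 1.
#'
#' @param a,b Numeric vectors of per-subject statistic values (paired,
#'   length >= 3). `NA` pairs are dropped.
#' @return List with `p_value`, `t_undefined` flag, `icc`, `r2`, `n`,
#'   `mean_diff`.
#' @export
group_compare <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stopf("need >= 3 complete pairs")
  d <- b - a
  t_undef <- stats::sd(d) < 1e-12 * max(1, mean(abs(d)))
  p <- if (t_undef) NA_real_ else
    tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
             error = function(e) {
               t_undef <<- TRUE
               NA_real_
             })
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)^2
  list(p_value = p, t_undefined = t_undef, icc = icc_a1(cbind(a, b)),
       r2 = r2, n = length(a), mean_diff = mean(d))
}

#' Full agreement report between two scorers over a cohort
#'
#' Per-subject accuracy and kappa (five-stage and sleep-wake), pooled
#' stage occupancies for both scorers, and group-level comparisons
#' (paired t, ICC(A,1), r-squared) of every sleep statistic.
#'
#' @param ref,test Lists of per-subject `hypnogram`s (same subjects).
#' @return A list of class `"agreement_report"`.
#' @export
agreement_report <- function(ref, test) {
  if (length(ref) != length(test)) stopf("need the same subjects")
  per <- do.call(rbind, lapply(seq_along(ref), function(i) {
    k5 <- kappa_accuracy(ref[[i]], test[[i]])
    k2 <- kappa_accuracy(collapse_sleep_wake(ref[[i]]),
                         collapse_sleep_wake(test[[i]]))
    data.frame(subject = i, accuracy = k5$accuracy, kappa = k5$kappa,
               accuracy_sw = k2$accuracy, kappa_sw = k2$kappa)
  }))
  stats_of <- function(hs, f) vapply(hs, function(h) {
    v <- sleep_stats(h)[[f]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  stat_names <- c("total_sleep_min", "sleep_efficiency", "waso_min",
                  "sol_min", "rem_latency_min")
  comparisons <- lapply(stat_names, function(s) {
    va <- stats_of(ref, s); vb <- stats_of(test, s)
    if (sum(is.finite(va) & is.finite(vb)) < 3) return(NULL)
    group_compare(va, vb)
  })
  names(comparisons) <- stat_names
  structure(list(per_subject = per,
                 occupancy_ref = occupancy(ref),
                 occupancy_test = occupancy(test),
                 comparisons = comparisons),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n  per-subject mean: ")
  cat(sprintf("accuracy %.3f, kappa %.3f (sleep-wake kappa %.3f)\n",
              mean(x$per_subject$accuracy), mean(x$per_subject$kappa),
              mean(x$per_subject$kappa_sw)))
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    if (is.null(cc)) next
    cat(sprintf("  %s: ICC(A,1) %.3f, r2 %.3f, paired-t p %s\n", nm,
                cc$icc, cc$r2,
                if (cc$t_undefined) "undefined" else sprintf("%.3g", cc$p_value)))
  }
  invisible(x)
}
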