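test_that("sleep statistics follow their definitions", {
  st <- sleep_stats(hypnogram(c("W", "W", "N2", "N2", "W", "N2", "W", "W")))
  expect_equal(st$total_sleep_min, 1.5)
  expect_equal(st$sleep_efficiency, 0.375)
  expect_equal(st$sol_min, 1.0)
  expect_equal(st$waso_min, 0.5)
  expect_true(is.na(st$rem_latency_min))

  # all asleep
  st <- sleep_stats(hypnogram(rep("N2", 100)))
  expect_equal(st$sleep_efficiency, 1)
  expect_equal(st$sol_min, 0)
  expect_equal(st$waso_min, 0)

  # all wake
  st <- sleep_stats(hypnogram(rep("W", 40)))
  expect_equal(st$total_sleep_min, 0)
  expect_equal(st$sleep_efficiency, 0)
  expect_equal(st$sol_min, 20)
  expect_equal(st$waso_min, 0)

  # REM latency measured from sleep onset
  lab <- c(rep("W", 10), rep("N2", 40), "REM", rep("N2", 9))
  expect_equal(sleep_stats(hypnogram(lab))$rem_latency_min, 20)

  # internal identity
  set.seed(19)
  for (s in 1:5) {
    h <- sample_hypnogram(200, seed = s)
    st <- sleep_stats(h)
    expect_equal(st$total_sleep_min,
                 st$sleep_efficiency * st$duration_min, tolerance = 1e-12)
  }
})

test_that("kappa and accuracy match hand-computed confusion matrices", {
  # identical hypnograms
  h <- hypnogram(c("W", "N2", "N2", "REM"))
  ka <- kappa_accuracy(h, h)
  expect_equal(ka$accuracy, 1)
  expect_equal(ka$kappa, 1)

  # confusion [[45,5],[10,40]]: accuracy 0.85, kappa 0.70
  a <- c(rep("W", 50), rep("S", 50))
  b <- c(rep("W", 45), rep("S", 5), rep("W", 10), rep("S", 40))
  ka <- kappa_accuracy(hypnogram(a), hypnogram(b))
  expect_equal(ka$accuracy, 0.85)
  expect_equal(ka$kappa, 0.70)

  # one constant scorer: kappa 0
  ka <- kappa_accuracy(hypnogram(a), hypnogram(rep("W", 100)))
  expect_equal(ka$kappa, 0)

  expect_error(kappa_accuracy(hypnogram("W"), hypnogram(c("W", "W"))),
               "equal length")
})

test_that("kappa agrees with a brute-force oracle on random pairs", {
  set.seed(33)
  stages <- sleep_stages()
  for (i in 1:300) {
    n <- sample(5:60, 1)
    a <- sample(stages, n, replace = TRUE)
    b <- if (runif(1) < 0.3) a else sample(stages, n, replace = TRUE)
    ka <- kappa_accuracy(hypnogram(a), hypnogram(b))
    # oracle: count agreements and marginal products directly
    po <- sum(a == b) / n
    pe <- 0
    for (s1 in stages) pe <- pe + sum(a == s1) * sum(b == s1) / n^2
    kap <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
    expect_equal(ka$accuracy, po, tolerance = 1e-12)
    expect_equal(ka$kappa, kap, tolerance = 1e-12)
  }
})

test_that("kappa is invariant under simultaneous relabelling", {
  set.seed(44)
  a <- sample(sleep_stages(), 200, TRUE)
  b <- sample(sleep_stages(), 200, TRUE)
  perm <- c(W = "N3", N1 = "REM", N2 = "W", N3 = "N1", REM = "N2")
  k1 <- kappa_accuracy(hypnogram(a), hypnogram(b))$kappa
  k2 <- kappa_accuracy(hypnogram(unname(perm[a])),
                       hypnogram(unname(perm[b])))$kappa
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("occupancy pools epochs before averaging", {
  h <- hypnogram(c(rep("W", 50), rep("N2", 50)))
  oc <- occupancy(h)
  expect_equal(unname(oc["W"]), 50)
  expect_equal(unname(oc["N2"]), 50)
  expect_equal(unname(oc["pooled_sleep"]), 50)

  # two subjects with 100 and 300 epochs: weights 1/4 and 3/4
  h1 <- hypnogram(rep("W", 100))
  h2 <- hypnogram(rep("N2", 300))
  oc <- occupancy(list(h1, h2))
  expect_equal(unname(oc["W"]), 25)
  expect_equal(unname(oc["N2"]), 75)
  expect_equal(unname(oc["N3"]), 0)
})

test_that("ICC(A,1) distinguishes agreement from correlation", {
  a <- c(3, 7, 1, 9, 4, 6, 2, 8, 5, 10)

  # identical vectors: perfect agreement; t-test undefined
  gc <- group_compare(a, a)
  expect_equal(gc$icc, 1)
  expect_equal(gc$r2, 1)
  expect_true(gc$t_undefined)

  # exact additive shift: r2 = 1, ICC < 1, zero-variance differences
  # make the t-test undefined
  set.seed(3)
  big_a <- rnorm(200)
  gc <- group_compare(big_a, big_a + 2)
  expect_equal(gc$r2, 1, tolerance = 1e-9)
  expect_lt(gc$icc, 0.6)
  expect_true(gc$t_undefined)

  # near-exact shift: t-test defined and highly significant
  gc <- group_compare(big_a, big_a + 2 + rnorm(200, sd = 0.01))
  expect_equal(gc$r2, 1, tolerance = 1e-3)
  expect_lt(gc$icc, 0.6)
  expect_lt(gc$p_value, 1e-6)

  # independent pairs: ICC near 0
  set.seed(5)
  gc <- group_compare(rnorm(1000), rnorm(1000))
  expect_lt(abs(gc$icc), 0.1)

  expect_error(group_compare(1:2, 2:3), ">= 3")
})

test_that("ICC(A,1) matches the variance-component formula on a fixture", {
  # direct two-way ANOVA computation, independently coded
  set.seed(9)
  n <- 30
  subj <- rnorm(n, sd = 2)
  x <- cbind(subj + rnorm(n, sd = 0.5), subj + 1 + rnorm(n, sd = 0.5))
  k <- 2
  mu <- mean(x)
  msr <- k * sum((rowMeans(x) - mu)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - mu)^2) / (k - 1)
  # residual SS computed straightforwardly, cell by cell
  res <- x
  for (i in 1:n) for (j in 1:k)
    res[i, j] <- x[i, j] - rowMeans(x)[i] - colMeans(x)[j] + mu
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(icc_a1(x), expected, tolerance = 1e-12)
})

test_that("agreement reports aggregate cohorts", {
  set.seed(71)
  truth <- lapply(1:4, function(i) sample_hypnogram(150, seed = 70 + i))
  noisy <- lapply(truth, function(h) {
    lab <- h$labels
    flip <- sample(length(lab), 15)
    lab[flip] <- sample(sleep_stages(), 15, replace = TRUE)
    hypnogram(lab)
  })
  rep <- agreement_report(truth, noisy)
  expect_equal(nrow(rep$per_subject), 4)
  expect_true(all(rep$per_subject$kappa > 0.7))
  expect_true(abs(sum(rep$occupancy_ref[sleep_stages()]) - 100) < 1e-9)
  gc <- rep$comparisons$total_sleep_min
  expect_true(is.null(gc) || gc$icc > 0.5)
})
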