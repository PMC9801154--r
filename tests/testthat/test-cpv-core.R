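test_that("variability index matches the hand-worked alternating series", {
  res <- variability_index(c(0, 1, 0, 1, 0))
  # d = (1,-1,1,-1): raw second moment 1, centered 4/3, T = 12/28
  expect_equal(res$T, 3 / 7, tolerance = 1e-15)
  expect_equal(res$sigma0_sq, 1)
  expect_equal(res$sigma1_sq, 4 / 3)
  expect_equal(res$mean_diff, 0)
  expect_equal(res$n_used, 5L)
  expect_identical(res$status, "ok")
})

test_that("degenerate series are flagged, not scored", {
  const <- variability_index(c(5, 5, 5, 5))
  expect_identical(const$status, "constant")
  expect_true(is.na(const$T))
  expect_identical(variability_index(c(1, 2))$status, "insufficient")
  expect_true(is.na(cpv_univariate(c(1, 2))$cpv))
  # missing values reduce to the retained subsequence
  with_na <- variability_index(c(1, NA, 4, 9, NA, 2))
  expect_equal(with_na$T, variability_index(c(1, 4, 9, 2))$T)
  expect_equal(with_na$n_used, 4L)
})

test_that("a perfect ramp forces T = 1 and a capped score", {
  res <- cpv_univariate(c(1, 2, 3, 4, 5))
  expect_equal(res$T, 1)
  expect_equal(res$cpv, cpv_cap())
  expect_true(res$capped)
  expect_identical(cpv_univariate(c(3, 3, 3, 3))$cpv, 0)
})

test_that("T is invariant under affine transforms of the series", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1))
    a <- runif(1, -5, 5)
    if (a == 0) a <- 1
    b <- runif(1, -100, 100)
    t1 <- variability_index(x)$T
    t2 <- variability_index(a * x + b)$T
    if (is.na(t1)) expect_true(is.na(t2)) else {
      expect_equal(t2, t1, tolerance = 1e-9)
    }
    expect_true(is.na(t1) || (t1 >= 0 && t1 <= 1))
  }
})

test_that("closed-form T agrees with a term-by-term computation", {
  set.seed(12)
  for (i in 1:200) {
    x <- rnorm(sample(5:12, 1), sd = runif(1, 0.1, 10))
    expect_equal(variability_index(x)$T, brute_force_T(x),
                 tolerance = 1e-12)
  }
})

test_that("cpv equals the incomplete-beta quadrature oracle", {
  x <- c(0, 1, 0, 1, 0)
  res <- cpv_univariate(x)
  a <- (5 - 1) / 2
  b <- (5 - 2) / 2
  f <- function(t) t^(a - 1) * (1 - t)^(b - 1)
  num <- stats::integrate(f, 0, res$T, rel.tol = 1e-12)$value
  den <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  expect_equal(res$cpv, -log(1 - num / den), tolerance = 1e-8)
  # unhalved (prose) variant uses shape parameters N-1, N-2
  res2 <- cpv_univariate(x, shape = "unhalved")
  expect_equal(res2$cpv,
               -stats::pbeta(3 / 7, 4, 3, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-12)
})

test_that("cpv is strictly increasing in T at fixed series length", {
  n <- 8
  ts <- seq(0.05, 0.95, by = 0.05)
  cpvs <- -stats::pbeta(ts, (n - 1) / 2, (n - 2) / 2, lower.tail = FALSE,
                        log.p = TRUE)
  expect_true(all(diff(cpvs) > 0))
  expect_true(all(exp(-cpvs) > 0 & exp(-cpvs) <= 1))
})

test_that("exact null tail matches simulation for Gaussian increments", {
  set.seed(13)
  n_sessions <- 10
  sims <- replicate(3000, {
    variability_index(cumsum(c(0, rnorm(n_sessions - 1))))$T
  })
  b <- rbeta(3000, 0.5, (n_sessions - 2) / 2)
  n <- n_sessions - 1
  transformed <- (n - 1) / (2 * n - 1 - n * b)
  ks <- suppressWarnings(stats::ks.test(sims, transformed))
  expect_gt(ks$p.value, 0.001)
  # and cpv_exact_pvalue is a valid tail: monotone nonincreasing, in [0,1]
  p <- cpv_exact_pvalue(seq(0.4, 0.999, by = 0.01), n_used = n_sessions)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("anova oracle handles boundaries and matches a direct F computation", {
  expect_true(is.na(anova_oracle(c(2, 2, 2, 2))))
  x <- c(1.4, 0.2, 3.1, 2.8, 0.9, 1.7)
  n <- length(x)
  # direct sums: within-group SS of consecutive pairs is sum(d^2)/2
  d <- diff(x)
  ssw <- sum(d^2) / 2
  means <- (x[-n] + x[-1]) / 2
  ssb <- 2 * sum((means - mean(rep(means, each = 2)))^2)
  f <- (ssb / (n - 2)) / (ssw / (n - 1))
  expect_equal(anova_oracle(x),
               stats::pf(f, n - 2, n - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # ramp: near-zero within-pair residual spread relative to between
  expect_lt(anova_oracle(seq_len(20)), 0.05)
})
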