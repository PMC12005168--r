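test_that("Poisson-limit NB fits reproduce closed forms", {
  set.seed(1)
  y <- rpois(12, 40)
  f <- fit_nb_glm(y, matrix(1, 12, 1), dispersion = 0)
  expect_equal(unname(f$coefficients), log(mean(y)), tolerance = 1e-8)
  g <- rep(0:1, each = 6)
  y2 <- c(rpois(6, 20), rpois(6, 60))
  f2 <- fit_nb_glm(y2, cbind(1, grp = g), dispersion = 0)
  expect_equal(unname(f2$coefficients[2]),
               log(mean(y2[g == 1]) / mean(y2[g == 0])), tolerance = 1e-8)
  expect_true(f2$converged)
  expect_true(all(f2$standard_errors > 0))
  expect_error(fit_nb_glm(y, cbind(rep(1, 12), rep(1, 12)), dispersion = 0),
               "rank deficient")
})

test_that("NB fit agrees with an independent ML implementation at the same dispersion", {
  skip_if_not_installed("MASS")
  set.seed(2)
  x <- rnorm(48)
  y <- rnbinom(48, mu = exp(4 + 0.5 * x), size = 8)
  m <- MASS::glm.nb(y ~ x)
  f <- fit_nb_glm(y, cbind(1, x = x), dispersion = 1 / m$theta)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-6)
  expect_equal(unname(f$standard_errors),
               unname(summary(m)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(f$log_likelihood, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("offsets act as exposure: doubling a size factor halves the fitted rate", {
  set.seed(3)
  y <- rpois(20, 100)
  off <- log(rep(c(1, 2), 10))
  f <- fit_nb_glm(y, matrix(1, 20, 1), dispersion = 0, offset = off)
  # exact ML for Poisson intercept with offset: sum(y) / sum(exp(offset))
  expect_equal(unname(exp(f$coefficients)), sum(y) / sum(exp(off)),
               tolerance = 1e-8)
})

test_that("Wald test matches the normal-quantile identity and flags failures", {
  set.seed(4)
  y <- rnbinom(30, mu = 50, size = 10)
  f <- fit_nb_glm(y, matrix(1, 30, 1), dispersion = 0.1)
  w <- wald_test(f, 1)
  expect_equal(w$p_value, 2 * stats::pnorm(-abs(w$statistic)))
  f0 <- f
  f0$coefficients[1] <- 0
  expect_equal(wald_test(f0, 1)$p_value, 1)
  f0$coefficients[1] <- 1.959964 * f0$standard_errors[1]
  expect_equal(wald_test(f0, 1)$p_value, 0.05, tolerance = 1e-5)
  f_bad <- f
  f_bad$converged <- FALSE
  expect_true(is.na(wald_test(f_bad, 1)$p_value))
})

test_that("LRT recovers the chi-square tail and rejects invalid nesting", {
  set.seed(5)
  y <- rnbinom(48, mu = 80, size = 20)
  X1 <- matrix(1, 48, 1)
  f0 <- fit_nb_glm(y, X1, dispersion = 0.05)
  lr0 <- lrt_test(f0, f0, df = 14)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # chi-square(14) upper 5% point is 23.685 (standard table)
  f_hi <- f0
  f_hi$log_likelihood <- f0$log_likelihood + 23.685 / 2
  expect_equal(lrt_test(f_hi, f0, df = 14)$p_value, 0.05, tolerance = 1e-4)
  f_lo <- f0
  f_lo$log_likelihood <- f0$log_likelihood - 1
  expect_error(lrt_test(f_lo, f0, df = 14), "fitting error")
})

test_that("slope recovery: continuous-day NB GLM estimates a known aging slope", {
  d <- make_design()
  off <- rep(0, 48)
  X <- cbind(1, day = d$day)
  beta <- 0.02
  set.seed(6)
  est <- replicate(300, {
    mu <- exp(4 + beta * d$day)
    y <- rnbinom(48, mu = mu, size = 1 / 0.05)
    unname(fit_nb_glm(y, X, dispersion = 0.05)$coefficients[2])
  })
  expect_lt(abs(mean(est) / beta - 1), 0.10)
})

test_that("dispersion estimation recovers known alpha and flags degenerate genes", {
  d <- make_design()
  X <- matrix(1, 48, 1)
  tr <- make_truth(2000, class_mix = c(null = 1), dispersion = 0.1, seed = 7)
  cts <- simulate_counts(tr, d, seed = 8)
  disp <- estimate_dispersion(cts, size_factors_median_of_ratios(cts), X)
  expect_true(stats::median(disp) > 0.07 && stats::median(disp) < 0.13)
  # Poisson truth with large means: nearly all estimates near zero
  trp <- make_truth(500, class_mix = c(null = 1), dispersion = 0,
                    baseline_range = c(200, 2000), seed = 9)
  ctsp <- simulate_counts(trp, d, seed = 10)
  dispp <- estimate_dispersion(ctsp, size_factors_median_of_ratios(ctsp), X)
  expect_gte(mean(dispp <= 0.01), 0.95)
  # all-zero gene: floored and flagged
  cts2 <- rbind(ctsp[1:5, ], zero = 0L)
  disp2 <- estimate_dispersion(cts2, size_factors_median_of_ratios(cts2), X)
  expect_equal(unname(disp2["zero"]), 1e-8)
  expect_true(attr(disp2, "flagged")[6])
})

test_that("BH adjustment follows the step-up rule, is monotone, and handles NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
  }
  p_na <- c(0.01, NA, 0.04)
  adj_na <- bh_adjust(p_na)
  expect_true(is.na(adj_na[2]))
  expect_equal(adj_na[c(1, 3)], stats::p.adjust(p_na, method = "BH")[c(1, 3)])
  expect_error(bh_adjust(c(0.5, 1.2)), "input error")
})

test_that("median-of-ratios size factors match hand computation and recover simulated depth", {
  expect_equal(size_factors_median_of_ratios(cbind(a = c(5L, 9L, 13L),
                                                   b = c(5L, 9L, 13L))),
               c(a = 1, b = 1))
  m <- rbind(c(10, 20), c(100, 200), c(4, 8))
  expect_equal(unname(size_factors_median_of_ratios(m)),
               c(1 / sqrt(2), sqrt(2)))
  sim <- sim_cohort(n_genes = 2000, class_mix = c(null = 1), seed = 12)
  sf <- size_factors_median_of_ratios(sim$counts)
  truef <- attr(sim$counts, "size_factors")
  truef <- truef / exp(mean(log(truef)))
  expect_lt(max(abs(sf / truef - 1)), 0.05)
  expect_error(size_factors_median_of_ratios(rbind(c(0L, 1L), c(1L, 0L))),
               "normalization error")
})
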