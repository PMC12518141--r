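test_that("correlation function: white noise decorrelates, uniform fields stay at 1", {
  n <- 128
  set.seed(3)
  f <- director_field(asin(matrix(runif(n * n, -0.5, 0.5), n, n)))
  r <- rejection_and_domains(f)
  cp <- correlation_function(r, "parallel")
  expect_equal(cp$values[1], 1, tolerance = 1e-9)
  far <- cp$values[cp$lags_um > 0]
  npair <- cp$n_pairs[cp$lags_um > 0]
  expect_true(all(abs(far) < 3 / sqrt(npair)))
  # uniform nonzero rejection: C = 1 at all lags
  fu <- director_field(matrix(0.4, 48, 48))
  cu <- correlation_function(rejection_and_domains(fu), "perpendicular")
  expect_true(all(abs(cu$values - 1) < 1e-12))
  expect_equal(cu$plateau, 1)
  # all-zero rejection is flagged
  f0 <- director_field(matrix(0, 48, 48))
  expect_error(correlation_function(rejection_and_domains(f0), "parallel"),
               "all-zero")
})

test_that("correlation function recovers an exponential kernel", {
  n <- 256; lambda <- 10
  dn <- exp_corr_field(n, lambda, seed = 5)
  f <- director_field(asin(pmin(pmax(0.3 * dn, -0.99), 0.99)))
  r <- rejection_and_domains(f)
  for (ax in c("parallel", "perpendicular")) {
    cc <- correlation_function(r, ax)
    lag <- cc$lags_um
    keep <- lag <= 3 * lambda
    expect_lt(max(abs(cc$values[keep] - exp(-lag[keep] / lambda))), 0.15)
    expect_lt(sqrt(mean((cc$values[keep] - exp(-lag[keep] / lambda))^2)), 0.06)
  }
})

test_that("1/e correlation length: closed forms and unavailability", {
  mk <- function(lags, vals) structure(
    list(lags_um = lags, values = vals, n_pairs = rep(100, length(lags)),
         axis = "parallel", plateau = mean(vals[lags >= quantile(lags, 0.75)])),
    class = "correlation_curve")
  lags <- seq(0, 60, by = 1)
  xi <- correlation_length(mk(lags, exp(-lags / 10)))
  expect_true(xi$available)
  expect_equal(xi$xi_um, 10, tolerance = 0.02)
  # linear crossing: C = max(0, 1 - dr/20) crosses 1/e at (1 - 1/e) * 20
  xl <- correlation_length(mk(lags, pmax(0, 1 - lags / 20)))
  expect_equal(xl$xi_um, (1 - exp(-1)) * 20, tolerance = 1e-9)
  # C = 1 everywhere: unavailable, plateau reported
  xc <- correlation_length(mk(lags, rep(1, length(lags))))
  expect_false(xc$available)
  expect_true(is.na(xc$xi_um))
  expect_equal(xc$plateau, 1)
})

test_that("growth exponent: exact power laws, noise robustness, constants", {
  t <- seq(10, 100, length.out = 10)
  g <- growth_exponent(t, 3 * t^0.5)
  expect_equal(g$slope, 0.5, tolerance = 1e-12)
  expect_equal(growth_exponent(t, rep(4, 10))$slope, 0, tolerance = 1e-12)
  # 5% multiplicative noise at 20 points stays in [0.4, 0.6]
  t2 <- seq(5, 200, length.out = 20)
  for (s in 1:5) {
    set.seed(s)
    xi <- 2 * t2^0.5 * (1 + rnorm(20, 0, 0.05))
    gs <- growth_exponent(t2, xi, seed = s)
    expect_gt(gs$slope, 0.4); expect_lt(gs$slope, 0.6)
    expect_lt(gs$ci[1], gs$slope); expect_gt(gs$ci[2], gs$slope)
  }
  expect_error(growth_exponent(t[1:3], (3 * t^0.5)[1:3]), "at least 5")
  expect_error(growth_exponent(t, -3 * t^0.5), "positive")
})

test_that("scaling collapse separates self-similar from dissimilar curve families", {
  mk <- function(lags, vals) structure(
    list(lags_um = lags, values = vals, n_pairs = rep(100, length(lags)),
         axis = "parallel", plateau = 0), class = "correlation_curve")
  lags <- seq(0, 100, by = 0.5)
  c10 <- mk(lags, exp(-lags / 10)); c20 <- mk(lags, exp(-lags / 20))
  err_same <- collapse_error(list(c10, c20), c(10, 20))
  expect_lt(err_same, 1e-4)
  # exponential versus Gaussian decay does not collapse
  cg <- mk(lags, exp(-(lags / 10)^2))
  err_mix <- collapse_error(list(c10, cg), c(10, 10 * sqrt(1)))
  expect_gt(err_mix, 10 * max(err_same, 1e-8))
  expect_equal(collapse_error(list(c10), 10), 0)
  expect_error(collapse_error(list(c10), NA_real_), "no curve")
})

test_that("bootstrap confidence intervals are exact on constants, match the normal closed form, and are reproducible", {
  expect_equal(unname(bootstrap_ci(rep(3.2, 10), seed = 1)), c(3.2, 3.2))
  expect_error(bootstrap_ci(1), "at least 2")
  set.seed(42)
  x <- rnorm(1000)
  ci <- bootstrap_ci(x, n_boot = 1000, level = 0.95, seed = 9)
  width <- ci[["upper"]] - ci[["lower"]]
  expect_equal(width, 2 * 1.96 / sqrt(1000), tolerance = 0.2)
  # same-seed-stream oracle: independent re-implementation of the resampler
  y <- c(0.1, 0.5, 0.9, 4, 7, 0.2, 0.3, 11, 0.4, 2)
  got <- bootstrap_ci(y, n_boot = 200, level = 0.95, seed = 5)
  set.seed(5)
  means <- vapply(1:200, function(b) mean(y[sample.int(10, 10, replace = TRUE)]),
                  numeric(1))
  want <- quantile(means, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(got), want, tolerance = 1e-12)
  # the global RNG stream is left untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(bootstrap_ci(y, n_boot = 50, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("phase boundaries sit at the extrema of the smoothed defect count", {
  times <- 1:15
  counts <- c(40, 30, 22, 12, 10, 8, 10, 14, 25, 24, 26, 18, 9, 4, 0)
  pb <- phase_boundaries(times, counts, window = 3)
  expect_false(is.na(pb$t_min)); expect_false(is.na(pb$t_max))
  expect_lt(pb$t_min, pb$t_max)
  expect_true(pb$t_min >= 4 && pb$t_min <= 8)
  expect_true(pb$t_max >= 9 && pb$t_max <= 12)
})
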