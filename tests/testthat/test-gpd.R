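# Generalized Pareto tail modeling of the permutation null.

test_that("exceedance selection follows the midpoint-threshold rule", {
  exc <- select_exceedances(c(5, 4, 3, 2, 1), 2)
  expect_equal(exc$t, 3.5)
  expect_equal(exc$exceedances, c(1.5, 0.5))

  expect_error(select_exceedances(rep(2, 50), 10), "zero-width")
  expect_error(select_exceedances(1:50, 50), "too large")
  expect_error(select_exceedances(1:50, 1), "at least 2")

  set.seed(40)
  z <- abs(rnorm(1000))
  exc <- select_exceedances(z, 250)
  zs <- sort(z, decreasing = TRUE)
  expect_equal(exc$t, (zs[250] + zs[251]) / 2)   # full-sort oracle
  expect_equal(exc$exceedances, zs[1:250] - exc$t)
  expect_true(all(exc$exceedances > 0))
})

test_that("the GPD CDF matches its closed form, limits and support bound", {
  expect_equal(gpd_cdf(0, 2, 0.3), 0)
  expect_equal(gpd_cdf(0, 2, -0.3), 0)
  expect_equal(gpd_cdf(-1, 1, 0.1), 0)
  # exponential limit
  x <- seq(0.1, 5, by = 0.1)
  expect_lt(max(abs(gpd_cdf(x, 1.3, 1e-12) - (1 - exp(-x / 1.3)))), 1e-6)
  # bounded support for k > 0
  expect_equal(gpd_cdf(2, 1, 0.5), 1)      # x = a/k
  expect_equal(gpd_cdf(5, 1, 0.5), 1)      # beyond support
  # plain plug-in value
  expect_equal(gpd_cdf(1, 1, 0.5), 1 - (1 - 0.5)^2)
  expect_error(gpd_cdf(1, -1, 0.5), "positive")
  # quantile function inverts the CDF
  p <- c(0.1, 0.5, 0.9, 0.99)
  for (k in c(-0.4, 0, 0.25)) {
    expect_equal(gpd_cdf(gpd_quantile(p, 2, k), 2, k), p, tolerance = 1e-10)
  }
})

test_that("ML fitting recovers known parameters", {
  set.seed(41)
  fit <- fit_gpd_ml(rgpd(5000, a = 2, k = 0.25), gof = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 2) / 2, 0.05)
  expect_lt(abs(fit$k - 0.25) / 0.25, 0.25)

  set.seed(42)
  fit0 <- fit_gpd_ml(rexp(2000), gof = FALSE)   # k = 0 truth
  expect_lt(abs(fit0$k), 0.1)
  expect_lt(abs(fit0$a - 1), 0.1)

  # degenerate input: flagged failure, no crash
  expect_false(fit_gpd_ml(rep(1, 50), gof = FALSE)$converged)
})

test_that("Anderson-Darling GOF is calibrated under the true model and powered against a wrong one", {
  set.seed(43)
  reps <- 60
  p_true <- replicate(reps, {
    fit <- fit_gpd_ml(rgpd(250, a = 1, k = 0.1))
    fit$gof_p
  })
  expect_gte(mean(p_true > 0.05, na.rm = TRUE), 0.85)

  # scaled uniform body vs fitted tail family: mostly rejected
  p_wrong <- replicate(reps, {
    x <- c(runif(200, 0, 1), runif(50, 60, 100))   # clearly non-GPD
    fit <- suppressWarnings(fit_gpd_ml(x))         # shape beyond table: clamped
    fit$gof_p
  })
  expect_gte(mean(p_wrong <= 0.05, na.rm = TRUE), 0.7)
})

test_that("fit_tail starts at min(250, n-1), decrements, and terminates", {
  set.seed(44)
  z <- abs(rt(100, df = 50))
  fit <- fit_tail(z)
  if (fit$converged) expect_lte(fit$n_exc, 99L)

  z2 <- abs(rt(10000, df = 100))
  fit2 <- fit_tail(z2)
  expect_true(fit2$converged)
  expect_lte(fit2$n_exc, 250L)
  expect_gt(fit2$gof_p, 0.05)

  # adversarial bimodal tail terminates either way
  set.seed(45)
  z3 <- c(runif(500, 0, 1), runif(500, 10, 10.01))
  expect_no_error(suppressWarnings(fit_tail(z3)))
  expect_error(fit_tail(1:15), "at least 20")
})

test_that("p_gpd is continuous at the threshold and matches the exponential closed form", {
  set.seed(46)
  z <- abs(rnorm(2000))
  fit <- fit_tail(z)
  expect_true(fit$converged)
  eps <- 1e-9
  p_at_t <- p_gpd(fit$t + eps, z, fit)$p_value
  expect_equal(p_at_t, fit$n_exc / length(z), tolerance = 1e-3)
  expect_error(p_gpd(fit$t - 0.01, z, fit), "not in tail")

  # closed-form exponential case: k = 0, a = 1, Nexc/N = 0.025, z-t = ln(100)
  fit_exp <- structure(list(a = 1, k = 0, gof_p = 0.5, n_exc = 25L,
                            t = 2, converged = TRUE, loglik = NA_real_),
                       class = "gpd_fit")
  null_stub <- rep(1, 1000)
  out <- p_gpd(2 + log(100), null_stub, fit_exp)
  expect_equal(out$p_value, 0.025 / 100, tolerance = 1e-12)

  # beyond the k > 0 support bound: exact zero with flag and upper bound
  fit_pos <- structure(list(a = 1, k = 0.5, gof_p = 0.5, n_exc = 25L,
                            t = 2, converged = TRUE, loglik = NA_real_),
                       class = "gpd_fit")
  out2 <- p_gpd(2 + 3, null_stub, fit_pos)   # support bound a/k = 2
  expect_equal(out2$p_value, 0)
  expect_true(out2$beyond_support)
  expect_equal(out2$p_upper_bound, 0.025 * 1e-12)
})

test_that("p_gpd is non-increasing in z over the modeled tail", {
  set.seed(47)
  z <- abs(rnorm(3000))
  fit <- fit_tail(z)
  expect_true(fit$converged)
  hi <- if (fit$k > 0) fit$t + 0.999 * fit$a / fit$k else fit$t + 5
  zs <- seq(fit$t + 1e-6, hi, length.out = 50)
  ps <- vapply(zs, function(zz) p_gpd(zz, z, fit)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("hybrid routing sends only extreme statistics to the GPD path", {
  set.seed(48)
  z0 <- abs(rnorm(1000))
  mid <- quantile(z0, 0.5)                     # M ~ 0.5 * N -> fixed path
  out_mid <- p_hybrid(mid, z0)
  expect_equal(out_mid$p_source, "fixed")

  big <- max(z0) + 1                           # M = 0 -> GPD attempted
  out_big <- p_hybrid(big, z0)
  expect_true(out_big$p_source %in% c("gpd", "gpd_failed"))
  if (out_big$p_source == "gpd") {
    expect_lt(out_big$p_value, 1 / 1001)       # below the empirical floor
    expect_false(is.na(out_big$gof_p))
  }
})
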