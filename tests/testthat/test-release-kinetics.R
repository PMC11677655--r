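test_that("power-law prediction matches direct evaluation", {
  expect_equal(peppas_predict(0.0189, 0.47, 1), 0.0189)
  expect_equal(peppas_predict(0.5, 0.43, 0), 0)
  expect_equal(peppas_predict(0.0189, 0.47, 100), 0.0189 * 100^0.47)
  expect_equal(round(peppas_predict(0.0189, 0.47, 100), 4), 0.1646)
  expect_error(peppas_predict(-1, 0.5, 1),
               class = "nanoaroma_invalid_parameter")

  # strictly increasing in t; scaling t by lambda scales output by
  # lambda^n
  t <- sort(stats::runif(10, 1, 500))
  f <- peppas_predict(0.02, 0.6, t)
  expect_true(all(diff(f) > 0))
  expect_equal(peppas_predict(0.02, 0.6, 3 * t), 3^0.6 * f,
               tolerance = 1e-12)
})

test_that("goodness-of-fit statistics follow their definitions", {
  gof <- goodness_of_fit(c(0, 0.3, 0.5, 1), c(0, 0.3, 0.5, 1))
  expect_equal(gof$r_squared, 1)
  expect_equal(gof$sse, 0)
  expect_equal(gof$rmse, 0)

  gof2 <- goodness_of_fit(c(0, 1, 0.5), c(0, 0.9, 0.5), n_params = 1)
  expect_equal(gof2$sse, 0.01)
  expect_equal(gof2$rmse, sqrt(0.01 / 3))

  # adjusted R2 from the standard formula, and never above R2
  obs <- seq(0.1, 1, length.out = 10)
  pred <- obs + stats::rnorm(10, 0, 0.05)
  g <- goodness_of_fit(obs, pred, n_params = 2)
  expect_equal(g$r_squared_adj,
               1 - (1 - g$r_squared) * 9 / 7, tolerance = 1e-12)
  expect_lte(g$r_squared_adj, g$r_squared)
  expect_equal(1 - (1 - 0.9) * 9 / 7, 0.87142857, tolerance = 1e-6)

  expect_error(goodness_of_fit(c(1, 1, 1, 1), c(1, 1, 1, 1)),
               class = "nanoaroma_undefined_r2")
  expect_error(goodness_of_fit(c(0, 1), c(0, 1)),
               class = "nanoaroma_insufficient_data")

  # RMSE divisor is configurable
  g2 <- goodness_of_fit(c(0, 1, 0.5, 0.2), c(0, 0.9, 0.5, 0.2),
                        n_params = 2, rmse_divisor = "n_minus_p")
  expect_equal(g2$rmse, sqrt(0.01 / 2))
})

test_that("noiseless curves are recovered exactly and match log-log OLS", {
  for (pars in list(c(k = 0.0234, n = 0.45), c(k = 0.0786, n = 0.30),
                    c(k = 0.0189, n = 0.47))) {
    curve <- simulate_release(seed = 1, k = pars[["k"]], n = pars[["n"]],
                              noise_sigma = 0)
    fit <- fit_peppas(curve)
    expect_true(fit$converged)
    expect_equal(fit$k, pars[["k"]], tolerance = 1e-4)
    expect_equal(fit$n, pars[["n"]], tolerance = 1e-4)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }

  # the Nelder-Mead optimum coincides with the closed-form log-log OLS
  # solution on exact power-law data
  t <- exp(seq(log(1), log(2000), length.out = 20))
  f <- 0.0234 * t^0.45
  ols <- stats::lm(log(f) ~ log(t))
  curve <- release_curve(t, pmin(f, 1))
  fit <- fit_peppas(curve)
  expect_equal(fit$k, exp(unname(coef(ols)[1])), tolerance = 1e-6)
  expect_equal(fit$n, unname(coef(ols)[2]), tolerance = 1e-6)
})

test_that("fitting is deterministic and fails cleanly on degenerate data", {
  curve <- simulate_release(seed = 9, noise_sigma = 0.05)
  f1 <- fit_peppas(curve)
  f2 <- fit_peppas(curve)
  expect_identical(c(f1$k, f1$n), c(f2$k, f2$n))

  flat <- release_curve(c(10, 20, 30, 40), rep(0.5, 4))
  expect_error(fit_peppas(flat), class = "nanoaroma_fit_failure")
  two <- release_curve(c(10, 20), c(0.1, 0.2))
  expect_error(fit_peppas(two), class = "nanoaroma_insufficient_data")

  # points at/above the cap are excluded from the fit
  t <- exp(seq(log(1), log(5000), length.out = 25))
  f <- pmin(0.0234 * t^0.6, 1)
  capped <- fit_peppas(release_curve(t, f))
  expect_equal(capped$n_points_used, sum(f < 1 & f > 0))
  expect_equal(capped$n, 0.6, tolerance = 1e-6)
})

test_that("noise degrades parameter recovery gracefully", {
  med_err <- vapply(c(0, 0.02, 0.05), function(sigma) {
    errs <- vapply(1:30, function(s) {
      fit <- fit_peppas(simulate_release(seed = s, k = 0.0234, n = 0.45,
                                         noise_sigma = sigma))
      abs(fit$n - 0.45) / 0.45
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_equal(med_err[1], 0, tolerance = 1e-6)
  expect_true(all(diff(med_err) >= 0))
  expect_lt(med_err[2], 0.10)
})

test_that("plateau normalization estimates the asymptote when absent", {
  t <- c(10, 60, 120, 240, 480, 630, 700, 800)
  v <- c(2, 4, 5.2, 5.9, 6.28, 6.30, 6.31, 6.29)
  curve <- normalize_release(t, v)
  expect_equal(curve$m_infinity_provenance, "plateau-estimated")
  expect_equal(curve$fractions[length(v)],
               v[length(v)] / curve$m_infinity)
  expect_equal(curve$m_infinity, mean(tail(v, 4)), tolerance = 0.02)
  expect_lt(abs(curve$fractions[length(v)] - 1), 0.02)

  forced <- normalize_release(t, v, m_infinity = max(v))
  expect_equal(forced$m_infinity_provenance, "supplied")
  expect_equal(max(forced$fractions), 1)

  expect_error(normalize_release(c(1, 2, 3, 4), c(1, 2, 4, 8)),
               class = "nanoaroma_cannot_normalize")
})

test_that("mechanism classification maps exponents to transport regimes", {
  expect_equal(classify_mechanism(0.43)$label, "Fickian")
  expect_equal(classify_mechanism(0.47)$label, "anomalous (non-Fickian)")
  expect_equal(classify_mechanism(0.45)$label, "anomalous (non-Fickian)")
  expect_equal(classify_mechanism(0.30)$label, "quasi-Fickian/combined")
  expect_equal(classify_mechanism(0.85)$label, "Case II")
  expect_equal(classify_mechanism(0.95)$label, "super Case II")
  expect_equal(classify_mechanism(0.50, geometry = "slab")$label,
               "Fickian")
  expect_error(classify_mechanism(0.5, geometry = "cube"),
               class = "nanoaroma_unsupported_geometry")
  expect_error(classify_mechanism(-0.1),
               class = "nanoaroma_invalid_parameter")
  # the band half-width is a tunable, not a constant
  expect_equal(classify_mechanism(0.45, tolerance = 0.03)$label,
               "Fickian")
})
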