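test_that("moments use the population (divisor-N) convention", {
  expect_equal(
    compute_moments(tiny_series(c(2, 2, 2, 2))),
    list(mean = 2, variance = 0)
  )
  expect_equal(
    compute_moments(tiny_series(c(0, 4))),
    list(mean = 2, variance = 4)
  )
})

test_that("variance equals mean of squares minus squared mean on random records", {
  set.seed(101)
  for (i in 1:10) {
    x <- rexp(sample(10:200, 1))
    mom <- compute_moments(tiny_series(x))
    expect_equal(mom$variance, mean(x^2) - mean(x)^2, tolerance = 1e-12)
  }
})

test_that("fluctuation intensity is variance over squared mean", {
  expect_equal(fluctuation_intensity(2, 4), 1)
  expect_equal(fluctuation_intensity(3, 0), 0)
  expect_equal(fluctuation_intensity(0.5, 1), 4)
  expect_error(fluctuation_intensity(0, 1), "mean <= 0")
  expect_error(fluctuation_intensity(-1, 1), "mean <= 0")
})

test_that("intermittency counts samples at or below the threshold", {
  expect_equal(intermittency_factor(tiny_series(c(1, 2, 3, 4))), 0)
  expect_equal(intermittency_factor(tiny_series(c(0, 0, 1, 1))), 0.5)
  expect_equal(intermittency_factor(tiny_series(c(0.1, 0.1, 1, 1)), 0.1), 0.5)
  expect_error(intermittency_factor(tiny_series(), -1), ">= 0")
})

test_that("autocorrelation matches stats::acf and is 1 at lag zero", {
  set.seed(5)
  x <- rgamma(300, 2, 1)
  s <- concentration_series(x, 0.01)
  cg <- autocorrelation(s, max_lag = 40)
  expect_equal(cg$rho[1], 1)
  expect_equal(
    cg$rho,
    as.numeric(acf(x, lag.max = 40, plot = FALSE, demean = TRUE)$acf),
    tolerance = 1e-10
  )
  expect_error(autocorrelation(tiny_series(c(1, 1, 1, 1))), "zero variance")
})

test_that("autocorrelation of an AR(1) record follows the phi^k closed form", {
  set.seed(13)
  n <- 1e5
  phi <- 0.9
  x <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi, "recursive"))
  x <- x - min(x) # shift to non-negative; correlation is shift-invariant
  cg <- autocorrelation(concentration_series(x, 0.01), max_lag = 25)
  # large-sample sd of r_k for AR(1) stays below ~0.01 at n = 1e5, k <= 20
  for (k in 1:20) {
    expect_lt(abs(cg$rho[k + 1] - phi^k), 0.04)
  }
})

test_that("autocorrelation of independent noise stays in the white-noise band", {
  set.seed(29)
  n <- 1e5
  x <- rexp(n)
  cg <- autocorrelation(concentration_series(x, 0.01), max_lag = 50)
  expect_true(all(abs(cg$rho[-1]) < 4 / sqrt(n)))
})

test_that("integral time scale integrates an exponential correlogram to T", {
  rho <- exp(-(0:1500) * 0.01 / 1)
  tc <- integral_time_scale(rho, dt = 0.01, truncation_rule = "zero_crossing")
  expect_equal(as.numeric(tc), 1, tolerance = 0.01)
  # one_over_e rule truncates at the memory time itself: integral of the
  # exponential up to T is (1 - 1/e) * T
  tc_e <- integral_time_scale(rho, dt = 0.01, truncation_rule = "one_over_e")
  expect_equal(as.numeric(tc_e), 1 - exp(-1), tolerance = 0.02)
})

test_that("integral time scale truncates at the first zero crossing", {
  expect_equal(as.numeric(integral_time_scale(c(1, 0.5, 0, -0.2), dt = 1)), 1)
  # crossing between samples: interpolated zero at the same area
  expect_equal(
    as.numeric(integral_time_scale(c(1, 0.5, -0.5), dt = 1)),
    0.75 + 0.5^2 / (2 * 1)
  )
  # max_lag rule integrates everything, negative lobe included
  expect_equal(
    as.numeric(integral_time_scale(c(1, 0.5, 0, -0.2),
      dt = 1,
      truncation_rule = "max_lag"
    )),
    0.75 + 0.25 - 0.1 # per-segment trapezoids, negative lobe included
  )
})

test_that("uncorrelated correlogram degenerates to dt/2 with a warning", {
  expect_warning(
    tc <- integral_time_scale(c(1, -0.01, 0.002), dt = 0.02),
    "uncorrelated"
  )
  expect_equal(as.numeric(tc), 0.01)
  expect_true(attr(tc, "degenerate"))
})

test_that("correlogram input is validated", {
  expect_error(integral_time_scale(c(0.9, 0.5), dt = 1), "normalised")
  expect_error(integral_time_scale(c(1, 0.5), dt = -1), "positive")
})

test_that("peak windowed concentration enumerates sliding windows", {
  expect_equal(max_averaged_concentration(tiny_series(c(1, 5, 2), 0.01), 0.01), 5)
  expect_equal(max_averaged_concentration(tiny_series(c(1, 5, 2, 0), 1), 2), 3.5)
  expect_equal(max_averaged_concentration(tiny_series(rep(3.3, 10), 1), 4), 3.3)
  expect_error(max_averaged_concentration(tiny_series(), 10), "longer than")
  expect_warning(max_averaged_concentration(tiny_series(c(1, 5, 2, 0), 1), 2.3), "rounded")
})

test_that("peak windowed concentration is non-increasing in the window", {
  set.seed(17)
  s <- concentration_series(rgamma(500, 1.5, 1), dt = 1)
  peaks <- vapply(
    c(1, 2, 5, 10, 50, 200, 500),
    function(w) max_averaged_concentration(s, w), numeric(1)
  )
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("summarize_series populates the full statistics row consistently", {
  set.seed(23)
  ser <- generate_series(generator_spec(
    mean_target = 2, intensity_target = 1.5, t_c_target = 0.3,
    gamma_target = 0.2, dt = 0.01, n_samples = 20000, seed = 23
  ))
  st <- summarize_series(ser)
  expect_false(st$screened)
  expect_equal(st$c_max, max(ser$values))
  expect_equal(st$d_max_obs, st$c_max * st$dt)
  expect_equal(st$intensity, st$variance / st$mean^2, tolerance = 1e-12)
  expect_gte(st$c_max, st$mean)
  expect_gt(st$t_c, 0)
})

test_that("summarize_series screens degenerate records instead of failing", {
  zero <- summarize_series(concentration_series(numeric(100), 0.01))
  expect_true(zero$screened)
  expect_match(zero$screen_reason, "mean")
  const <- summarize_series(concentration_series(rep(2, 100), 0.01))
  expect_true(const$screened)
  expect_match(const$screen_reason, "variance")
  expect_equal(const$intensity, 0)
})

test_that("summarize_campaign skips malformed records and aborts past 50%", {
  good <- replicate(3, tiny_series(c(0, 1, 2, 3)), simplify = FALSE)
  bad <- list(structure(list(), class = "not_a_series"))
  tab <- suppressMessages(summarize_campaign(c(good, bad)))
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "n_failed"), 1)
  expect_error(
    suppressMessages(summarize_campaign(c(good[1], bad, bad))),
    "aborting"
  )
})
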