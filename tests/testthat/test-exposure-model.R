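test_that("predict_dmax evaluates the deterministic model", {
  # beta = 0 collapses to the mean exposure
  p0 <- predict_dmax(2, 1, 0.5, 1, exposure_params(beta = 0, n_exp = 0.3))
  expect_equal(p0$d_max, 2)
  # dtau = t_c kills the power law regardless of n
  for (n_exp in c(0.1, 0.3, 2)) {
    p <- predict_dmax(2, 1.5, 0.7, 0.7, exposure_params(1.3, n_exp))
    expect_equal(p$d_max, 2 * (1 + 1.3 * 1.5) * 0.7, tolerance = 1e-12)
  }
  # direct arithmetic with the field-refined beta
  p <- predict_dmax(1, 1, 1, 0.01, exposure_params(1.72, 0.3))
  expect_equal(p$d_max, 0.01 * (1 + 1.72 * 0.01^-0.3), tolerance = 1e-12)
  expect_equal(p$d_max, 0.0785, tolerance = 1e-3)
  expect_equal(p$c_max_pred * p$dtau, p$d_max, tolerance = 1e-12)
  expect_error(predict_dmax(1, 1, 0, 0.01), "positive")
  expect_error(predict_dmax(1, 1, 1, -1), "positive")
})

test_that("predicted exposure never falls below the mean exposure", {
  set.seed(7)
  for (i in 1:50) {
    m <- runif(1, 0.01, 10)
    dtau <- runif(1, 1e-3, 10)
    p <- predict_dmax(
      m, runif(1, 0, 5), runif(1, 0.01, 5), dtau,
      exposure_params(runif(1, 0, 5), runif(1, 0, 2))
    )
    expect_gte(p$d_max, m * dtau - 1e-12)
  }
})

test_that("predict_dmax is monotone in its parameters", {
  base <- function(beta = 1.5, I = 1, n = 0.3, dtau = 0.01, t_c = 1, m = 1) {
    predict_dmax(m, I, t_c, dtau, exposure_params(beta, n))$d_max
  }
  expect_gt(base(beta = 2), base(beta = 1))
  expect_gt(base(I = 2), base(I = 1))
  expect_gt(base(m = 2), base(m = 1))
  # (dtau/t_c)^(-n) grows with n for dtau < t_c and shrinks for dtau > t_c
  expect_gt(base(n = 0.5, dtau = 0.01, t_c = 1), base(n = 0.3, dtau = 0.01, t_c = 1))
  expect_lt(base(n = 0.5, dtau = 2, t_c = 1), base(n = 0.3, dtau = 2, t_c = 1))
})

test_that("scale_cmax applies the power law and composes", {
  expect_equal(scale_cmax(10, 3600, 3600, 0.3), 10)
  expect_equal(scale_cmax(10, 1, 3600, 0), 10)
  expect_equal(scale_cmax(10, 36, 3600, 0.3), 10 * 100^0.3, tolerance = 1e-12)
  # two-step scaling equals direct scaling
  one_step <- scale_cmax(5, 2, 3600, 0.4)
  two_step <- scale_cmax(scale_cmax(5, 60, 3600, 0.4), 2, 60, 0.4)
  expect_equal(two_step, one_step, tolerance = 1e-12)
  expect_error(scale_cmax(-1, 1, 1, 0.3), "positive")
})

test_that("inversions are exact algebraic inverses of the prediction", {
  set.seed(11)
  for (i in 1:100) {
    m <- runif(1, 0.1, 10)
    I <- runif(1, 0.05, 5)
    t_c <- runif(1, 0.05, 5)
    dtau <- runif(1, 1e-3, 1)
    beta_true <- runif(1, 0.05, 12)
    n_true <- runif(1, 0.02, 3)
    if (abs(dtau - t_c) < 1e-3) next
    c_max_b <- predict_dmax(m, I, t_c, dtau, exposure_params(beta_true, 0.3))$c_max_pred
    expect_equal(
      invert_beta(c_max_b, m, I, dtau, t_c, n_fixed = 0.3), beta_true,
      tolerance = 1e-12
    )
    c_max_n <- predict_dmax(m, I, t_c, dtau, exposure_params(1.5, n_true))$c_max_pred
    expect_equal(
      invert_n(c_max_n, m, I, dtau, t_c, beta_fixed = 1.5), n_true,
      tolerance = 1e-12
    )
  }
})

test_that("inversion arithmetic matches hand-computed values", {
  expect_equal(invert_beta(4.981, 1, 1, 0.01, 1, n_fixed = 0.3),
    (4.981 - 1) / 10^0.6,
    tolerance = 1e-12
  )
  expect_equal(invert_beta(4.981, 1, 1, 0.01, 1, n_fixed = 0.3), 1, tolerance = 1e-4)
  expect_equal(invert_n(1 + 3 * 10^0.6, 1, 2, 0.01, 1, beta_fixed = 1.5),
    0.3,
    tolerance = 1e-12
  )
})

test_that("invalid inversions flag NA rather than raising", {
  # peak at or below the mean: non-positive beta
  expect_true(is.na(invert_beta(1, 1, 1, 0.01, 1)))
  expect_true(is.na(invert_beta(0.5, 1, 1, 0.01, 1)))
  expect_true(is.na(invert_beta(2, 1, 0, 0.01, 1))) # zero intensity
  expect_true(is.na(invert_n(1, 1, 1, 0.01, 1))) # unit log argument edge
  expect_true(is.na(invert_n(2, 1, 1, 1, 1))) # dtau == t_c
  # unit log-argument: c_max = mean (1 + beta I) gives n = 0, still valid
  expect_equal(invert_n(1 + 1.5 * 2, 1, 2, 0.01, 1, beta_fixed = 1.5), 0)
})

test_that("batch inversion accounts for every record", {
  tab <- generate_model_consistent_campaign(200, seed = 42)
  # corrupt a few rows to exercise the exclusion paths
  tab$c_max[1:5] <- tab$mean[1:5] * 0.9 # peak below mean
  tab$screened[6:8] <- TRUE
  out <- invert_parameters(tab)
  expect_equal(nrow(out), 200)
  excl <- attr(out, "exclusions")
  expect_equal(unname(excl["screened"]), 3)
  expect_equal(unname(excl["beta_invalid"]), 5)
  expect_equal(sum(out$beta_valid), 192)
  expect_equal(
    nrow(tab),
    sum(out$screened) + sum(out$beta_valid) + unname(excl["beta_invalid"])
  )
  # valid rows recover the sampled constants exactly
  ok <- out$beta_valid
  expect_lt(max(abs(out$beta[ok] - tab$beta_true[ok])), 1e-10)
})
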