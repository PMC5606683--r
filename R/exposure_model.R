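#' Deterministic exposure-model parameters
#'
#' The peak-to-mean exposure model has two empirical parameters: a
#' proportionality constant `beta` and a power-law exponent `n_exp` linking
#' the peak-to-mean concentration ratio to the normalised averaging time
#' dtau / T_C. The representative values under neutral stability are
#' beta = 1.5 and n = 0.3; the field-refined mean beta is 1.72.
#'
#' @param beta Proportionality constant, > 0.
#' @param n_exp Power-law exponent, > 0.
#' @return An object of class `exposure_params`.
#' @export
exposure_params <- function(beta = 1.5, n_exp = 0.3) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("`beta` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(n_exp) || length(n_exp) != 1L || n_exp < 0) {
    stop("`n_exp` must be a single non-negative number", call. = FALSE)
  }
  structure(list(beta = beta, n_exp = n_exp), class = "exposure_params")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat(sprintf("<exposure_params> beta = %g, n = %g\n", x$beta, x$n_exp))
  invisible(x)
}

#' Predict the expected maximum individual exposure
#'
#' The deterministic model: over an averaging interval `dtau`, the expected
#' maximum exposure is
#' \deqn{D_{max}(\Delta\tau) = \bar{C}\,[1 + \beta I (\Delta\tau/T_C)^{-n}]\,\Delta\tau}
#' where `mean` is the mean concentration, `intensity` the fluctuation
#' intensity and `t_c` the concentration integral time scale. The bracket is
#' always >= 1, so the predicted exposure never falls below the mean
#' exposure `mean * dtau`.
#'
#' @param mean Mean concentration (ug m^-3), > 0.
#' @param intensity Fluctuation intensity I, >= 0.
#' @param t_c Integral time scale (s), > 0.
#' @param dtau Averaging interval (s), > 0.
#' @param params An [exposure_params()] object.
#' @return A list of class `exposure_prediction` with `d_max`
#'   (ug s m^-3), `c_max_pred` (ug m^-3) and `dtau` (s). All numeric
#'   arguments may be vectors of equal length.
#' @examples
#' predict_dmax(mean = 1, intensity = 1, t_c = 1, dtau = 0.01,
#'              params = exposure_params(1.72, 0.3))
#' @export
predict_dmax <- function(mean, intensity, t_c, dtau, params = exposure_params()) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(mean <= 0)) stop("`mean` must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("`intensity` must be non-negative", call. = FALSE)
  if (any(t_c <= 0) || any(dtau <= 0)) {
    stop("`t_c` and `dtau` must be positive time scales", call. = FALSE)
  }
  c_max_pred <- mean * (1 + params$beta * intensity * (dtau / t_c)^(-params$n_exp))
  structure(
    list(d_max = c_max_pred * dtau, c_max_pred = c_max_pred, dtau = dtau),
    class = "exposure_prediction"
  )
}

#' @export
print.exposure_prediction <- function(x, ...) {
  cat(sprintf(
    "<exposure_prediction> dtau = %g s: D_max = %g ug s m^-3 (C_max = %g ug m^-3)\n",
    x$dtau[1L], x$d_max[1L], x$c_max_pred[1L]
  ))
  if (length(x$d_max) > 1L) cat(sprintf("  ... %d predictions\n", length(x$d_max)))
  invisible(x)
}

#' Rescale a peak concentration to another averaging time
#'
#' Power-law scaling of the peak averaged concentration between averaging
#' intervals: `cmax_at_dtau = cmax_ref * (dtau / dt_ref)^(-n_exp)`.
#'
#' @param cmax_ref Reference peak concentration at interval `dt_ref`.
#' @param dtau Target averaging interval (s).
#' @param dt_ref Reference averaging interval (s), e.g. one hour.
#' @param n_exp Power-law exponent, >= 0.
#' @return The peak concentration at `dtau`.
#' @examples
#' scale_cmax(10, dtau = 36, dt_ref = 3600, n_exp = 0.3) # 10 * 100^0.3
#' @export
scale_cmax <- function(cmax_ref, dtau, dt_ref, n_exp) {
  if (any(cmax_ref <= 0) || any(dtau <= 0) || any(dt_ref <= 0)) {
    stop("scales and concentrations must be positive", call. = FALSE)
  }
  cmax_ref * (dtau / dt_ref)^(-n_exp)
}

#' Invert the model for the proportionality constant beta
#'
#' Given an observed peak concentration and the series statistics, solve the
#' deterministic model for beta while holding the exponent fixed at its
#' representative value:
#' \deqn{\beta = \frac{C_{max}(\Delta\tau) - \bar{C}}{\bar{C}\, I\, (\Delta\tau/T_C)^{-n}}}
#'
#' Records with `c_max_obs <= mean` give a non-positive beta and records
#' with zero intensity are undefined; both return `NA` (vectorised) so batch
#' inversion over thousands of sensors proceeds, with exclusions counted by
#' the caller. No upper clamp is applied: extreme inverted values are data,
#' not errors.
#'
#' @param c_max_obs Observed peak concentration at interval `dtau`.
#' @param mean,intensity,t_c Per-series statistics (see [summarize_series()]).
#' @param dtau Averaging interval of the observation (s).
#' @param n_fixed Fixed exponent; default 0.3.
#' @return Numeric vector of inverted beta values (`NA` where excluded).
#' @export
invert_beta <- function(c_max_obs, mean, intensity, dtau, t_c, n_fixed = 0.3) {
  out <- (c_max_obs - mean) / (mean * intensity * (dtau / t_c)^(-n_fixed))
  out[!is.finite(out) | c_max_obs <= mean | intensity <= 0 | mean <= 0] <- NA_real_
  out
}

#' Invert the model for the exponent n
#'
#' Solve the deterministic model for the power-law exponent while holding
#' beta fixed at its representative value:
#' \deqn{n = -\ln\!\left[\frac{C_{max}(\Delta\tau) - \bar{C}}{\bar{C}\,\beta\, I}\right] \Big/ \ln(\Delta\tau / T_C)}
#'
#' Undefined when the log argument is non-positive (`c_max_obs <= mean`) or
#' when `dtau == t_c`; such records return `NA`.
#'
#' @inheritParams invert_beta
#' @param beta_fixed Fixed proportionality constant; default 1.5.
#' @return Numeric vector of inverted exponents (`NA` where excluded).
#' @export
invert_n <- function(c_max_obs, mean, intensity, dtau, t_c, beta_fixed = 1.5) {
  arg <- (c_max_obs - mean) / (mean * beta_fixed * intensity)
  denom <- log(dtau / t_c)
  out <- suppressWarnings(-log(arg) / denom) # negative args flagged NA below
  out[!is.finite(out) | arg <= 0 | denom == 0 | intensity <= 0 | mean <= 0] <- NA_real_
  out
}

#' Batch parameter inversion over a statistics table
#'
#' Applies [invert_beta()] and [invert_n()] to every non-screened row of a
#' per-series statistics table (from [summarize_campaign()] or the synthetic
#' campaign generators), flagging exclusions.
#'
#' @param stats_table Data frame with columns `mean`, `intensity`, `t_c`,
#'   `c_max`, `dt` (and optionally `trial_id`, `sensor_id`, `screened`).
#' @param n_fixed,beta_fixed Fixed representative values used by the two
#'   single-parameter inversions.
#' @return A data frame with per-record `beta`, `n`, logical validity flags
#'   and an `exclusions` attribute counting screened and invalid records.
#' @export
invert_parameters <- function(stats_table, n_fixed = 0.3, beta_fixed = 1.5) {
  needed <- c("mean", "intensity", "t_c", "c_max", "dt")
  missing_cols <- setdiff(needed, names(stats_table))
  if (length(missing_cols)) {
    stop("stats_table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  screened <- if ("screened" %in% names(stats_table)) {
    stats_table$screened | !is.finite(stats_table$t_c)
  } else {
    !is.finite(stats_table$t_c) | stats_table$mean <= 0 | stats_table$intensity <= 0
  }
  out <- data.frame(
    trial_id = if ("trial_id" %in% names(stats_table)) stats_table$trial_id else NA_character_,
    sensor_id = if ("sensor_id" %in% names(stats_table)) stats_table$sensor_id else NA_character_,
    beta = NA_real_,
    n = NA_real_,
    screened = screened,
    stringsAsFactors = FALSE
  )
  ok <- !screened
  out$beta[ok] <- invert_beta(
    stats_table$c_max[ok], stats_table$mean[ok], stats_table$intensity[ok],
    stats_table$dt[ok], stats_table$t_c[ok],
    n_fixed = n_fixed
  )
  out$n[ok] <- invert_n(
    stats_table$c_max[ok], stats_table$mean[ok], stats_table$intensity[ok],
    stats_table$dt[ok], stats_table$t_c[ok],
    beta_fixed = beta_fixed
  )
  out$beta_valid <- !is.na(out$beta)
  out$n_valid <- !is.na(out$n)
  attr(out, "exclusions") <- c(
    screened = sum(screened),
    beta_invalid = sum(ok & !out$beta_valid),
    n_invalid = sum(ok & !out$n_valid)
  )
  out
}
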