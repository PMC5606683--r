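#' Fraction of predictions within a factor of k
#'
#' The factor-of-k metric over paired predictions and observations: the
#' fraction of pairs whose ratio lies in `[1/k, k]`, both bounds inclusive.
#' `fac_k(..., k = 2)` is the FAC2 metric and `k = 5` the FAC5 metric of
#' air-quality model evaluation. The membership band is symmetric in the
#' ratio, so the metric is unchanged if predictions and observations are
#' swapped.
#'
#' @param predictions,observations Equal-length positive numeric vectors.
#' @param k Factor, > 1.
#' @return The fraction in \[0, 1\].
#' @examples
#' fac_k(c(1, 3, 0.4), c(1, 1, 1), k = 2) # 2/3
#' @export
fac_k <- function(predictions, observations, k) {
  if (length(predictions) != length(observations)) {
    stop("`predictions` and `observations` must have equal length", call. = FALSE)
  }
  if (!length(predictions)) stop("no pairs supplied", call. = FALSE)
  if (any(!is.finite(predictions)) || any(!is.finite(observations)) ||
    any(predictions <= 0) || any(observations <= 0)) {
    stop("pairs must be positive and finite; pre-screen invalid pairs", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 1) {
    stop("`k` must be a single factor > 1", call. = FALSE)
  }
  r <- predictions / observations
  mean(r >= 1 / k & r <= k)
}

#' Validate model predictions against observed maximum exposures
#'
#' For each non-screened row of a per-series statistics table, predicts the
#' maximum exposure from the row's (mean, intensity, T_C) at the row's own
#' measurement interval, pairs it with the observed maximum exposure
#' `d_max_obs = c_max * dt`, and reports FAC2 and FAC5 with counts. Because
#' both sides of each pair share the factor `dt`, the metrics computed on
#' exposures equal those computed on peak concentrations.
#'
#' Pairs where either side is non-positive or missing are dropped and
#' counted, not raised: field campaigns contain screened-out sensors.
#'
#' @param stats_table Data frame with columns `mean`, `intensity`, `t_c`,
#'   `dt`, `d_max_obs` (see [summarize_campaign()]).
#' @param params An [exposure_params()] object used for prediction,
#'   typically `exposure_params(1.72, 0.3)`.
#' @return An object of class `validation_report`: list with `fac2`, `fac5`,
#'   `n_pairs`, `n_within2`, `n_within5`, `n_dropped` and a `pairs` data
#'   frame (predicted, observed, ratio, membership flags).
#' @export
build_validation <- function(stats_table, params = exposure_params(1.72, 0.3)) {
  needed <- c("mean", "intensity", "t_c", "dt", "d_max_obs")
  missing_cols <- setdiff(needed, names(stats_table))
  if (length(missing_cols)) {
    stop("stats_table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  screened <- if ("screened" %in% names(stats_table)) stats_table$screened else FALSE
  ok <- !screened &
    is.finite(stats_table$mean) & stats_table$mean > 0 &
    is.finite(stats_table$intensity) &
    is.finite(stats_table$t_c) & stats_table$t_c > 0 &
    is.finite(stats_table$d_max_obs) & stats_table$d_max_obs > 0
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no valid prediction/observation pairs", call. = FALSE)
  tab <- stats_table[ok, , drop = FALSE]

  pred <- predict_dmax(tab$mean, tab$intensity, tab$t_c, tab$dt, params = params)
  ratio <- pred$d_max / tab$d_max_obs
  within2 <- ratio >= 0.5 & ratio <= 2
  within5 <- ratio >= 0.2 & ratio <= 5

  pairs <- data.frame(
    trial_id = if ("trial_id" %in% names(tab)) tab$trial_id else NA_character_,
    sensor_id = if ("sensor_id" %in% names(tab)) tab$sensor_id else NA_character_,
    predicted = pred$d_max,
    observed = tab$d_max_obs,
    ratio = ratio,
    within2 = within2,
    within5 = within5,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      fac2 = mean(within2), fac5 = mean(within5),
      n_pairs = nrow(pairs),
      n_within2 = sum(within2), n_within5 = sum(within5),
      n_dropped = n_dropped,
      params = params,
      pairs = pairs
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> predicted vs observed maximum exposure\n")
  cat(sprintf(
    "  model: beta = %g, n = %g; %d pairs (%d dropped)\n",
    x$params$beta, x$params$n_exp, x$n_pairs, x$n_dropped
  ))
  cat(sprintf(
    "  FAC2 = %.1f%% (%d/%d), FAC5 = %.1f%% (%d/%d)\n",
    100 * x$fac2, x$n_within2, x$n_pairs,
    100 * x$fac5, x$n_within5, x$n_pairs
  ))
  invisible(x)
}
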