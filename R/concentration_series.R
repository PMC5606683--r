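#' Construct a concentration time series
#'
#' A `concentration_series` is a uniformly sampled record of scalar
#' concentration (micrograms per cubic metre) at a fixed sampling interval
#' `dt` (seconds), tagged with the trial and sensor it came from. It is the
#' raw input of every downstream statistic.
#'
#' @param values Numeric vector of concentration samples (ug m^-3). Must be
#'   finite, non-negative and of length at least 2.
#' @param dt Sampling interval in seconds; strictly positive.
#' @param trial_id,sensor_id Character labels identifying the record.
#'
#' @return An object of class `concentration_series`: a list with elements
#'   `values`, `dt`, `trial_id`, `sensor_id`.
#' @examples
#' s <- concentration_series(c(0, 1.2, 0.8, 0), dt = 0.01)
#' length(s$values)
#' @export
concentration_series <- function(values, dt, trial_id = "trial", sensor_id = "sensor") {
  if (!is.numeric(values) || length(values) < 2) {
    stop("`values` must be a numeric vector with at least 2 samples", call. = FALSE)
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  structure(
    list(
      values = values,
      dt = as.numeric(dt),
      trial_id = as.character(trial_id)[1L],
      sensor_id = as.character(sensor_id)[1L]
    ),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf(
    "<concentration_series> %s/%s: %d samples @ dt = %g s (%.4g s record)\n",
    x$trial_id, x$sensor_id, length(x$values), x$dt, length(x$values) * x$dt
  ))
  cat(sprintf(
    "  mean = %.4g, max = %.4g ug m^-3\n",
    mean(x$values), max(x$values)
  ))
  invisible(x)
}

is_concentration_series <- function(x) inherits(x, "concentration_series")

assert_series <- function(series) {
  if (!is_concentration_series(series)) {
    stop("expected a `concentration_series` object", call. = FALSE)
  }
  invisible(series)
}
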