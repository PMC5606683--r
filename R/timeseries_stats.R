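#' Mean and variance of a concentration record
#'
#' Population-convention moments: the variance is the mean squared deviation
#' with divisor N, consistent with the definition of the fluctuation
#' intensity as a ratio of population moments.
#'
#' @param series A [concentration_series()].
#' @return A list with elements `mean` (ug m^-3) and `variance` (ug^2 m^-6).
#' @examples
#' compute_moments(concentration_series(c(0, 4), dt = 0.01)) # mean 2, var 4
#' @export
compute_moments <- function(series) {
  assert_series(series)
  x <- series$values
  m <- mean(x)
  list(mean = m, variance = mean((x - m)^2))
}

#' Concentration fluctuation intensity
#'
#' The dimensionless ratio of concentration variance to squared mean,
#' I = var(C) / mean(C)^2, the standard measure of turbulent scatter of a
#' dispersing plume.
#'
#' @param mean Mean concentration; must be positive.
#' @param variance Concentration variance; non-negative.
#' @return The intensity I (dimensionless).
#' @export
fluctuation_intensity <- function(mean, variance) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("fluctuation intensity undefined for mean <= 0; screen such records out",
      call. = FALSE
    )
  }
  if (any(variance < 0)) stop("variance must be non-negative", call. = FALSE)
  variance / mean^2
}

#' Intermittency factor of a concentration record
#'
#' Fraction of samples at or below `zero_threshold`, reflecting the on/off
#' passage of the plume over the sensor. The default threshold is exactly
#' zero; field instruments with a noise floor may need a small positive one.
#'
#' @inheritParams compute_moments
#' @param zero_threshold Non-negative concentration below or at which a
#'   sample counts as "zero".
#' @return The intermittency factor, a fraction in \[0, 1\].
#' @export
intermittency_factor <- function(series, zero_threshold = 0) {
  assert_series(series)
  if (!is.numeric(zero_threshold) || zero_threshold < 0) {
    stop("`zero_threshold` must be >= 0", call. = FALSE)
  }
  mean(series$values <= zero_threshold)
}

#' Sample autocorrelation of a concentration record
#'
#' Biased sample autocorrelation of the mean-removed signal, normalised so
#' the lag-0 value is exactly 1. Computed with an FFT so that long records
#' (10^6 samples) with thousands of lags remain cheap; on short series it
#' agrees with `stats::acf` to machine precision.
#'
#' @inheritParams compute_moments
#' @param max_lag Largest lag (in samples) to compute; must be below the
#'   record length. Defaults to `min(n - 1, 10000)`.
#' @return An object of class `correlogram`: a list with `rho` (values at
#'   lags `0:max_lag`), `lag_s` (lag times in seconds) and `dt`.
#' @export
autocorrelation <- function(series, max_lag = NULL) {
  assert_series(series)
  x <- series$values
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 10000L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n) {
    stop("`max_lag` must be in [1, length(series) - 1]", call. = FALSE)
  }
  x <- x - mean(x)
  if (sum(x^2) == 0) {
    stop("degenerate series: zero variance, autocorrelation undefined", call. = FALSE)
  }
  # circular convolution of the zero-padded signal gives the linear
  # autocovariance sums; dividing by the lag-0 sum yields the biased
  # (divisor-N) normalised correlogram
  m <- stats::nextn(n + max_lag)
  f <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L)]
  rho <- ac / ac[1L]
  rho[1L] <- 1
  structure(
    list(rho = rho, lag_s = (0:max_lag) * series$dt, dt = series$dt),
    class = "correlogram"
  )
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "<correlogram> %d lags @ dt = %g s; rho[1] = %.4f\n",
    length(x$rho) - 1L, x$dt, x$rho[2L]
  ))
  invisible(x)
}

#' Integral time scale of concentration
#'
#' The memory time of the concentration signal: the integral of the
#' autocorrelation coefficient over lag time. The infinite upper limit of the
#' defining integral is unrealisable on a sample correlogram, so the
#' trapezoidal integration is truncated:
#'
#' * `"zero_crossing"` (default, standard turbulence practice): integrate up
#'   to the first non-positive correlogram value, ending the last trapezoid
#'   at the linearly interpolated zero crossing;
#' * `"one_over_e"`: integrate up to the first lag where the correlogram
#'   drops below 1/e;
#' * `"max_lag"`: integrate the whole supplied correlogram.
#'
#' If the correlogram is never positive beyond lag 0 under the chosen rule
#' the signal is effectively uncorrelated at the sampling resolution; the
#' half-interval `dt / 2` is returned with a warning and a `degenerate`
#' attribute.
#'
#' @param correlogram A `correlogram` object from [autocorrelation()], or a
#'   plain numeric vector of correlation values at lags `0, 1, 2, ...`
#'   (first element must be 1).
#' @param dt Sampling interval in seconds; taken from the correlogram object
#'   when omitted.
#' @param truncation_rule One of `"zero_crossing"`, `"one_over_e"`,
#'   `"max_lag"`.
#' @return The integral time scale T_C in seconds, with attribute
#'   `degenerate` (logical) and `n_lags_used`.
#' @examples
#' integral_time_scale(c(1, 0.5, 0, -0.2), dt = 1) # trapezoid over 1, 0.5, 0 -> 1 s
#' @export
integral_time_scale <- function(correlogram, dt = NULL,
                                truncation_rule = c("zero_crossing", "one_over_e", "max_lag")) {
  truncation_rule <- match.arg(truncation_rule)
  if (inherits(correlogram, "correlogram")) {
    rho <- correlogram$rho
    if (is.null(dt)) dt <- correlogram$dt
  } else {
    rho <- as.numeric(correlogram)
  }
  if (is.null(dt) || !is.numeric(dt) || dt <= 0) {
    stop("`dt` must be a positive sampling interval in seconds", call. = FALSE)
  }
  if (length(rho) < 2L) stop("correlogram needs at least lags 0 and 1", call. = FALSE)
  if (abs(rho[1L] - 1) > 1e-8) {
    stop("correlogram must be normalised: value at lag 0 must be 1", call. = FALSE)
  }

  trapz <- function(y) dt * (sum(y) - (y[1L] + y[length(y)]) / 2)

  if (truncation_rule == "max_lag") {
    tc <- trapz(rho)
    return(structure(max(tc, 0), degenerate = FALSE, n_lags_used = length(rho) - 1L))
  }

  if (truncation_rule == "one_over_e") {
    below <- which(rho < exp(-1))
    k <- if (length(below)) below[1L] else length(rho)
    if (k <= 2L && rho[2L] <= 0) {
      warning("correlogram not positive beyond lag 0; returning dt/2 (uncorrelated signal)")
      return(structure(dt / 2, degenerate = TRUE, n_lags_used = 1L))
    }
    return(structure(trapz(rho[seq_len(k)]), degenerate = FALSE, n_lags_used = k - 1L))
  }

  # zero-crossing rule
  nonpos <- which(rho[-1L] <= 0)
  if (!length(nonpos)) {
    # no crossing within the available lags: integrate everything
    return(structure(trapz(rho), degenerate = FALSE, n_lags_used = length(rho) - 1L))
  }
  k <- nonpos[1L] + 1L # index (1-based) of first non-positive value
  if (k == 2L) {
    warning("correlogram not positive beyond lag 0; returning dt/2 (uncorrelated signal)")
    return(structure(dt / 2, degenerate = TRUE, n_lags_used = 1L))
  }
  head_part <- trapz(rho[seq_len(k - 1L)])
  # last trapezoid ends at the interpolated zero crossing between lags k-2 and k-1
  tail_part <- dt * rho[k - 1L]^2 / (2 * (rho[k - 1L] - rho[k]))
  structure(head_part + tail_part, degenerate = FALSE, n_lags_used = k - 1L)
}

#' Maximum window-averaged concentration
#'
#' The largest mean concentration over any sliding window of length `window`
#' seconds (every-sample offsets, so the detected peak is maximal). When the
#' window equals the sampling interval this reduces to the sample maximum.
#' The window is rounded to the nearest integer multiple of `dt`; a warning
#' is emitted when the requested window is not (within tolerance) such a
#' multiple.
#'
#' @inheritParams compute_moments
#' @param window Averaging interval in seconds; at least `dt` and at most
#'   the record length.
#' @return The peak windowed mean concentration (ug m^-3).
#' @examples
#' s <- concentration_series(c(1, 5, 2, 0), dt = 1)
#' max_averaged_concentration(s, window = 2) # max of 3, 3.5, 1
#' @export
max_averaged_concentration <- function(series, window) {
  assert_series(series)
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("`window` must be a single positive duration in seconds", call. = FALSE)
  }
  w <- as.integer(round(window / series$dt))
  if (w < 1L) stop("`window` must be at least one sampling interval", call. = FALSE)
  if (abs(w * series$dt - window) > 1e-6 * series$dt) {
    warning(sprintf(
      "window %g s rounded to %d samples (%g s)",
      window, w, w * series$dt
    ))
  }
  n <- length(series$values)
  if (w > n) stop("`window` is longer than the record", call. = FALSE)
  if (w == 1L) {
    return(max(series$values))
  }
  max(data.table::frollmean(series$values, n = w), na.rm = TRUE)
}

#' Summarise a concentration record
#'
#' Computes every per-series quantity the exposure model consumes: mean,
#' variance (divisor N), fluctuation intensity, intermittency factor,
#' integral time scale, peak concentration at the measurement interval, and
#' the observed maximum exposure `d_max_obs = c_max * dt`.
#'
#' Records whose mean is not positive or whose variance is zero cannot enter
#' the model inversion; they are returned with `screened = TRUE` (and a
#' `screen_reason`) rather than raising an error, so that batch processing
#' of large sensor campaigns proceeds.
#'
#' @inheritParams intermittency_factor
#' @inheritParams integral_time_scale
#' @param max_lag Passed to [autocorrelation()].
#' @return A one-row `data.frame` (class `series_statistics`) with columns
#'   `trial_id`, `sensor_id`, `n_samples`, `dt`, `mean`, `variance`,
#'   `intensity`, `intermittency`, `t_c`, `c_max`, `d_max_obs`, `screened`,
#'   `screen_reason`.
#' @export
summarize_series <- function(series, zero_threshold = 0,
                             truncation_rule = "zero_crossing", max_lag = NULL) {
  assert_series(series)
  mom <- compute_moments(series)
  gam <- intermittency_factor(series, zero_threshold)
  out <- data.frame(
    trial_id = series$trial_id,
    sensor_id = series$sensor_id,
    n_samples = length(series$values),
    dt = series$dt,
    mean = mom$mean,
    variance = mom$variance,
    intensity = NA_real_,
    intermittency = gam,
    t_c = NA_real_,
    c_max = max(series$values),
    d_max_obs = max(series$values) * series$dt,
    screened = FALSE,
    screen_reason = "",
    stringsAsFactors = FALSE
  )
  if (mom$mean <= 0) {
    out$screened <- TRUE
    out$screen_reason <- "non-positive mean"
    return(structure(out, class = c("series_statistics", "data.frame")))
  }
  if (mom$variance == 0) {
    out$screened <- TRUE
    out$screen_reason <- "zero variance"
    out$intensity <- 0
    return(structure(out, class = c("series_statistics", "data.frame")))
  }
  out$intensity <- fluctuation_intensity(mom$mean, mom$variance)
  rho <- autocorrelation(series, max_lag = max_lag)
  out$t_c <- as.numeric(integral_time_scale(rho, truncation_rule = truncation_rule))
  structure(out, class = c("series_statistics", "data.frame"))
}

#' Summarise a campaign of concentration records
#'
#' Applies [summarize_series()] to each record of a list, collecting the
#' one-row summaries into a single table. Records that fail outright (e.g.
#' malformed inputs) are dropped with a message; if more than half fail the
#' batch is aborted.
#'
#' @param campaign A list of [concentration_series()] objects.
#' @inheritParams summarize_series
#' @return A `data.frame` with one row per record (see [summarize_series()]),
#'   with attribute `n_failed`.
#' @export
summarize_campaign <- function(campaign, zero_threshold = 0,
                               truncation_rule = "zero_crossing", max_lag = NULL) {
  if (!length(campaign)) stop("empty campaign", call. = FALSE)
  rows <- vector("list", length(campaign))
  failed <- 0L
  for (i in seq_along(campaign)) {
    rows[[i]] <- tryCatch(
      summarize_series(campaign[[i]],
        zero_threshold = zero_threshold,
        truncation_rule = truncation_rule, max_lag = max_lag
      ),
      error = function(e) {
        failed <<- failed + 1L
        message(sprintf("series %d skipped: %s", i, conditionMessage(e)))
        NULL
      }
    )
  }
  if (failed > length(campaign) / 2) {
    stop(sprintf(
      "%d of %d series malformed; aborting batch", failed, length(campaign)
    ), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  attr(out, "n_failed") <- failed
  out
}
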