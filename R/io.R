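#' Write a concentration series to CSV
#'
#' One column named `concentration`; the sampling interval and identifiers
#' travel in the campaign manifest, not the data file.
#'
#' @param series A [concentration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  assert_series(series)
  utils::write.csv(data.frame(concentration = series$values), path, row.names = FALSE)
  invisible(path)
}

#' Read a concentration series from CSV
#'
#' @param path CSV file with a concentration column.
#' @param dt Sampling interval in seconds.
#' @param trial_id,sensor_id Identifiers to attach.
#' @param column Name of the concentration column; default `"concentration"`.
#' @return A [concentration_series()].
#' @export
read_series_csv <- function(path, dt, trial_id = "trial", sensor_id = "sensor",
                            column = "concentration") {
  tab <- utils::read.csv(path)
  if (!column %in% names(tab)) {
    stop(sprintf("column '%s' not found in %s", column, path), call. = FALSE)
  }
  concentration_series(tab[[column]], dt, trial_id, sensor_id)
}

#' Write a campaign of series to a directory
#'
#' One CSV per sensor record plus a `manifest.csv` recording file, trial,
#' sensor, sampling interval and record length, so the campaign can be
#' read back with [read_campaign()].
#'
#' @param campaign List of [concentration_series()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vector("list", length(campaign))
  for (i in seq_along(campaign)) {
    ser <- campaign[[i]]
    assert_series(ser)
    file <- sprintf("%s_%s.csv", ser$trial_id, ser$sensor_id)
    write_series_csv(ser, file.path(dir, file))
    rows[[i]] <- data.frame(
      file = file, trial_id = ser$trial_id, sensor_id = ser$sensor_id,
      dt = ser$dt, n_samples = length(ser$values), stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a campaign written by [write_campaign()]
#'
#' @param dir Directory containing `manifest.csv` and the per-sensor CSVs.
#' @return List of [concentration_series()].
#' @export
read_campaign <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", dir, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_series_csv(
      file.path(dir, manifest$file[i]),
      dt = manifest$dt[i],
      trial_id = manifest$trial_id[i],
      sensor_id = manifest$sensor_id[i]
    )
  })
}

#' Read concentration records from a long-format table
#'
#' Accepts a table with columns `trial_id`, `sensor_id`, `sample_index`,
#' `concentration` and splits it into one series per (trial, sensor),
#' ordered by sample index.
#'
#' @param path CSV file in long format.
#' @param dt Single sampling interval, or a data frame with columns
#'   `trial_id`, `sensor_id`, `dt` giving per-record intervals.
#' @return List of [concentration_series()].
#' @export
read_long_table <- function(path, dt) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_id", "sensor_id", "sample_index", "concentration")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("long table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  key <- interaction(tab$trial_id, tab$sensor_id, drop = TRUE)
  groups <- split(tab, key)
  lapply(groups, function(g) {
    g <- g[order(g$sample_index), ]
    this_dt <- if (is.data.frame(dt)) {
      hit <- dt$trial_id == g$trial_id[1L] & dt$sensor_id == g$sensor_id[1L]
      if (!any(hit)) {
        stop(sprintf(
          "no sampling interval for %s/%s", g$trial_id[1L], g$sensor_id[1L]
        ), call. = FALSE)
      }
      dt$dt[hit][1L]
    } else {
      dt
    }
    concentration_series(g$concentration, this_dt, g$trial_id[1L], g$sensor_id[1L])
  })
}
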