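#' Readers for the CSV input files
#'
#' Each reader loads one of the model's tabular inputs with an explicit
#' column specification and validates the schema before returning a
#' tibble. Files are plain CSV with a header row.
#'
#' * `read_roads()`: `id, x1_m, y1_m, x2_m, y2_m, lanes, sff_mph,
#'   cap_vphpl, alpha, beta` and optional `road_type`; returned through
#'   [road_segments()] so derived columns are attached.
#' * `read_receptors()`: `id, x_m, y_m`.
#' * `read_met()`: `date, hour, wind_dir, wind_speed` and optional
#'   logical `calm` (defaults to speed 0 or missing).
#' * `read_weekday_profile()`: `hour, total_vph` typical-weekday hourly
#'   volumes.
#' * `read_mix()`: `road_type, class, hour, fraction` weekday vehicle-mix
#'   fractions.
#' * `read_day_factors()`: `f1` table (`day_type, hour, f1`) or `f3`
#'   table (`day_type, hour, duty, f3`), auto-detected by column.
#' * `read_emission_factors()`: `pollutant, season, class, speed_mph,
#'   g_per_mi`, validated with [validate_emission_table()].
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @name readers
NULL

check_cols <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      what, " file is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}

#' @rdname readers
#' @export
read_roads <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  road_segments(df)
}

#' @rdname readers
#' @export
read_receptors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, c("id", "x_m", "y_m"), "receptor")
  df$id <- as.character(df$id)
  df
}

#' @rdname readers
#' @export
read_met <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, c("date", "hour", "wind_dir", "wind_speed"), "met")
  if (!"calm" %in% names(df)) {
    df$calm <- is.na(df$wind_speed) | df$wind_speed == 0
  }
  df$date <- as.Date(df$date)
  if (any(df$wind_dir < 0 | df$wind_dir >= 360, na.rm = TRUE)) {
    abort("wind_dir must lie in [0, 360)")
  }
  df
}

#' @rdname readers
#' @export
read_weekday_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, c("hour", "total_vph"), "weekday traffic profile")
  if (!setequal(df$hour, 0:23)) {
    abort("weekday traffic profile must cover hours 0-23 exactly once")
  }
  df
}

#' @rdname readers
#' @export
read_mix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, c("road_type", "class", "hour", "fraction"), "vehicle mix")
  bad <- setdiff(unique(df$class), vehicle_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown vehicle class(es): ", paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname readers
#' @export
read_day_factors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("f1" %in% names(df)) {
    check_cols(df, c("day_type", "hour", "f1"), "day-factor")
  } else {
    check_cols(df, c("day_type", "hour", "duty", "f3"), "day-factor")
  }
  df
}

#' @rdname readers
#' @export
read_emission_factors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(
    df, c("pollutant", "season", "class", "speed_mph", "g_per_mi"),
    "emission-factor"
  )
  validate_emission_table(df)
  df
}

#' Write hourly or daily model output to CSV
#'
#' Thin wrapper over [readr::write_csv()] kept for symmetry with the
#' readers; returns its input invisibly so it can end a pipe.
#'
#' @param x A tibble of model output.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_output <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
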