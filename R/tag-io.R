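# Reading/writing tag archives and GPS fixes, and GPS quality filtering.
#
# File dialect: comma-separated with a header row and ISO-8601 UTC
# timestamps, so that a write/read cycle is lossless.
# Tag columns: seal_id,timestamp,depth_m,temp_c,ll,wet
# GPS columns: seal_id,timestamp,lon,lat,nsats,residual

TAG_COLS <- c("seal_id", "timestamp", "depth_m", "temp_c", "ll", "wet")
GPS_COLS <- c("seal_id", "timestamp", "lon", "lat", "nsats", "residual")

#' Read a tag archive CSV
#'
#' Parses 10-s dive samples (time, depth, temperature, light level, wet/dry).
#' Rows violating the sensor invariants (light level outside 25-225, depth
#' below -2 m, unparseable fields) are skipped and counted; out-of-order
#' timestamps are re-sorted with a warning.
#'
#' @param path CSV file path.
#' @return tibble of tag records, time-sorted within seal, with the number
#'   of skipped rows in attribute `"n_skipped"`.
#' @export
read_tag_archive <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          seal_id = readr::col_character(),
                          timestamp = readr::col_datetime(),
                          depth_m = readr::col_double(),
                          temp_c = readr::col_double(),
                          ll = readr::col_double(),
                          wet = readr::col_logical()
                        ))
  assert_cols(df, TAG_COLS, basename(path))
  ok <- complete.cases(df[TAG_COLS]) &
    df$ll >= 25 & df$ll <= 225 &
    df$depth_m >= -2
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    inform(sprintf("read_tag_archive: skipped %d malformed row(s)", n_skip))
  }
  df <- df[ok, TAG_COLS]
  if (is.unsorted(order(df$seal_id, df$timestamp)) ||
      any(unlist(tapply(as.numeric(df$timestamp), df$seal_id, diff)) < 0)) {
    warn("timestamps out of order; re-sorting")
  }
  df <- dplyr::arrange(df, .data$seal_id, .data$timestamp)
  attr(df, "n_skipped") <- n_skip
  df
}

#' Read a GPS fix CSV
#'
#' @param path CSV file path.
#' @return tibble of fixes, time-sorted within seal; rows with impossible
#'   coordinates or unparseable fields are skipped and counted in attribute
#'   `"n_skipped"`.
#' @export
read_gps_fixes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          seal_id = readr::col_character(),
                          timestamp = readr::col_datetime(),
                          lon = readr::col_double(),
                          lat = readr::col_double(),
                          nsats = readr::col_integer(),
                          residual = readr::col_double()
                        ))
  assert_cols(df, GPS_COLS, basename(path))
  ok <- complete.cases(df[GPS_COLS]) &
    abs(df$lat) <= 90 & abs(df$lon) <= 180
  n_skip <- sum(!ok)
  if (n_skip > 0) inform(sprintf("read_gps_fixes: skipped %d malformed row(s)", n_skip))
  df <- dplyr::arrange(df[ok, GPS_COLS], .data$seal_id, .data$timestamp)
  attr(df, "n_skipped") <- n_skip
  df
}

#' Write tag records / GPS fixes as CSV
#'
#' @param x tibble of tag records or fixes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tag_archive <- function(x, path) {
  assert_cols(x, TAG_COLS, "tag records")
  readr::write_csv(x[TAG_COLS], path)
  invisible(path)
}

#' @rdname write_tag_archive
#' @export
write_gps_fixes <- function(x, path) {
  assert_cols(x, GPS_COLS, "gps fixes")
  readr::write_csv(x[GPS_COLS], path)
  invisible(path)
}

great_circle_speeds <- function(lon, lat, t) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  d <- geosphere::distHaversine(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1]))
  d / diff(as.numeric(t))
}

#' Quality- and speed-filter GPS fixes
#'
#' First removes fixes derived from fewer than 5 satellites or with residual
#' error above 30. Then applies a speed filter: while any consecutive-pair
#' great-circle speed exceeds `max_speed`, the single fix participating in
#' the worst violation whose removal best reduces the local speed is
#' deleted, and speeds are recomputed. The procedure is deterministic and
#' idempotent, and guarantees all remaining consecutive speeds are at or
#' below `max_speed`.
#'
#' @param fixes tibble of fixes (see [read_gps_fixes()]), time-sorted.
#' @param max_speed speed threshold (m s^-1).
#' @param min_satellites,max_residual quality thresholds; fixes with
#'   `nsats < min_satellites` or `residual > max_residual` are removed.
#' @return filtered fixes tibble; counts of removals are stored in attribute
#'   `"filter_counts"`.
#' @export
filter_gps <- function(fixes, max_speed = 10,
                       min_satellites = 5, max_residual = 30) {
  assert_cols(fixes, GPS_COLS, "fixes")
  qual <- fixes$nsats >= min_satellites & fixes$residual <= max_residual
  n_quality <- sum(!qual)
  fixes <- fixes[qual, ]

  speed_filter_one <- function(df) {
    if (nrow(df) < 2) {
      warn("fewer than 2 fixes after quality filter; returned as-is")
      return(df)
    }
    repeat {
      sp <- great_circle_speeds(df$lon, df$lat, df$timestamp)
      bad <- which(sp > max_speed)
      if (!length(bad)) break
      i <- bad[which.max(sp[bad])]  # worst violating pair (i, i + 1)
      # try removing either endpoint; keep the removal that most reduces the
      # largest speed among the pairs it touches
      local_max <- function(drop_idx) {
        nb <- setdiff((drop_idx - 2):(drop_idx + 2), drop_idx)
        nb <- nb[nb >= 1 & nb <= nrow(df)]
        if (length(nb) < 2) return(0)
        max(great_circle_speeds(df$lon[nb], df$lat[nb], df$timestamp[nb]))
      }
      drop <- if (local_max(i) <= local_max(i + 1)) i else i + 1
      df <- df[-drop, ]
      if (nrow(df) < 2) break
    }
    df
  }

  n0 <- nrow(fixes)
  out <- fixes |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(~ speed_filter_one(.x)) |>
    dplyr::ungroup()
  attr(out, "filter_counts") <- c(quality = n_quality, speed = n0 - nrow(out))
  out
}
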