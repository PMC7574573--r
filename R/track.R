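# Planar projection and regularisation of GPS tracks.
#
# The DCRW operates on planar displacements, so geographic fixes are
# projected with a spherical azimuthal-equidistant projection centred on the
# track centroid; distances from the centre are exact great-circle distances.

EARTH_RADIUS_KM <- 6371.0088

#' Project geographic fixes to planar kilometres
#'
#' Azimuthal-equidistant projection centred on the track centroid (or a
#' supplied centre). The inverse is available via [unproject_xy()].
#'
#' @param fixes tibble with `lon`, `lat` (degrees).
#' @param center optional `c(lon, lat)` projection centre; defaults to the
#'   mean fix position.
#' @return `fixes` with `x_km`, `y_km` columns appended; the centre is stored
#'   in attribute `"center"`.
#' @export
project_track <- function(fixes, center = NULL) {
  assert_cols(fixes, c("lon", "lat"), "fixes")
  if (is.null(center)) center <- c(mean(fixes$lon), mean(fixes$lat))
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  lam <- fixes$lon * pi / 180; phi <- fixes$lat * pi / 180
  dlam <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  out <- dplyr::mutate(
    fixes,
    x_km = EARTH_RADIUS_KM * k * cos(phi) * sin(dlam),
    y_km = EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  )
  attr(out, "center") <- center
  out
}

#' Inverse azimuthal-equidistant projection
#'
#' @param x_km,y_km planar coordinates (km).
#' @param center `c(lon, lat)` projection centre (degrees).
#' @return tibble with `lon`, `lat` (degrees).
#' @export
unproject_xy <- function(x_km, y_km, center) {
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  rho <- sqrt(x_km^2 + y_km^2)
  c_ang <- rho / EARTH_RADIUS_KM
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y_km * sin(c_ang) * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x_km * sin(c_ang),
                             rho * cos(phi0) * cos(c_ang) - y_km * sin(phi0) * sin(c_ang)))
  tibble::tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Interpolate a track onto a regular time grid
#'
#' The state-switching movement model is discrete-time, so filtered fixes are
#' linearly interpolated onto a fixed step (3 h by default, chosen relative
#' to foraging-patch distances and residence times). Grid points bracketed by
#' fixes more than `max_gap` steps apart are not interpolated; such gaps
#' (haulouts, tag outages) split the track into independent segments.
#'
#' @param fixes projected fixes: tibble with `seal_id`, `timestamp`, `x_km`,
#'   `y_km`, time-sorted within seal.
#' @param step_h grid step (hours).
#' @param max_gap largest bracketing gap to interpolate across, in steps.
#' @param min_segment segments shorter than this many positions are dropped
#'   (a DCRW needs at least 3).
#' @return tibble with `seal_id`, `segment`, `timestamp`, `x_km`, `y_km`;
#'   constant time step within each segment.
#' @export
regularize_track <- function(fixes, step_h = 3, max_gap = 4, min_segment = 3) {
  assert_cols(fixes, c("seal_id", "timestamp", "x_km", "y_km"), "fixes")
  step_s <- step_h * 3600
  out <- fixes |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        warn(sprintf("fewer than 2 fixes; empty regular track"))
        return(tibble::tibble(segment = integer(), timestamp = df$timestamp[0],
                              x_km = numeric(), y_km = numeric()))
      }
      df <- dplyr::arrange(df, .data$timestamp)
      tt <- as.numeric(df$timestamp)
      grid <- seq(tt[1], tt[length(tt)], by = step_s)
      idx <- findInterval(grid, tt)
      # bracketing fixes; grid endpoints coincide with fixes so idx >= 1
      lo <- tt[idx]
      hi <- tt[pmin(idx + 1, length(tt))]
      on_fix <- grid == lo
      gap_ok <- on_fix | (hi - lo) <= max_gap * step_s
      w <- ifelse(on_fix, 0, (grid - lo) / (hi - lo))
      x <- df$x_km[idx] * (1 - w) + df$x_km[pmin(idx + 1, length(tt))] * w
      y <- df$y_km[idx] * (1 - w) + df$y_km[pmin(idx + 1, length(tt))] * w
      keep <- gap_ok
      if (!any(keep)) {
        warn("all gaps exceed max_gap; empty regular track")
        return(tibble::tibble(segment = integer(), timestamp = df$timestamp[0],
                              x_km = numeric(), y_km = numeric()))
      }
      # segment id = run id of consecutive kept grid points
      run <- cumsum(c(TRUE, !keep[-length(keep)]))
      res <- tibble::tibble(
        segment = run[keep],
        timestamp = as.POSIXct(grid[keep], origin = "1970-01-01", tz = "UTC"),
        x_km = x[keep], y_km = y[keep]
      )
      res$segment <- as.integer(factor(res$segment))
      res |>
        dplyr::group_by(.data$segment) |>
        dplyr::filter(dplyr::n() >= min_segment) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
  out
}
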