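# shared small helpers

#' Wrap angles to (-pi, pi]
#'
#' Turning-angle estimates from unconstrained optimisation can land near any
#' multiple of 2*pi; wrapping maps them to the principal interval for
#' interpretation.
#'
#' @param x numeric vector of angles (radians).
#' @return angles wrapped to (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, 2 * pi, -3 * pi / 2, 7))
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # boundary: keep pi rather than -pi
  y[y == -pi] <- pi
  y
}

# 2x2 rotation applied to displacement columns (dx, dy)
rotate_xy <- function(dx, dy, theta) {
  cbind(cos(theta) * dx - sin(theta) * dy,
        sin(theta) * dx + cos(theta) * dy)
}

# Atlantic Standard Time is UTC-4 with no daylight saving; the chlorophyll
# noon window is defined on this clock.
AST_OFFSET_H <- -4

# decimal hour of day in AST for POSIXct (UTC) input
ast_hour <- function(time) {
  t_ast <- as.POSIXct(time, tz = "UTC") + AST_OFFSET_H * 3600
  lt <- as.POSIXlt(t_ast, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

month_of <- function(time) as.POSIXlt(as.POSIXct(time, tz = "UTC"), tz = "UTC")$mon + 1L

#' Season labels used in the association models
#'
#' Summer is June-August, fall is September-December. January observations
#' (animals converging on the breeding colony) are outside both seasons and
#' mapped to `NA`, as are February-May months that do not occur in a
#' summer/fall deployment.
#'
#' @param time POSIXct (UTC).
#' @return factor with levels `fall`, `summer` (fall is the reference level).
#' @export
season_of <- function(time) {
  m <- month_of(time)
  s <- dplyr::case_when(
    m %in% 6:8 ~ "summer",
    m %in% 9:12 ~ "fall",
    TRUE ~ NA_character_
  )
  factor(s, levels = c("fall", "summer"))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

logistic <- function(x) plogis(x)
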