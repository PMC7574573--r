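#' Simulate Fastloc-style GPS fixes along a simulated track
#'
#' Fixes are attempted every `gps_interval_min` minutes while the animal is
#' at sea, positioned on the linearly interpolated true path with small
#' Gaussian jitter. Each attempted fix is missed with probability
#' `gps_dropout_prob` and corrupted with probability `gps_bad_prob`; a
#' corrupted fix either reports fewer than 5 satellites, a residual error
#' above 30, or is displaced far enough to imply a swim speed above
#' 10 m s^-1. During a haulout only the first (dry) fix is recorded, after
#' which location attempts are suspended until the animal returns to sea.
#'
#' @param config a [sim_config()].
#' @param track output of [simulate_track()].
#' @param origin deployment origin `c(lon, lat)` in degrees; planar track
#'   coordinates are mapped to geographic positions about this point.
#' @return tibble with columns `seal_id`, `timestamp`, `lon`, `lat`, `nsats`,
#'   `residual`. Attribute `"truth"` flags which fixes were corrupted and how.
#' @export
simulate_gps_fixes <- function(config, track,
                               origin = c(-59.91, 43.95)) {
  validate_sim_config(config)
  seal_idx <- as.integer(sub("seal_", "", track$seal_id[1]))
  set.seed(config$seed + 15485863L * seal_idx + 2L)

  tt <- as.numeric(track$time)
  step_s <- config$step_hours * 3600
  # fix attempt times: every interval within each at-sea step; one fix at the
  # start of each haulout block, then silence until the next step
  attempts <- list()
  for (i in seq_len(nrow(track) - 1)) {
    at_sea_end <- tt[i] + step_s
    attempts[[i]] <- seq(tt[i], at_sea_end - 1, by = config$gps_interval_min * 60)
    if (track$haulout_after[i]) {
      attempts[[i]] <- c(attempts[[i]], at_sea_end)  # first dry fix
    }
  }
  at <- sort(unique(unlist(attempts)))

  # true planar position at attempt times (position holds across haulouts)
  x <- approx(tt, track$x_km, xout = at, rule = 2)$y
  y <- approx(tt, track$y_km, xout = at, rule = 2)$y

  keep <- runif(length(at)) >= config$gps_dropout_prob
  at <- at[keep]; x <- x[keep]; y <- y[keep]
  n <- length(at)

  x <- x + rnorm(n, 0, config$gps_noise_km)
  y <- y + rnorm(n, 0, config$gps_noise_km)
  nsats <- sample(5:11, n, replace = TRUE)
  residual <- runif(n, 0, 25)

  bad <- runif(n) < config$gps_bad_prob
  mode <- ifelse(bad, sample(1:3, n, replace = TRUE), 0L)
  nsats[mode == 1] <- sample(2:4, sum(mode == 1), replace = TRUE)
  residual[mode == 2] <- runif(sum(mode == 2), 31, 80)
  n3 <- sum(mode == 3)
  if (n3 > 0) {
    ang <- runif(n3, 0, 2 * pi)
    dist <- runif(n3, 15, 40)  # >> 10 m/s over a 15-min interval (9 km)
    x[mode == 3] <- x[mode == 3] + dist * cos(ang)
    y[mode == 3] <- y[mode == 3] + dist * sin(ang)
  }

  ll <- unproject_xy(x, y, origin)
  out <- tibble::tibble(
    seal_id = track$seal_id[1],
    timestamp = as.POSIXct(at, origin = "1970-01-01", tz = "UTC"),
    lon = ll$lon, lat = ll$lat,
    nsats = nsats, residual = residual
  )
  attr(out, "truth") <- tibble::tibble(timestamp = out$timestamp, corrupt_mode = mode)
  out
}
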