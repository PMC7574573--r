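#' Simulate a two-state correlated-random-walk movement track
#'
#' Movement follows a first-difference correlated random walk (DCRW) switching
#' between a travelling and an apparent-foraging state: each displacement is
#' the previous displacement rotated by the state's mean turning angle
#' `theta`, damped by the state's autocorrelation `gamma`, plus isotropic
#' bivariate Gaussian noise with the state's `step_sd`,
#' `d_t = gamma_s R(theta_s) d_{t-1} + eps_t`.
#' States follow a first-order Markov chain with the configured transition
#' matrix. Positions are cumulative sums of displacements from `start_xy`.
#'
#' Haulout blocks of `haulout_hours` are inserted after every
#' `steps_per_trip` steps: the clock jumps while the position holds, which
#' creates the temporal gaps that track regularisation and the CAR(1)
#' correlation structure downstream must absorb.
#'
#' @param config a [sim_config()].
#' @param seal_id integer seal index (also seeds the per-seal RNG stream).
#' @param start_xy starting position (km).
#' @param start_disp first displacement (km); defaults to
#'   `c(step_sd[1], 0)` (or `c(1, 0)` when `step_sd[1]` is 0).
#' @return tibble with columns `seal_id`, `step`, `time`, `x_km`, `y_km`,
#'   `state` (state of the displacement leading into the *next* position;
#'   `NA` for the final row) and `haulout_after` (logical: a dry gap follows
#'   this position). The per-displacement true state vector is attached as
#'   attribute `"truth"` (a list with `states`, an integer vector of length
#'   `track_steps - 1`, 1 = travelling, 2 = foraging).
#' @export
#' @examples
#' trk <- simulate_track(sim_config(track_steps = 50, seed = 2))
#' table(attr(trk, "truth")$states)
simulate_track <- function(config, seal_id = 1L, start_xy = c(0, 0),
                           start_disp = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 7919L * as.integer(seal_id))
  n <- config$track_steps
  if (n < 3) abort("track_steps must be >= 3")
  if (is.null(start_disp)) {
    start_disp <- c(if (config$step_sd[1] > 0) config$step_sd[1] else 1, 0)
  }

  # Markov chain over states, one state per displacement (n - 1 of them)
  A <- config$transition_matrix
  s <- integer(n - 1)
  s[1] <- sample.int(2L, 1L, prob = config$delta)
  for (t in seq_len(n - 2)) {
    s[t + 1] <- sample.int(2L, 1L, prob = A[s[t], ])
  }

  d <- matrix(0, n - 1, 2)
  d[1, ] <- start_disp
  for (t in 2:(n - 1)) {
    k <- s[t]
    mu <- config$gamma[k] * drop(rotate_xy(d[t - 1, 1], d[t - 1, 2], config$theta[k]))
    d[t, ] <- mu + rnorm(2, 0, config$step_sd[k])
  }

  xy <- matrix(start_xy, n, 2, byrow = TRUE)
  xy[-1, ] <- xy[-1, ] + apply(d, 2, cumsum)
  colnames(xy) <- c("x_km", "y_km")

  # clock: 3-h grid with haulout gaps inserted between trips
  gap_after <- (seq_len(n) %% config$steps_per_trip == 0) & seq_len(n) < n
  dt_h <- rep(config$step_hours, n - 1) + config$haulout_hours * gap_after[-n]
  times <- config$start_time + c(0, cumsum(dt_h)) * 3600

  out <- tibble::tibble(
    seal_id = sprintf("seal_%02d", as.integer(seal_id)),
    step = seq_len(n),
    time = times,
    x_km = xy[, 1], y_km = xy[, 2],
    state = c(s, NA_integer_),
    haulout_after = gap_after
  )
  attr(out, "truth") <- list(states = s)
  out
}

#' Convert a simulated track to the regular-track layout
#'
#' A simulated track is already on the step grid; this relabels it with the
#' columns the HMM functions expect (`timestamp`, `segment`), starting a new
#' segment after every haulout gap.
#'
#' @param track output of [simulate_track()].
#' @return tibble with `seal_id`, `segment`, `timestamp`, `x_km`, `y_km`.
#' @export
as_regular_track <- function(track) {
  seg <- cumsum(c(TRUE, head(track$haulout_after, -1)))
  tibble::tibble(
    seal_id = track$seal_id,
    segment = as.integer(seg),
    timestamp = track$time,
    x_km = track$x_km,
    y_km = track$y_km
  )
}
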