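#' Trapezoidal dive depth profile sampled at the tag cadence
#'
#' Benthic dives are emulated as a trapezoid: constant-rate descent to
#' `max_depth`, a flat bottom phase, constant-rate ascent, sampled every
#' `cadence_s` seconds from the dive start. A dive deeper than the local
#' seafloor is physically impossible and rejected.
#'
#' @param max_depth dive maximum depth (m).
#' @param seafloor_depth local seafloor depth (m).
#' @param descent_rate,ascent_rate vertical rates (m s^-1).
#' @param bottom_fraction fraction of total dive duration spent at the bottom.
#' @param cadence_s sampling cadence (s).
#' @return tibble with `t_s` (seconds from dive start) and `depth_m`.
#' @export
#' @examples
#' dive_profile(60, 80, 1.2, 1.0, 0.5)
dive_profile <- function(max_depth, seafloor_depth,
                         descent_rate, ascent_rate,
                         bottom_fraction, cadence_s = 10) {
  if (max_depth > seafloor_depth) {
    abort(sprintf("dive to %.1f m exceeds seafloor depth %.1f m",
                  max_depth, seafloor_depth))
  }
  if (descent_rate <= 0 || ascent_rate <= 0) abort("vertical rates must be > 0")
  t_d <- max_depth / descent_rate
  t_a <- max_depth / ascent_rate
  t_b <- bottom_fraction / (1 - bottom_fraction) * (t_d + t_a)
  total <- t_d + t_b + t_a
  t_s <- seq(0, total, by = cadence_s)
  depth <- ifelse(t_s <= t_d, descent_rate * t_s,
           ifelse(t_s <= t_d + t_b, max_depth,
                  pmax(0, max_depth - ascent_rate * (t_s - t_d - t_b))))
  tibble::tibble(t_s = t_s, depth_m = depth)
}

#' Simulate the tag archive (depth, temperature, light, wet/dry) for a track
#'
#' For each 3-h movement step the number of dives is Poisson with mean
#' `dive_rate * step_hours`; each dive descends to just above the local
#' seafloor with a trapezoidal profile and is sampled every 10 s. Dives are
#' placed sequentially through the step so records never overlap in time;
#' dives that would spill past the end of a step are dropped.
#' Temperature comes from the configured stratified profile at the sample
#' depth. Light level decays linearly with depth on the sensor's log scale,
#' `LL(z) = surface_LL - (units_per_decade / ln 10) * K_d * z`, with `K_d`
#' obtained from the chlorophyll-a field through the forward bio-optical
#' model, plus optional Gaussian sensor noise; values are clamped to the
#' sensor range [25, 225]. Samples are wet during dives; haulout blocks emit
#' dry surface records at a 60-s cadence.
#'
#' @param config a [sim_config()].
#' @param track output of [simulate_track()].
#' @return tibble of tag records with columns `seal_id`, `timestamp`,
#'   `depth_m`, `temp_c`, `ll`, `wet`. Attribute `"truth"` holds a per-dive
#'   tibble of ground truth (`start`, position, `true_chla`, `true_kd`,
#'   `max_depth`).
#' @export
simulate_dive_records <- function(config, track) {
  validate_sim_config(config)
  seal_idx <- as.integer(sub("seal_", "", track$seal_id[1]))
  set.seed(config$seed + 104729L * seal_idx + 1L)
  n <- nrow(track)
  cad <- config$cadence_s
  step_s <- config$step_hours * 3600

  recs <- list()
  truth <- list()
  for (i in seq_len(n - 1)) {
    n_dives <- rpois(1, config$dive_rate * config$step_hours)
    if (n_dives > 0) {
      slot <- step_s / n_dives
      cursor <- 0
      for (k in seq_len(n_dives)) {
        t_off <- max((k - 1) * slot + runif(1, 0, 60), cursor + 30)
        frac <- t_off / step_s
        x <- track$x_km[i] + frac * (track$x_km[i + 1] - track$x_km[i])
        y <- track$y_km[i] + frac * (track$y_km[i + 1] - track$y_km[i])
        t0 <- track$time[i] + t_off
        sf <- config$seafloor_depth_field(x, y)
        md <- max(10, sf - runif(1, 0, 5))
        chla <- config$chla_field(x, y, t0)
        kd <- kd_from_chla(chla, config$optics)
        prof <- dive_profile(
          md, sf,
          descent_rate = runif(1, config$descent_rate_range[1], config$descent_rate_range[2]),
          ascent_rate = runif(1, config$ascent_rate_range[1], config$ascent_rate_range[2]),
          bottom_fraction = runif(1, config$bottom_fraction_range[1], config$bottom_fraction_range[2]),
          cadence_s = cad
        )
        if (t_off + max(prof$t_s) > step_s - cad) next  # would spill past the step
        cursor <- t_off + max(prof$t_s) + cad
        noise <- if (config$ll_noise_sd > 0) rnorm(nrow(prof), 0, config$ll_noise_sd) else 0
        recs[[length(recs) + 1L]] <- tibble::tibble(
          timestamp = t0 + prof$t_s,
          depth_m = prof$depth_m,
          temp_c = temp_at_depth(prof$depth_m, config),
          ll = ll_at_depth(prof$depth_m, kd, config, noise),
          wet = TRUE
        )
        truth[[length(truth) + 1L]] <- tibble::tibble(
          start = t0, x_km = x, y_km = y,
          true_chla = chla, true_kd = kd, max_depth = md
        )
      }
    }
    if (track$haulout_after[i]) {
      ho_start <- track$time[i] + step_s
      ho_t <- seq(0, config$haulout_hours * 3600, by = 60)
      recs[[length(recs) + 1L]] <- tibble::tibble(
        timestamp = ho_start + ho_t,
        depth_m = 0,
        temp_c = temp_at_depth(0, config),
        ll = ll_at_depth(0, 0, config),
        wet = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(recs)
  out <- dplyr::arrange(out, .data$timestamp)
  out <- tibble::tibble(seal_id = track$seal_id[1], out)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}
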