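# Per-dive environmental covariates estimated from the tag's own sensors.
# The ascent phase samples the water column from the bottom up and is used
# for profile quantities; the bottom phase describes conditions where a
# benthic forager actually feeds.

#' Mean upper-water-column temperature (T50)
#'
#' Arithmetic mean of ascent-phase temperatures at depths within the upper
#' water column (50 m), which contains most of the mixed layer and
#' phytoplankton biomass in shelf seas.
#'
#' @param samples one dive's samples with a `phase` column
#'   (see [split_phases()]).
#' @param max_depth_m upper-column limit (m).
#' @return mean temperature (deg C), or `NA` if no qualifying samples.
#' @export
upper_column_temperature <- function(samples, max_depth_m = 50) {
  s <- samples[samples$phase == "ascent" & samples$depth_m <= max_depth_m, ]
  if (!nrow(s)) return(NA_real_)
  mean(s$temp_c)
}

#' Estimate light attenuation from ascent-phase light levels
#'
#' The tag stores log-transformed irradiance (fixed number of sensor units
#' per decade), so irradiance decaying as `exp(-K_d z)` appears as a straight
#' line of LL against depth. The ordinary least-squares slope `b` of LL on
#' depth over the upper water column gives
#' `LA = max(0, -b * ln(10) / units_per_decade)` in m^-1. Samples pinned at
#' the sensor limits (25 or 225) are saturated and excluded before the
#' regression.
#'
#' @param samples one dive's samples with a `phase` column.
#' @param units_per_decade sensor units per decade of irradiance.
#' @param max_depth_m upper-column limit (m).
#' @param min_samples minimum usable samples for a defined estimate.
#' @return attenuation (m^-1), or `NA` if fewer than `min_samples` usable
#'   samples or no depth variance.
#' @export
estimate_light_attenuation <- function(samples, units_per_decade = 20,
                                       max_depth_m = 50, min_samples = 5) {
  s <- samples[samples$phase == "ascent" & samples$depth_m <= max_depth_m &
                 samples$ll > 25 & samples$ll < 225, ]
  if (nrow(s) < min_samples) return(NA_real_)
  if (sd(s$depth_m) < 1e-12) return(NA_real_)
  b <- coef(lm(ll ~ depth_m, data = s))[["depth_m"]]
  max(0, -b * log(10) / units_per_decade)
}

#' Invert the bio-optical model for chlorophyll-a
#'
#' Given attenuation `LA` and coefficients of the forward model
#' `K_d = K_w + chi * chla^e`, returns `chla = ((LA - K_w) / chi)^(1/e)`;
#' attenuation at or below the pure-water value maps to 0.
#'
#' @param LA attenuation (m^-1); may be a vector.
#' @param optics [bio_optics()] coefficients.
#' @return chlorophyll-a (mg m^-3).
#' @export
#' @examples
#' estimate_chla(kd_from_chla(1.0))  # round trip: 1.0
estimate_chla <- function(LA, optics = bio_optics()) {
  if (!inherits(optics, "bio_optics")) optics <- do.call(bio_optics, optics)
  ifelse(is.na(LA), NA_real_,
         ifelse(LA <= optics$K_w, 0,
                ((LA - optics$K_w) / optics$chi)^(1 / optics$e)))
}

#' Mixed-layer depth from an ascent temperature profile
#'
#' Shallowest depth at which temperature deviates from the near-surface
#' reference (mean of samples at 5 m or shallower) by at least `delta_T`.
#' If no sample deviates, the profile is mixed to at least its deepest
#' sample and the estimate is flagged bottom-limited. The threshold method
#' is a conventional criterion; tags record no salinity, so density-based
#' definitions are unavailable.
#'
#' @param samples one dive's samples with a `phase` column.
#' @param delta_T temperature deviation threshold (deg C).
#' @param ref_depth_m near-surface reference layer (m).
#' @return list with `mld` (m, `NA` if undefined) and `bottom_limited`.
#' @export
mixed_layer_depth <- function(samples, delta_T = 0.5, ref_depth_m = 5) {
  s <- samples[samples$phase == "ascent", ]
  s <- s[order(s$depth_m), ]
  if (!nrow(s) || diff(range(s$depth_m)) < 10) {
    return(list(mld = NA_real_, bottom_limited = FALSE))
  }
  ref_samples <- s$temp_c[s$depth_m <= ref_depth_m]
  if (!length(ref_samples)) return(list(mld = NA_real_, bottom_limited = FALSE))
  ref <- mean(ref_samples)
  dev <- which(abs(s$temp_c - ref) >= delta_T)
  if (length(dev)) {
    list(mld = s$depth_m[min(dev)], bottom_limited = FALSE)
  } else {
    list(mld = max(s$depth_m), bottom_limited = TRUE)
  }
}

#' Mean depth and temperature of the bottom phase
#'
#' @param samples one dive's samples with a `phase` column.
#' @return list with `bot_depth` (m) and `bot_temp` (deg C).
#' @export
bottom_conditions <- function(samples) {
  s <- samples[samples$phase == "bottom", ]
  if (!nrow(s)) return(list(bot_depth = NA_real_, bot_temp = NA_real_))
  list(bot_depth = mean(s$depth_m), bot_temp = mean(s$temp_c))
}

#' Per-dive environmental covariate table
#'
#' Computes, for every dive: T50, mixed-layer depth, light attenuation,
#' chlorophyll-a, bottom-phase mean depth/temperature, and the noon-window
#' flag. Chlorophyll-a is only defined when the dive's temporal midpoint
#' falls inside the 10:00-14:00 AST window (minimising solar-zenith effects)
#' and the dive reaches at least `chla_min_depth` (so the regression spans
#' the upper water column).
#'
#' @param dives phase-annotated dive tibble from [split_phases()].
#' @param optics [bio_optics()] coefficients for the chlorophyll inversion.
#' @param units_per_decade light-sensor units per decade of irradiance.
#' @param chla_min_depth minimum dive depth (m) for a chlorophyll estimate.
#' @param noon_window AST decimal hours `c(start, end)`; membership is
#'   `start <= hour < end` for the dive midpoint.
#' @return tibble: `seal_id`, `dive_id`, `dive_start`, `dive_end`, `T50`,
#'   `mld_m`, `mld_bottom_limited`, `la_per_m`, `chla_mg_m3`, `bot_depth_m`,
#'   `bot_temp_c`, `bot_dur_s`, `max_depth_m`, `noon`.
#' @export
dive_environment <- function(dives, optics = bio_optics(),
                             units_per_decade = 20,
                             chla_min_depth = 50,
                             noon_window = c(10, 14)) {
  if (!nrow(dives)) return(tibble::tibble())
  mid <- dives$start + as.numeric(dives$end - dives$start, units = "secs") / 2
  hr <- ast_hour(mid)
  noon <- hr >= noon_window[1] & hr < noon_window[2]
  env <- purrr::map(dives$samples, function(smp) {
    mld <- mixed_layer_depth(smp)
    bot <- bottom_conditions(smp)
    tibble::tibble(
      T50 = upper_column_temperature(smp),
      la_per_m = estimate_light_attenuation(smp, units_per_decade),
      mld_m = mld$mld, mld_bottom_limited = mld$bottom_limited,
      bot_depth_m = bot$bot_depth, bot_temp_c = bot$bot_temp
    )
  }) |> dplyr::bind_rows()
  out <- tibble::tibble(
    seal_id = dives$seal_id,
    dive_id = dives$dive_id,
    dive_start = dives$start,
    dive_end = dives$end,
    env,
    bot_dur_s = dives$bottom_duration_s,
    max_depth_m = dives$max_depth_m,
    noon = noon
  )
  out$chla_mg_m3 <- ifelse(
    out$noon & out$max_depth_m >= chla_min_depth & !is.na(out$la_per_m),
    estimate_chla(out$la_per_m, optics), NA_real_
  )
  dplyr::relocate(out, "chla_mg_m3", .after = "la_per_m")
}
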