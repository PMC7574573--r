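#' Simulation configuration for synthetic seal deployments
#'
#' Bundles every knob of the synthetic-data generator: the two-state movement
#' process, dive generation, the water-column environment (temperature
#' stratification, chlorophyll-a field, bio-optics), haulout scheduling and
#' GPS degradation. Defaults describe a Scotian-Shelf-like deployment: 3-h
#' movement steps, benthic dives over an 60-110 m seafloor, a stratified
#' summer water column and a light sensor spanning 10 decades of irradiance
#' in 200 logarithmic units.
#'
#' The movement defaults are the behavioural-state parameters recovered from
#' grey seal tracks: persistent travelling (`gamma` 0.9, `theta` 0) versus
#' tortuous apparent foraging (`gamma` 0.2), switching with a row-stochastic
#' transition matrix.
#'
#' @param n_seals number of simulated animals.
#' @param sex_ratio fraction of females.
#' @param track_steps number of positions per simulated track.
#' @param step_hours movement time step (hours).
#' @param theta per-state mean turning angle (radians), travelling first.
#' @param gamma per-state displacement autocorrelation, in (0, 1).
#' @param step_sd per-state process noise SD of the displacement innovation (km).
#' @param transition_matrix 2x2 row-stochastic behavioural transition matrix.
#' @param delta initial state distribution.
#' @param dive_rate dives per hour while at sea.
#' @param steps_per_trip movement steps between haulouts.
#' @param haulout_hours duration of each dry haulout block (hours).
#' @param seafloor_depth_field `function(x, y)` returning seafloor depth (m,
#'   positive down) at planar position (km).
#' @param chla_field `function(x, y, time)` returning chlorophyll-a
#'   (mg m^-3) at position/time.
#' @param temp_surface,temp_bottom surface and deep temperature (deg C).
#' @param thermocline_depth,thermocline_width centre and width (m) of the
#'   logistic thermocline.
#' @param surface_ll light level at zero depth (sensor units).
#' @param ll_units_per_decade sensor units per decade of irradiance; 20 units
#'   per decade spans the 25-225 range over the sensor's 10 decades and fixes
#'   the attenuation conversion constant ln(10)/20.
#' @param ll_noise_sd additive LL noise SD (units); 0 gives noiseless optics.
#' @param optics bio-optical coefficients from [bio_optics()].
#' @param descent_rate_range,ascent_rate_range uniform draw ranges for dive
#'   vertical rates (m s^-1).
#' @param bottom_fraction_range uniform draw range for the fraction of dive
#'   duration spent in the bottom phase.
#' @param cadence_s tag sampling cadence during dives (seconds).
#' @param gps_interval_min surface GPS fix cadence (minutes).
#' @param gps_noise_km SD of positional jitter on good fixes (km).
#' @param gps_dropout_prob probability a scheduled fix is missed entirely.
#' @param gps_bad_prob probability a fix is corrupted (few satellites, large
#'   residual error, or an implied speed above 10 m s^-1).
#' @param start_time deployment start (POSIXct UTC).
#' @param seed integer seed; a fixed seed reproduces every output exactly.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_seals = 2, track_steps = 40, seed = 1)
#' cfg$gamma
sim_config <- function(n_seals = 4,
                       sex_ratio = 0.5,
                       track_steps = 240,
                       step_hours = 3,
                       theta = c(0, 0),
                       gamma = c(0.9, 0.2),
                       step_sd = c(4.4, 2.0),
                       transition_matrix = matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE),
                       delta = c(0.5, 0.5),
                       dive_rate = 6,
                       steps_per_trip = 80,
                       haulout_hours = 18,
                       seafloor_depth_field = default_seafloor,
                       chla_field = default_chla_field,
                       temp_surface = 14,
                       temp_bottom = 5,
                       thermocline_depth = 30,
                       thermocline_width = 8,
                       surface_ll = 220,
                       ll_units_per_decade = 20,
                       ll_noise_sd = 0,
                       optics = bio_optics(),
                       descent_rate_range = c(0.5, 2.5),
                       ascent_rate_range = c(0.5, 2.5),
                       bottom_fraction_range = c(0.4, 0.6),
                       cadence_s = 10,
                       gps_interval_min = 15,
                       gps_noise_km = 0.03,
                       gps_dropout_prob = 0.05,
                       gps_bad_prob = 0.05,
                       start_time = as.POSIXct("2014-06-15 00:00:00", tz = "UTC"),
                       seed = 1L) {
  cfg <- list(
    n_seals = as.integer(n_seals), sex_ratio = sex_ratio,
    track_steps = as.integer(track_steps), step_hours = step_hours,
    theta = theta, gamma = gamma, step_sd = step_sd,
    transition_matrix = transition_matrix, delta = delta,
    dive_rate = dive_rate, steps_per_trip = as.integer(steps_per_trip),
    haulout_hours = haulout_hours,
    seafloor_depth_field = seafloor_depth_field, chla_field = chla_field,
    temp_surface = temp_surface, temp_bottom = temp_bottom,
    thermocline_depth = thermocline_depth, thermocline_width = thermocline_width,
    surface_ll = surface_ll, ll_units_per_decade = ll_units_per_decade,
    ll_noise_sd = ll_noise_sd, optics = optics,
    descent_rate_range = descent_rate_range,
    ascent_rate_range = ascent_rate_range,
    bottom_fraction_range = bottom_fraction_range,
    cadence_s = cadence_s, gps_interval_min = gps_interval_min,
    gps_noise_km = gps_noise_km, gps_dropout_prob = gps_dropout_prob,
    gps_bad_prob = gps_bad_prob,
    start_time = as.POSIXct(start_time, tz = "UTC"), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  A <- cfg$transition_matrix
  if (!is.matrix(A) || any(dim(A) != 2) || any(A < 0) ||
      any(abs(rowSums(A) - 1) > 1e-8)) {
    abort("transition_matrix must be 2x2 with non-negative rows summing to 1")
  }
  # gamma = 1 (pure persistence) is admitted for noise-free constructions;
  # estimation keeps gamma strictly inside (0, 1)
  if (any(cfg$gamma <= 0) || any(cfg$gamma > 1)) {
    abort("gamma must lie in (0, 1]")
  }
  if (any(cfg$step_sd < 0)) abort("step_sd must be >= 0")
  if (length(cfg$theta) != 2 || length(cfg$gamma) != 2 || length(cfg$step_sd) != 2) {
    abort("theta, gamma and step_sd must each have one value per state")
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) abort("sex_ratio must be in [0, 1]")
  if (abs(sum(cfg$delta) - 1) > 1e-8 || any(cfg$delta < 0)) {
    abort("delta must be a probability vector")
  }
  invisible(cfg)
}

#' Bio-optical coefficients linking diffuse attenuation to chlorophyll-a
#'
#' Parameterises the forward model `K_d = K_w + chi * chla^e` relating the
#' diffuse attenuation coefficient (m^-1) to chlorophyll-a concentration
#' (mg m^-3), where `K_w` is the pure-seawater attenuation. Defaults are
#' Morel-type open-ocean coefficients; users analysing real deployments
#' should substitute locally validated values.
#'
#' @param K_w pure-water attenuation (m^-1).
#' @param chi chlorophyll scaling coefficient (> 0).
#' @param e chlorophyll exponent (> 0).
#' @return list of class `bio_optics`.
#' @export
#' @examples
#' kd_from_chla(1, bio_optics())
bio_optics <- function(K_w = 0.04, chi = 0.0518, e = 0.428) {
  if (chi <= 0 || e <= 0) abort("bio-optical coefficients chi and e must be > 0")
  if (K_w < 0) abort("K_w must be >= 0")
  structure(list(K_w = K_w, chi = chi, e = e), class = "bio_optics")
}

#' Forward bio-optical model: attenuation from chlorophyll-a
#' @param chla chlorophyll-a concentration (mg m^-3).
#' @param optics coefficients from [bio_optics()].
#' @return diffuse attenuation K_d (m^-1).
#' @export
kd_from_chla <- function(chla, optics = bio_optics()) {
  optics$K_w + optics$chi * chla^optics$e
}

# default smooth positive chlorophyll field (mg m^-3) over planar km coords
default_chla_field <- function(x, y, time = NULL) {
  pmax(0.1, 1.2 + 0.8 * sin(x / 30) * cos(y / 40))
}

# default seafloor (m, positive down): gentle banks between ~60 and 110 m
default_seafloor <- function(x, y) {
  85 + 25 * sin(x / 50) * sin(y / 60)
}

# stratified temperature profile: logistic thermocline between surface and
# bottom water masses
temp_at_depth <- function(z, cfg) {
  cfg$temp_bottom + (cfg$temp_surface - cfg$temp_bottom) /
    (1 + exp((z - cfg$thermocline_depth) / cfg$thermocline_width))
}

# forward optics: light level at depth z for attenuation kd; the tag stores
# log10 irradiance scaled to ll_units_per_decade units per decade, clamped to
# the sensor range [25, 225]
ll_at_depth <- function(z, kd, cfg, noise = 0) {
  ll <- cfg$surface_ll - (cfg$ll_units_per_decade / log(10)) * kd * z + noise
  pmin(225, pmax(25, ll))
}
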