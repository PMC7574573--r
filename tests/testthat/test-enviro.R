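# per-dive environmental estimation: T50, attenuation, chlorophyll, MLD,
# bottom conditions

# dive samples with prescribed ascent depths/temps/lights
ascent_samples <- function(depths, temps = 8, lls = 150) {
  n <- length(depths)
  tibble::tibble(
    timestamp = t_utc("2014-07-01 15:00:00") + (seq_len(n) - 1) * 10,
    depth_m = depths,
    temp_c = rep_len(temps, n),
    ll = rep_len(lls, n),
    wet = TRUE,
    phase = "ascent"
  )
}

test_that("T50 is the ascent mean within 50 m, excluding deeper samples", {
  iso <- ascent_samples(seq(50, 0, by = -10), temps = 10)
  expect_equal(upper_column_temperature(iso), 10)

  z <- seq(50, 0, by = -10)
  s <- ascent_samples(z, temps = 5 + 0.2 * (50 - z))
  expect_equal(upper_column_temperature(s), mean(5 + 0.2 * (50 - z)))

  deep <- ascent_samples(c(60, z), temps = c(99, 5 + 0.2 * (50 - z)))
  expect_equal(upper_column_temperature(deep), mean(5 + 0.2 * (50 - z)))

  none <- ascent_samples(c(70, 60))
  expect_true(is.na(upper_column_temperature(none)))
})

test_that("constant light gives zero attenuation", {
  s <- ascent_samples(seq(50, 0, by = -10), lls = 140)
  expect_equal(estimate_light_attenuation(s), 0)
})

test_that("a noiseless linear light profile gives the closed-form attenuation", {
  z <- seq(45, 5, by = -5)
  s <- ascent_samples(z, lls = 200 - 2 * z)
  expect_equal(estimate_light_attenuation(s, units_per_decade = 20),
               2 * log(10) / 20, tolerance = 1e-12)
  expect_equal(estimate_light_attenuation(s), 0.23026, tolerance = 1e-4)
})

test_that("saturated samples are excluded and sparse profiles are undefined", {
  z <- seq(45, 5, by = -5)
  ll <- 200 - 2 * z
  ll[z > 30] <- 25  # pinned at the sensor floor
  s <- ascent_samples(z, lls = ll)
  # only the unclipped samples enter; the line is intact there
  expect_equal(estimate_light_attenuation(s), 2 * log(10) / 20, tolerance = 1e-12)
  few <- ascent_samples(c(40, 30, 20, 10), lls = c(120, 140, 160, 180))
  expect_true(is.na(estimate_light_attenuation(few)))
  flat <- ascent_samples(rep(20, 6), lls = 150)
  expect_true(is.na(estimate_light_attenuation(flat)))
})

test_that("OLS slope matches a normal-equations oracle on random profiles", {
  set.seed(101)
  for (i in 1:20) {
    z <- sort(runif(sample(5:15, 1), 0, 50), decreasing = TRUE)
    ll <- runif(1, 100, 200) - runif(1, 0, 3) * z + rnorm(length(z), 0, 5)
    ll <- pmin(pmax(ll, 26), 224)
    s <- ascent_samples(z, lls = ll)
    X <- cbind(1, z)
    b <- solve(t(X) %*% X, t(X) %*% ll)[2]
    expect_equal(estimate_light_attenuation(s), max(0, -b * log(10) / 20),
                 tolerance = 1e-10)
  }
})

test_that("bio-optical inversion round-trips and handles the pure-water limit", {
  opt <- bio_optics()
  expect_equal(estimate_chla(opt$K_w, opt), 0)
  expect_equal(estimate_chla(opt$K_w - 0.01, opt), 0)
  expect_equal(estimate_chla(kd_from_chla(1.0, opt), opt), 1.0, tolerance = 1e-12)
  for (chla in c(0.1, 0.5, 1, 5, 10)) {
    expect_equal(estimate_chla(kd_from_chla(chla, opt), opt), chla,
                 tolerance = 1e-10)
  }
  expect_error(bio_optics(chi = -1), "chi")
  expect_error(bio_optics(e = 0), "chi|e")
})

test_that("chlorophyll is monotone non-decreasing in attenuation", {
  la <- seq(0.03, 1, length.out = 200)
  ch <- estimate_chla(la)
  expect_true(all(diff(ch) >= 0))
})

test_that("mixed-layer depth follows the threshold criterion", {
  z <- seq(60, 0, by = -5)
  iso <- ascent_samples(z, temps = 9)
  m <- mixed_layer_depth(iso)
  expect_equal(m$mld, 60)
  expect_true(m$bottom_limited)

  step <- ascent_samples(z, temps = ifelse(z >= 30, 6, 12))
  m2 <- mixed_layer_depth(step)
  expect_equal(m2$mld, 30)
  expect_false(m2$bottom_limited)

  m3 <- mixed_layer_depth(step, delta_T = 0)
  expect_equal(m3$mld, min(z))
})

test_that("bottom conditions are arithmetic means over the bottom phase", {
  smp <- ascent_samples(c(80, 90, 100, 90), temps = c(6, 6, 6, 6))
  smp$phase <- "bottom"
  bc <- bottom_conditions(smp)
  expect_equal(bc$bot_depth, 90)
  expect_equal(bc$bot_temp, 6)

  one <- ascent_samples(48, temps = 5.5)
  one$phase <- "bottom"
  expect_equal(bottom_conditions(one)$bot_depth, 48)
})

test_that("chlorophyll requires the noon window and a 50 m dive", {
  cfg <- sim_config()
  # slow ascent so at least 5 ascent samples sit above the bottom envelope
  deep <- trapezoid_depths(60, 60, 120, 120)
  make_env <- function(start) {
    rec <- make_records(c(0, deep, 0), start = start)
    kd <- kd_from_chla(1, cfg$optics)
    rec$ll <- sealforage:::ll_at_depth(rec$depth_m, kd, cfg)
    dv <- detect_dives(rec) |> split_phases()
    dive_environment(dv)
  }
  # 16:00 UTC = noon AST: inside the window
  env_noon <- make_env(t_utc("2014-07-01 16:00:00"))
  expect_true(env_noon$noon)
  expect_equal(env_noon$chla_mg_m3, 1.0, tolerance = 1e-6)
  # 15:30 AST: outside
  env_pm <- make_env(t_utc("2014-07-01 19:30:00"))
  expect_false(env_pm$noon)
  expect_true(is.na(env_pm$chla_mg_m3))
  # shallow dive at noon: undefined
  rec <- make_records(c(0, trapezoid_depths(40, 40, 80, 40), 0),
                      start = t_utc("2014-07-01 16:00:00"))
  rec$ll <- sealforage:::ll_at_depth(rec$depth_m, 0.06, cfg)
  dv <- detect_dives(rec) |> split_phases()
  expect_true(is.na(dive_environment(dv)$chla_mg_m3))
})

test_that("noiseless synthetic optics invert to the true chlorophyll within 1%", {
  cfg <- sim_config(n_seals = 1, track_steps = 60, seed = 4, dive_rate = 4,
                    ll_noise_sd = 0)
  trk <- simulate_track(cfg, 1)
  rec <- simulate_dive_records(cfg, trk)
  truth <- attr(rec, "truth")
  dv <- process_dives(rec)
  env <- dive_environment(dv, optics = cfg$optics)
  m <- vapply(as.numeric(dv$start), function(s) {
    which.min(abs(as.numeric(truth$start) - s))
  }, integer(1))
  ok <- !is.na(env$chla_mg_m3)
  expect_gt(sum(ok), 5)
  rel <- abs(env$chla_mg_m3[ok] - truth$true_chla[m[ok]]) / truth$true_chla[m[ok]]
  expect_lt(max(rel), 0.01)
})
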