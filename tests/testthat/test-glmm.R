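# CAR(1) correlation, PQL estimation, odds ratios, observation assembly

test_that("CAR(1) entries are rho^|dt| in hours and rho = 0 is the identity", {
  C <- car1_corr(c(0, 3, 6), 0.8)
  expect_equal(C[1, 2], 0.8^3)
  expect_equal(C[1, 3], 0.8^6)
  expect_equal(C[2, 3], 0.512)
  expect_equal(C[1, 3], 0.262144)
  expect_equal(car1_corr(c(0, 5, 9), 0), diag(3))
  expect_error(car1_corr(c(0, 1), 1), "rho")
})

test_that("CAR(1) matrices are positive definite on random time sets", {
  set.seed(51)
  for (i in 1:100) {
    times <- sort(runif(sample(5:25, 1), 0, 100))
    rho <- runif(1, -0.99, 0.99)
    C <- car1_corr(times, rho)
    expect_silent(chol(C))
  }
})

test_that("PQL with no random effect and no correlation equals logistic IRLS", {
  sim <- simulate_glmm_dataset(n_seals = 6, n_obs_per_seal = 80, re_sd = 0,
                               rho_step = 0, noise_sd = 0, seed = 5)
  d <- sim$observations
  f0 <- fit_pql_glmm(d, "water_column", include_re = FALSE, include_car = FALSE)
  g <- glm(model_formula("water_column"), binomial, data = d)
  expect_equal(f0$coefficients$estimate, unname(coef(g)), tolerance = 1e-4)
  expect_lt(max(abs(f0$coefficients$estimate - coef(g))), 1e-4)
})

test_that("the inner whitened REML fit reproduces nlme::lme exactly", {
  skip_if_not_installed("nlme")
  set.seed(3)
  G <- 6; m <- 40
  d <- data.frame(g = rep(factor(1:G), each = m),
                  t = rep(seq(0, by = 3, length.out = m), G),
                  x = rnorm(G * m))
  nu <- rnorm(G, 0, 0.7)
  eps <- unlist(lapply(1:G, function(i) {
    e <- numeric(m); e[1] <- rnorm(1)
    for (k in 2:m) e[k] <- 0.85 * e[k - 1] + rnorm(1, 0, sqrt(1 - 0.85^2))
    e
  }))
  d$w <- runif(G * m, 0.1, 0.3)
  d$z <- 1 + 0.5 * d$x + nu[d$g] + eps / sqrt(d$w)
  d$invw <- 1 / d$w
  lf <- nlme::lme(z ~ x, random = ~1 | g, data = d,
                  correlation = nlme::corCAR1(form = ~t | g),
                  weights = nlme::varFixed(~invw), method = "REML")
  inner <- sealforage:::inner_lmm(
    d$z, d$w, cbind(1, d$x), as.integer(d$g), !duplicated(d$g),
    c(0, diff(d$t)) * as.numeric(duplicated(d$g)), TRUE, TRUE)
  expect_equal(inner$beta, unname(nlme::fixef(lf)), tolerance = 1e-4)
  expect_equal(inner$rho,
               as.numeric(coef(lf$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(sqrt(inner$sigma2), lf$sigma, tolerance = 1e-3)
  expect_equal(sqrt(inner$lambda * inner$sigma2),
               as.numeric(nlme::VarCorr(lf)[1, 2]), tolerance = 1e-3)
  expect_equal(sqrt(diag(inner$cov_beta)), unname(sqrt(diag(stats::vcov(lf)))),
               tolerance = 1e-3)
})

test_that("full PQL agrees with the reference glmmPQL implementation", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("nlme")
  sim <- simulate_glmm_dataset(n_seals = 8, n_obs_per_seal = 80,
                               re_sd = 0.5, rho_step = 0.5, seed = 9)
  d <- as.data.frame(sim$observations)
  f <- fit_pql_glmm(d, "water_column")
  g <- suppressMessages(MASS::glmmPQL(
    model_formula("water_column"), random = ~1 | seal_id, family = binomial,
    data = d, correlation = nlme::corCAR1(form = ~t_hours | seal_id),
    verbose = FALSE))
  ref <- nlme::fixef(g)[f$coefficients$term]
  se_ref <- sqrt(diag(vcov(g)))[f$coefficients$term]
  # the two PQL variants stop at slightly different points; agreement is
  # asserted relative to the coefficient uncertainty
  expect_lt(max(abs(f$coefficients$estimate - ref) / se_ref), 0.2)
  expect_equal(f$coefficients$std.error, unname(se_ref), tolerance = 0.2)
  expect_equal(f$sigma, g$sigma, tolerance = 0.05)
})

test_that("null simulations are calibrated: |coef| < 2 SE almost always", {
  null_coefs <- water_column_truth() * 0
  cover <- sapply(1:15, function(r) {
    sim <- simulate_glmm_dataset(null_coefs, "water_column", n_seals = 15,
                                 n_obs_per_seal = 80, re_sd = 0.3,
                                 rho_step = 0.3, seed = 600 + r)
    f <- fit_pql_glmm(sim$observations, "water_column")
    mean(abs(f$coefficients$estimate) < 2 * f$coefficients$std.error)
  })
  expect_gte(mean(cover), 0.9)
})

test_that("odds-ratio table is the exact exponential of the coefficients", {
  sim <- simulate_glmm_dataset(n_seals = 6, n_obs_per_seal = 60, seed = 8)
  f <- fit_pql_glmm(sim$observations, "water_column")
  or <- odds_ratio_table(f)
  expect_equal(or$or, exp(f$coefficients$estimate))
  expect_equal(or$ci_lo, exp(f$coefficients$estimate - 1.96 * f$coefficients$std.error))
  expect_equal(or$ci_hi, exp(f$coefficients$estimate + 1.96 * f$coefficients$std.error))
})

test_that("the published sex coefficient exponentiates to the published OR", {
  # 1.40 (0.36) -> OR 4.06 [2.00, 8.21]; table prints 4.07 [2.02, 8.17]
  # (difference is rounding of the coefficient before exponentiation)
  expect_equal(exp(1.40), 4.0552, tolerance = 1e-4)
  expect_equal(exp(1.40 - 1.96 * 0.36), 2.003, tolerance = 1e-3)
  expect_equal(exp(1.40 + 1.96 * 0.36), 8.2098, tolerance = 1e-3)
})

test_that("between-seal terms get containment degrees of freedom", {
  sim <- simulate_glmm_dataset(n_seals = 10, n_obs_per_seal = 50, seed = 10)
  f <- fit_pql_glmm(sim$observations, "water_column")
  co <- f$coefficients
  expect_equal(unname(co$df[co$term == "sexF"]), 10 - 2)
  expect_true(all(co$df[co$term %in% c("chl", "T50")] ==
                    f$n_obs - f$n_groups - (nrow(co) - 2)))
})

# ---- observation assembly -------------------------------------------------

make_states <- function(times, states, seal = "seal_01") {
  tibble::tibble(
    seal_id = seal, segment = 1L, timestamp = times,
    x_km = 0, y_km = 0,
    state = factor(states, levels = c("travelling", "foraging")),
    p_forage = as.numeric(states == "foraging")
  )
}

make_env_row <- function(seal, end, chla = NA, T50 = 8, depth = 60, temp = 6,
                         dur = 120) {
  tibble::tibble(
    seal_id = seal, dive_id = 1L,
    dive_start = end - 300, dive_end = end,
    T50 = T50, la_per_m = 0.1, chla_mg_m3 = chla,
    mld_m = NA_real_, mld_bottom_limited = FALSE,
    bot_depth_m = depth, bot_temp_c = temp, bot_dur_s = dur,
    max_depth_m = depth + 5, noon = !is.na(chla)
  )
}

test_that("season assignment and January exclusion follow the calendar rules", {
  times <- t_utc(c("2014-07-10 12:00:00", "2014-10-10 12:00:00",
                   "2015-01-05 12:00:00"))
  st <- make_states(times, c("foraging", "travelling", "foraging"))
  env <- dplyr::bind_rows(lapply(times, function(tm) {
    make_env_row("seal_01", tm - 600, chla = 1)
  }))
  meta <- tibble::tibble(seal_id = "seal_01", sex = "F")
  obs <- assemble_observations(st, env, meta, "water_column")
  expect_equal(nrow(obs), 2)
  expect_equal(as.character(obs$season), c("summer", "fall"))
  expect_equal(attr(obs, "n_dropped"), 1L)
})

test_that("covariates are medians over dives ending in the step window", {
  tm <- t_utc("2014-07-10 12:00:00")
  st <- make_states(tm, "foraging")
  env <- dplyr::bind_rows(
    make_env_row("seal_01", tm - 3600, chla = NA, depth = 30, dur = 100),
    make_env_row("seal_01", tm - 600, chla = 2, depth = 60, dur = 200),
    make_env_row("seal_01", tm + 600, chla = 9, depth = 90, dur = 900),  # future
    make_env_row("seal_01", tm - 4 * 3600, chla = 9, depth = 90, dur = 900)  # too old
  )
  meta <- tibble::tibble(seal_id = "seal_01", sex = "M")
  # water-column model: only the >= 50 m noon dive has chla
  m1 <- assemble_observations(st, env, meta, "water_column")
  expect_equal(m1$chl, 2)
  # bottom model: medians over both in-window dives
  m2 <- assemble_observations(st, env, meta, "bottom_conditions")
  expect_equal(m2$bot_depth, 45)
  expect_equal(m2$bot_dur, 150)
  expect_equal(m2$log_bot_depth, log(45))
})

test_that("unknown sex is a hard error and missing covariates are counted", {
  tm <- t_utc("2014-07-10 12:00:00")
  st <- make_states(tm, "foraging")
  env <- make_env_row("seal_01", tm - 600, chla = NA)
  expect_error(
    assemble_observations(st, env, tibble::tibble(seal_id = "seal_01", sex = "X"),
                          "water_column"),
    "sex")
  obs <- assemble_observations(st, env,
                               tibble::tibble(seal_id = "seal_01", sex = "F"),
                               "water_column")
  expect_equal(nrow(obs), 0)
  expect_equal(attr(obs, "n_dropped"), 1L)
})
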