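#' Simulate behavioural-state observations from an association model
#'
#' Generates ready-made observation tables for the binomial association
#' models with known ground truth. Each individual gets a deployment window
#' (random start between 1 June and 30 November, observations every
#' `step_hours` on that clock, so both summer and fall occur across
#' individuals), covariates drawn from documented distributions, a Gaussian
#' random intercept, and CAR(1)-correlated latent Gaussian noise; the linear
#' predictor follows the requested model's fixed-effect structure and states
#' are Bernoulli draws through the logit link.
#'
#' Covariate distributions: chlorophyll-a ~ lognormal(meanlog log 1, sdlog
#' 0.6) mg m^-3; T50 ~ Normal(8, 3) degC; bottom duration ~ Normal(180, 80) s
#' truncated at 10 s; bottom temperature ~ Normal(6, 3) degC; bottom depth ~
#' lognormal(log 80, 0.5) m (entering the model as its natural log). Sexes
#' alternate so any even number of seals is exactly half female.
#'
#' @param coefs named coefficient vector on the logit scale; names must match
#'   the model design-matrix columns (see [water_column_truth()],
#'   [bottom_conditions_truth()]).
#' @param model `"water_column"` or `"bottom_conditions"`.
#' @param n_seals,n_obs_per_seal numbers of individuals and observations each.
#' @param re_sd SD of the per-individual random intercept (logit scale).
#' @param rho_step latent-noise correlation between observations one step
#'   apart (the per-hour base is `rho_step^(1/step_hours)`); `|rho_step| < 1`.
#' @param noise_sd stationary SD of the CAR(1) latent noise (logit scale).
#' @param step_hours observation spacing (hours).
#' @param seed integer seed.
#' @return list with `observations` (tibble: `seal_id`, `time`, `t_hours`,
#'   `y`, covariates, `sex`, `season`) and `truth` (generative parameters and
#'   per-seal intercepts).
#' @export
#' @examples
#' sim <- simulate_glmm_dataset(n_seals = 4, n_obs_per_seal = 50, seed = 1)
#' head(sim$observations)
simulate_glmm_dataset <- function(coefs = water_column_truth(),
                                  model = c("water_column", "bottom_conditions"),
                                  n_seals = 40, n_obs_per_seal = 200,
                                  re_sd = 0.5, rho_step = 0.5,
                                  noise_sd = 0.5,
                                  step_hours = 3, seed = 1L) {
  model <- match.arg(model)
  if (abs(rho_step) >= 1) abort("|rho_step| must be < 1")
  set.seed(as.integer(seed))
  n <- n_obs_per_seal

  obs <- purrr::map(seq_len(n_seals), function(i) {
    sex <- factor(if (i %% 2 == 1) "F" else "M", levels = c("M", "F"))
    start <- as.POSIXct("2014-06-01 00:00:00", tz = "UTC") +
      runif(1, 0, 182) * 86400
    time <- start + (seq_len(n) - 1) * step_hours * 3600
    df <- tibble::tibble(
      seal_id = sprintf("seal_%02d", i),
      time = time,
      t_hours = (seq_len(n) - 1) * step_hours,
      sex = sex,
      season = season_of(time),
      chl = stats::rlnorm(n, log(1), 0.6),
      T50 = rnorm(n, 8, 3),
      bot_dur = pmax(10, rnorm(n, 180, 80)),
      bot_temp = rnorm(n, 6, 3),
      bot_depth = stats::rlnorm(n, log(80), 0.5)
    )
    df$log_bot_depth <- log(df$bot_depth)
    df
  }) |> dplyr::bind_rows()
  # December overruns can reach January; those months are not modelled
  obs <- obs[!is.na(obs$season), ]
  obs <- dplyr::arrange(obs, .data$seal_id, .data$t_hours)

  obs$y <- 0  # placeholder so model.matrix can be built
  X <- build_design(model_formula(model), obs)
  if (!setequal(names(coefs), colnames(X))) {
    abort(sprintf("coefs names must match the %s design: %s",
                  model, paste(colnames(X), collapse = ", ")))
  }
  beta <- coefs[colnames(X)]

  nu <- rnorm(n_seals, 0, re_sd)
  names(nu) <- sprintf("seal_%02d", seq_len(n_seals))

  # CAR(1) latent noise per seal: AR(1) on the regular step grid
  eps <- unlist(lapply(split(seq_len(nrow(obs)), obs$seal_id), function(idx) {
    m <- length(idx)
    e <- numeric(m)
    e[1] <- rnorm(1, 0, noise_sd)
    if (m > 1) for (t in 2:m) {
      e[t] <- rho_step * e[t - 1] + rnorm(1, 0, noise_sd * sqrt(1 - rho_step^2))
    }
    e
  }))
  # split() orders by seal_id, matching the sorted observation order
  eta <- drop(X %*% beta) + nu[obs$seal_id] + eps
  obs$y <- rbinom(nrow(obs), 1, plogis(eta))

  list(
    observations = obs,
    truth = list(coefs = beta, re_sd = re_sd, rho_step = rho_step,
                 noise_sd = noise_sd, seal_effects = nu, model = model)
  )
}
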