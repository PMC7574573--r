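# DCRW HMM: likelihood, decoding, fitting

test_that("forward log-likelihood matches exhaustive enumeration (T = 6)", {
  set.seed(31)
  for (i in 1:10) {
    params <- random_dcrw_params()
    trk <- random_walk_track(8)  # 7 displacements, 6 modelled
    d <- cbind(diff(trk$x_km), diff(trk$y_km))
    expect_equal(dcrw_loglik(trk, params), bf_forward_loglik(d, params),
                 tolerance = 1e-10)
  }
})

test_that("identical states collapse to the single-state Gaussian likelihood", {
  set.seed(32)
  params <- dcrw_params(theta = c(0.4, 0.4), gamma = c(0.6, 0.6),
                        sigma = c(1.2, 1.2))
  trk <- random_walk_track(30)
  d <- cbind(diff(trk$x_km), diff(trk$y_km))
  n <- nrow(d)
  mu <- params$gamma[1] * sealforage:::rotate_xy(d[-n, 1], d[-n, 2], params$theta[1])
  direct <- sum(dnorm(d[-1, 1], mu[, 1], params$sigma[1], log = TRUE) +
                dnorm(d[-1, 2], mu[, 2], params$sigma[1], log = TRUE))
  expect_equal(dcrw_loglik(trk, params), direct, tolerance = 1e-10)
})

test_that("a degenerate chain pins the likelihood to one state's density", {
  set.seed(33)
  params <- random_dcrw_params()
  params$A <- diag(2)
  params$delta <- c(1, 0)
  trk <- random_walk_track(25)
  d <- cbind(diff(trk$x_km), diff(trk$y_km))
  n <- nrow(d)
  mu <- params$gamma[1] * sealforage:::rotate_xy(d[-n, 1], d[-n, 2], params$theta[1])
  direct <- sum(dnorm(d[-1, 1], mu[, 1], params$sigma[1], log = TRUE) +
                dnorm(d[-1, 2], mu[, 2], params$sigma[1], log = TRUE))
  expect_equal(dcrw_loglik(trk, params), direct, tolerance = 1e-10)
  # and decoding returns that state everywhere
  params$delta <- c(0, 1)
  dec <- decode_states(trk, params)
  expect_true(all(dec$state == "foraging"))
})

test_that("the likelihood is invariant to state relabelling", {
  set.seed(34)
  for (i in 1:5) {
    params <- random_dcrw_params()
    swapped <- dcrw_params(params$theta[2:1], params$gamma[2:1],
                           params$sigma[2:1], params$A[2:1, 2:1],
                           params$delta[2:1])
    trk <- random_walk_track(40)
    expect_equal(dcrw_loglik(trk, params), dcrw_loglik(trk, swapped),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi path matches exhaustive argmax (T = 8)", {
  set.seed(35)
  for (i in 1:8) {
    params <- random_dcrw_params()
    trk <- random_walk_track(10)  # 8 modelled displacements
    d <- cbind(diff(trk$x_km), diff(trk$y_km))
    dec <- decode_states(trk, params)
    expect_equal(as.integer(dec$state), bf_viterbi(d, params))
  }
})

test_that("forward-backward posteriors sum to one at every step", {
  set.seed(36)
  params <- random_dcrw_params()
  trk <- random_walk_track(60)
  d <- cbind(diff(trk$x_km), diff(trk$y_km))
  post <- sealforage:::hmm_posteriors_cpp(
    sealforage:::dcrw_logdens(d, params), params$A, params$delta)
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-12)
})

test_that("multi-segment tracks sum their segment log-likelihoods", {
  set.seed(37)
  params <- random_dcrw_params()
  t1 <- random_walk_track(15)
  t2 <- random_walk_track(12)
  t2$segment <- 2L
  both <- dplyr::bind_rows(t1, t2)
  expect_equal(dcrw_loglik(both, params),
               dcrw_loglik(t1, params) + dcrw_loglik(t2, params),
               tolerance = 1e-10)
})

test_that("likelihood at the truth beats perturbed parameters on average", {
  cfg <- sim_config(track_steps = 300, seed = 41)
  truth <- dcrw_params(cfg$theta, cfg$gamma, cfg$step_sd, cfg$transition_matrix,
                       cfg$delta)
  diffs <- sapply(1:6, function(i) {
    trk <- as_regular_track(simulate_track(cfg, i))
    pert <- truth
    pert$gamma <- pmin(0.99, pmax(0.01, truth$gamma + c(-0.15, 0.15)))
    pert$sigma <- truth$sigma * 1.3
    dcrw_loglik(trk, truth) - dcrw_loglik(trk, pert)
  })
  expect_gt(mean(diffs), 0)
})

test_that("fitting recovers generative parameters and wraps angles", {
  # tortuous state simulated at theta = pi: the reversal convention
  cfg <- sim_config(track_steps = 1000, theta = c(0, pi), seed = 42)
  trk <- as_regular_track(simulate_track(cfg, 1))
  fit <- fit_hmm(trk, n_restarts = 6, seed = 1)
  expect_true(fit$convergence)
  expect_lt(abs(fit$params$gamma[1] - 0.9), 0.05)
  expect_lt(abs(fit$params$gamma[2] - 0.2), 0.1)
  expect_lt(abs(wrap_angle(fit$params$theta[1])), 0.15)
  expect_lt(abs(abs(wrap_angle(fit$params$theta[2])) - pi), 0.4)
  # theta is reported inside (-pi, pi]
  expect_true(all(fit$params$theta > -pi & fit$params$theta <= pi))
  # determinism: same data, same seed, same fit
  fit2 <- fit_hmm(trk, n_restarts = 6, seed = 1)
  expect_identical(tidy(fit), tidy(fit2))
  # travelling state is labelled by the larger autocorrelation
  expect_gt(fit$params$gamma[1], fit$params$gamma[2])
})

test_that("tracks that are too short or non-finite are rejected", {
  trk <- random_walk_track(20)
  expect_error(fit_hmm(trk, n_restarts = 2, seed = 1, min_disp = 50), "displacements")
  trk$x_km[3] <- NA
  expect_error(dcrw_loglik(trk, random_dcrw_params()), "finite")
})
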