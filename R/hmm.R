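# Two-state first-difference correlated random walk (DCRW) hidden Markov
# model. Conditional on the state s_t, each displacement is a rotated,
# damped copy of the previous one plus isotropic Gaussian noise:
#   d_t | d_{t-1}, s_t ~ N2(gamma_{s_t} R(theta_{s_t}) d_{t-1},
#                           sigma_{s_t}^2 I).
# The first displacement of every segment is conditioned on, not modelled,
# so a segment of n positions contributes n - 2 modelled displacements.

#' DCRW hidden-Markov-model parameters
#'
#' @param theta per-state mean turning angle (rad), wrapped to (-pi, pi].
#' @param gamma per-state autocorrelation in direction and speed, in (0, 1):
#'   near 1 is persistent directed travel, near 0 uncorrelated tortuous
#'   movement.
#' @param sigma per-state process noise SD (km), > 0.
#' @param A 2x2 row-stochastic transition matrix.
#' @param delta initial state distribution.
#' @return object of class `dcrw_params`.
#' @export
dcrw_params <- function(theta, gamma, sigma,
                        A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                        delta = c(0.5, 0.5)) {
  stopifnot(length(theta) == 2, length(gamma) == 2, length(sigma) == 2)
  if (any(gamma <= 0 | gamma >= 1)) abort("gamma must be strictly inside (0, 1)")
  if (any(sigma <= 0)) abort("sigma must be > 0")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) {
    abort("A must be row-stochastic")
  }
  if (any(delta < 0) || abs(sum(delta) - 1) > 1e-8) {
    abort("delta must be a probability vector")
  }
  structure(list(theta = wrap_angle(theta), gamma = gamma, sigma = sigma,
                 A = A, delta = delta),
            class = "dcrw_params")
}

# displacement matrices per (seal, segment); each with >= 3 positions
track_displacements <- function(track) {
  assert_cols(track, c("seal_id", "segment", "x_km", "y_km"), "track")
  if (any(!is.finite(track$x_km)) || any(!is.finite(track$y_km))) {
    abort("track contains non-finite positions")
  }
  segs <- split(track, interaction(track$seal_id, track$segment, drop = TRUE))
  disp <- lapply(segs, function(s) {
    if (nrow(s) < 3) return(NULL)
    cbind(dx = diff(s$x_km), dy = diff(s$y_km))
  })
  disp[!vapply(disp, is.null, logical(1))]
}

# T-1 x 2 matrix of state-conditional log densities for one segment's
# displacements (rows are modelled displacements 2..T)
dcrw_logdens <- function(d, params) {
  n <- nrow(d)
  prev <- d[-n, , drop = FALSE]
  cur <- d[-1, , drop = FALSE]
  ld <- matrix(0, n - 1, 2)
  for (k in 1:2) {
    mu <- params$gamma[k] * rotate_xy(prev[, 1], prev[, 2], params$theta[k])
    ld[, k] <- dnorm(cur[, 1], mu[, 1], params$sigma[k], log = TRUE) +
      dnorm(cur[, 2], mu[, 2], params$sigma[k], log = TRUE)
  }
  ld
}

#' Marginal log-likelihood of a regular track under the two-state DCRW
#'
#' Computed by the forward algorithm over the hidden state sequence; tracks
#' with several segments contribute the sum of their segment log-likelihoods,
#' each restarted from the initial state distribution `delta`.
#'
#' @param track regular track from [regularize_track()] (columns `seal_id`,
#'   `segment`, `x_km`, `y_km`).
#' @param params a [dcrw_params()].
#' @return log-likelihood (scalar).
#' @export
dcrw_loglik <- function(track, params) {
  disp <- track_displacements(track)
  if (!length(disp)) abort("no segment with >= 3 positions")
  sum(vapply(disp, function(d) {
    hmm_forward_cpp(dcrw_logdens(d, params), params$A, params$delta)
  }, numeric(1)))
}

par_to_params <- function(par) {
  dcrw_params(
    theta = par[1:2],
    gamma = plogis(par[3:4]),
    sigma = exp(par[5:6]),
    A = rbind(c(plogis(par[7]), 1 - plogis(par[7])),
              c(1 - plogis(par[8]), plogis(par[8]))),
    delta = c(plogis(par[9]), 1 - plogis(par[9]))
  )
}

#' Fit the two-state DCRW HMM by maximum likelihood
#'
#' Maximises the forward-algorithm likelihood by BFGS over unconstrained
#' transforms (logit for `gamma`, diagonal of `A` and `delta`; log for
#' `sigma`; `theta` free and wrapped afterwards). Because the likelihood
#' surface has label-switching and rotational local optima, the best of
#' `n_restarts` dispersed starts is kept: turning-angle starts cover both the
#' straight-ahead and reversal conventions, autocorrelation starts bracket
#' the travelling/foraging split. States are labelled so the state with the
#' larger fitted `gamma` is "travelling".
#'
#' @param track regular track ([regularize_track()] output).
#' @param n_restarts number of dispersed optimisation starts.
#' @param seed RNG seed for start dispersion.
#' @param min_disp minimum total modelled displacements required.
#' @return object of class `dcrw_hmm`: fitted [dcrw_params()], `loglik`,
#'   decoded `states` tibble (see [decode_states()]), `convergence` flag and
#'   `n_restarts_used`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_hmm <- function(track, n_restarts = 10, seed = 1L, min_disp = 50) {
  disp <- track_displacements(track)
  if (!length(disp)) abort("no segment with >= 3 positions")
  n_mod <- sum(vapply(disp, nrow, integer(1)) - 1)
  if (n_mod < min_disp) {
    abort(sprintf("only %d modelled displacements; need >= %d", n_mod, min_disp))
  }
  negll <- function(par) {
    p <- tryCatch(par_to_params(par), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- sum(vapply(disp, function(d) {
      hmm_forward_cpp(dcrw_logdens(d, p), p$A, p$delta)
    }, numeric(1)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  set.seed(as.integer(seed))
  scale_guess <- stats::sd(unlist(lapply(disp, as.numeric)))
  starts <- lapply(seq_len(n_restarts), function(r) {
    c(rnorm(1, 0, 0.2),
      (if (r %% 2 == 0) pi else 0) + rnorm(1, 0, 0.2),
      qlogis(0.8) + rnorm(1, 0, 0.4),
      qlogis(0.3) + rnorm(1, 0, 0.4),
      log(scale_guess) + rnorm(1, 0, 0.3),
      log(scale_guess * 0.6) + rnorm(1, 0, 0.3),
      qlogis(0.85) + rnorm(1, 0, 0.3),
      qlogis(0.85) + rnorm(1, 0, 0.3),
      0)
  })
  fits <- lapply(starts, function(s) {
    tryCatch(optim(s, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) abort("all optimisation restarts failed")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  conv <- vapply(fits, `[[`, integer(1), "convergence") == 0L
  best_among <- if (any(conv)) which(conv)[which.min(vals[conv])] else which.min(vals)
  best <- fits[[best_among]]
  if (!any(conv)) warn("no restart converged; returning best incomplete fit")

  params <- par_to_params(best$par)
  # label states: larger gamma = travelling (state 1)
  if (params$gamma[1] < params$gamma[2]) {
    perm <- c(2, 1)
    params <- dcrw_params(params$theta[perm], params$gamma[perm],
                          params$sigma[perm], params$A[perm, perm],
                          params$delta[perm])
  }
  params$theta <- wrap_angle(params$theta)

  states <- decode_states(track, params)
  structure(list(
    params = params,
    loglik = -best$value,
    states = states,
    convergence = any(conv),
    n_restarts_used = length(fits),
    n_displacements = n_mod
  ), class = "dcrw_hmm")
}

#' Decode behavioural states along a track
#'
#' Returns both the jointly most probable state path (Viterbi) and the
#' per-step forward-backward posterior probability of the apparent-foraging
#' state. Decoded steps are the modelled displacements, labelled with the
#' timestamp of the position each displacement arrives at.
#'
#' @param track regular track ([regularize_track()] output).
#' @param params fitted [dcrw_params()] (state 1 = travelling).
#' @return tibble: `seal_id`, `segment`, `timestamp`, `x_km`, `y_km`,
#'   `state` (factor travelling/foraging), `p_forage`.
#' @export
decode_states <- function(track, params) {
  segs <- split(track, interaction(track$seal_id, track$segment, drop = TRUE))
  out <- lapply(segs, function(s) {
    if (nrow(s) < 3) return(NULL)
    d <- cbind(diff(s$x_km), diff(s$y_km))
    ld <- dcrw_logdens(d, params)
    path <- hmm_viterbi_cpp(ld, params$A, params$delta)
    post <- hmm_posteriors_cpp(ld, params$A, params$delta)
    tibble::tibble(
      seal_id = s$seal_id[1], segment = s$segment[1],
      timestamp = s$timestamp[-(1:2)],
      x_km = s$x_km[-(1:2)], y_km = s$y_km[-(1:2)],
      state = factor(c("travelling", "foraging")[path],
                     levels = c("travelling", "foraging")),
      p_forage = post[, 2]
    )
  })
  dplyr::bind_rows(out)
}

#' @export
print.dcrw_hmm <- function(x, ...) {
  cat("Two-state DCRW hidden Markov model\n")
  cat(sprintf("log-likelihood %.2f over %d displacements (%s)\n",
              x$loglik, x$n_displacements,
              if (x$convergence) "converged" else "NOT converged"))
  p <- x$params
  cat(sprintf("  travelling: theta % .3f  gamma %.3f  sigma %.3f km\n",
              p$theta[1], p$gamma[1], p$sigma[1]))
  cat(sprintf("  foraging:   theta % .3f  gamma %.3f  sigma %.3f km\n",
              p$theta[2], p$gamma[2], p$sigma[2]))
  cat("transition matrix:\n")
  print(round(p$A, 3))
  invisible(x)
}
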