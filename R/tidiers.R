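# broom-style methods for the two fitted-object classes

#' Tidy a fitted DCRW HMM
#'
#' @param x a [fit_hmm()] object.
#' @param ... unused.
#' @return tibble with one row per behavioural state: `state`, `theta`,
#'   `gamma`, `sigma`, and the self-transition probability `p_stay`.
#' @exportS3Method generics::tidy
tidy.dcrw_hmm <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    state = c("travelling", "foraging"),
    theta = p$theta,
    gamma = p$gamma,
    sigma = p$sigma,
    p_stay = diag(p$A)
  )
}

#' @rdname tidy.dcrw_hmm
#' @return for `glance()`: a one-row tibble with `logLik`, `n_displacements`,
#'   `n_parameters`, `converged`, `prop_foraging`.
#' @exportS3Method generics::glance
glance.dcrw_hmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_displacements = x$n_displacements,
    n_parameters = 9L,
    converged = x$convergence,
    prop_foraging = mean(x$states$state == "foraging")
  )
}

#' Tidy a PQL-fitted association model
#'
#' @param x a [fit_pql_glmm()] object.
#' @param exponentiate also append odds ratios and Wald 95% limits?
#' @param ... unused.
#' @return coefficient tibble (`term`, `estimate`, `std.error`, `statistic`,
#'   `df`, `p.value`, and with `exponentiate = TRUE` also `or`, `ci_lo`,
#'   `ci_hi`).
#' @exportS3Method generics::tidy
tidy.pql_glmm <- function(x, exponentiate = FALSE, ...) {
  if (exponentiate) odds_ratio_table(x) else x$coefficients
}

#' @rdname tidy.pql_glmm
#' @return for `glance()`: one-row tibble with `rho`, `re_sd`, `sigma`,
#'   `n_obs`, `n_groups`, `iterations`, `converged`.
#' @exportS3Method generics::glance
glance.pql_glmm <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, re_sd = x$re_sd, sigma = x$sigma,
    n_obs = x$n_obs, n_groups = x$n_groups,
    iterations = x$iterations, converged = x$converged
  )
}
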