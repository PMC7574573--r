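# fixtures and independent oracles used across the suite

t_utc <- function(s) as.POSIXct(s, tz = "UTC")

# build a tag-record tibble from a depth vector at fixed cadence
make_records <- function(depths, start = t_utc("2014-07-01 12:00:00"),
                         cadence = 10, temp = 8, ll = 150, wet = TRUE,
                         seal_id = "seal_01") {
  n <- length(depths)
  tibble::tibble(
    seal_id = seal_id,
    timestamp = start + (seq_len(n) - 1) * cadence,
    depth_m = depths,
    temp_c = rep_len(temp, n),
    ll = rep_len(ll, n),
    wet = rep_len(wet, n)
  )
}

# trapezoid depth sequence: linear descent, flat bottom, linear ascent,
# bracketed by surface samples
trapezoid_depths <- function(max_depth = 50, descent_s = 60, bottom_s = 120,
                             ascent_s = 60, cadence = 10) {
  tt <- seq(0, descent_s + bottom_s + ascent_s, by = cadence)
  ifelse(tt <= descent_s, max_depth * tt / descent_s,
  ifelse(tt <= descent_s + bottom_s, max_depth,
         pmax(0, max_depth * (1 - (tt - descent_s - bottom_s) / ascent_s))))
}

# one ready-made dive tibble (detected + phase-annotated) from a depth series
make_dive <- function(depths, ...) {
  rec <- make_records(c(0, depths, 0), ...)
  detect_dives(rec, min_depth = 0.5) |> split_phases()
}

# ---- brute-force HMM oracles (exhaustive enumeration over state paths) ----

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

bf_state_logdens <- function(d, params) {
  # same quantity as the package computes, but rebuilt here independently
  n <- nrow(d)
  ld <- matrix(NA_real_, n - 1, 2)
  for (t in 2:n) {
    for (k in 1:2) {
      th <- params$theta[k]; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      mu <- params$gamma[k] * as.numeric(R %*% d[t - 1, ])
      ld[t - 1, k] <- sum(dnorm(d[t, ], mu, params$sigma[k], log = TRUE))
    }
  }
  ld
}

bf_forward_loglik <- function(d, params) {
  ld <- bf_state_logdens(d, params)
  T_ <- nrow(ld)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  lp <- apply(paths, 1, function(s) {
    l <- log(params$delta[s[1]]) + ld[1, s[1]]
    if (T_ > 1) for (t in 2:T_) l <- l + log(params$A[s[t - 1], s[t]]) + ld[t, s[t]]
    l
  })
  logsumexp(lp)
}

bf_viterbi <- function(d, params) {
  ld <- bf_state_logdens(d, params)
  T_ <- nrow(ld)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  lp <- apply(paths, 1, function(s) {
    l <- log(params$delta[s[1]]) + ld[1, s[1]]
    if (T_ > 1) for (t in 2:T_) l <- l + log(params$A[s[t - 1], s[t]]) + ld[t, s[t]]
    l
  })
  as.integer(paths[which.max(lp), ])
}

random_dcrw_params <- function() {
  dcrw_params(
    theta = runif(2, -pi, pi),
    gamma = runif(2, 0.05, 0.95),
    sigma = runif(2, 0.5, 3),
    A = {
      a <- runif(2, 0.55, 0.95)
      rbind(c(a[1], 1 - a[1]), c(1 - a[2], a[2]))
    },
    delta = { p <- runif(1, 0.2, 0.8); c(p, 1 - p) }
  )
}

random_walk_track <- function(n, sd = 1, seal = "seal_01") {
  tibble::tibble(
    seal_id = seal, segment = 1L,
    timestamp = t_utc("2014-07-01 00:00:00") + (seq_len(n) - 1) * 10800,
    x_km = cumsum(rnorm(n, 0, sd)),
    y_km = cumsum(rnorm(n, 0, sd))
  )
}
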