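#' Configuration for sequential discounting EM (SDEM)
#'
#' @param beta Discounting rate in (0, 1); larger values weight recent
#'   observations more.
#' @param K Number of mixture components, integer \code{>= 1}.
#' @param gamma_smooth Mixing-weight smoothing constant (default 0.001).
#' @return An object of class \code{"sdem_config"}.
#' @export
sdem_config <- function(beta, K = 10, gamma_smooth = 0.001) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0, beta < 1,
            length(K) == 1, K >= 1, K == as.integer(K),
            gamma_smooth > 0)
  structure(list(beta = beta, K = as.integer(K),
                 gamma_smooth = gamma_smooth),
            class = "sdem_config")
}

#' Initialize an SDEM state
#'
#' Raw mixing weights start uniform (\code{1/K}); the discounted weighted
#' sufficient statistics are initialized as \code{mu_tilde = pi_tilde * mu0}
#' and \code{sigma2_tilde = pi_tilde * sigma2_0} so the ratio identities
#' \code{mu = mu_tilde/pi_tilde}, \code{sigma2 = sigma2_tilde/pi_tilde}
#' hold from the first step.
#'
#' @param config An [sdem_config()].
#' @param mu0 Initial component means, recycled to length \code{K}.
#' @param sigma2_0 Initial component variances, recycled to length \code{K}.
#' @return An object of class \code{"sdem_state"}.
#' @export
sdem_init <- function(config, mu0 = 2.5, sigma2_0 = 0.05) {
  stopifnot(inherits(config, "sdem_config"))
  K <- config$K
  mu <- rep_len(as.numeric(mu0), K)
  sigma2 <- rep_len(as.numeric(sigma2_0), K)
  stopifnot(all(is.finite(mu)), all(sigma2 > 0))
  pi_tilde <- rep(1 / K, K)
  structure(list(config = config,
                 pi_tilde = pi_tilde, pi = pi_tilde,
                 mu_tilde = pi_tilde * mu, sigma2_tilde = pi_tilde * sigma2,
                 mu = mu, sigma2 = sigma2,
                 q = rep(NA_real_, K), t = 1L),
            class = "sdem_state")
}

#' SDEM E-step responsibilities
#'
#' \eqn{q_k = \pi_k N(d \mid \mu_k, \Sigma_k) / \sum_j \pi_j N(d \mid
#' \mu_j, \Sigma_j)}.
#'
#' @param state An \code{"sdem_state"}.
#' @param d Observation.
#' @return Probability vector of length \code{K}.
#' @export
sdem_responsibilities <- function(state, d) {
  stopifnot(inherits(state, "sdem_state"), is.finite(d))
  f <- .floor_dens(stats::dnorm(d, state$mu, sqrt(state$sigma2)))
  w <- state$pi * f
  w / sum(w)
}

#' Advance SDEM by one observation
#'
#' E-step responsibilities, then discounted M-step: raw weights and the
#' weighted sufficient statistics are convex combinations with rate
#' \code{beta} (the squared deviation uses the pre-update mean), component
#' parameters are recovered as ratios, and mixing weights are smoothed
#' with \code{gamma_smooth} and renormalized.  \code{K = 1} reduces exactly
#' to the exponential moving average.
#'
#' @param state An \code{"sdem_state"}.
#' @param d Observation.
#' @return List with \code{state} (updated) and \code{estimate}, the
#'   post-update \code{c(mu, sigma2)} of the component with the highest
#'   responsibility.
#' @export
sdem_step <- function(state, d) {
  q <- sdem_responsibilities(state, d)
  cfg <- state$config
  b <- cfg$beta
  state$q <- q
  state$pi_tilde <- (1 - b) * state$pi_tilde + b * q
  state$mu_tilde <- (1 - b) * state$mu_tilde + b * q * d
  state$sigma2_tilde <- (1 - b) * state$sigma2_tilde +
    b * q * (d - state$mu)^2
  state$mu <- state$mu_tilde / state$pi_tilde
  state$sigma2 <- pmax(state$sigma2_tilde / state$pi_tilde, .VAR_FLOOR)
  state$pi <- (state$pi_tilde + cfg$gamma_smooth) /
    (cfg$K * cfg$gamma_smooth + sum(state$pi_tilde))
  state$t <- state$t + 1L
  j <- which.max(q)
  list(state = state,
       estimate = c(mu = state$mu[j], sigma2 = state$sigma2[j]))
}

#' Run SDEM over a whole stream
#'
#' @param state An \code{"sdem_state"}.
#' @param d Numeric vector of observations.
#' @return List with \code{state} (final), \code{mu_hat}, \code{sigma2_hat}
#'   and \code{max_index} (per-step highest-responsibility component).
#' @export
sdem_filter <- function(state, d) {
  stopifnot(inherits(state, "sdem_state"), all(is.finite(d)))
  cfg <- state$config
  b <- cfg$beta
  g <- cfg$gamma_smooth
  K <- cfg$K
  pi_t <- state$pi_tilde; piw <- state$pi
  mu_t <- state$mu_tilde; s2_t <- state$sigma2_tilde
  mu <- state$mu; s2 <- state$sigma2
  T_len <- length(d)
  mu_hat <- numeric(T_len); s2_hat <- numeric(T_len)
  max_idx <- integer(T_len)
  q <- state$q
  for (t in seq_len(T_len)) {
    dt <- d[t]
    f <- stats::dnorm(dt, mu, sqrt(s2))
    f[f < .DENS_FLOOR] <- .DENS_FLOOR
    w <- piw * f
    q <- w / sum(w)
    pi_t <- (1 - b) * pi_t + b * q
    mu_t <- (1 - b) * mu_t + b * q * dt
    s2_t <- (1 - b) * s2_t + b * q * (dt - mu)^2
    mu <- mu_t / pi_t
    s2 <- pmax(s2_t / pi_t, .VAR_FLOOR)
    piw <- (pi_t + g) / (K * g + sum(pi_t))
    j <- which.max(q)
    mu_hat[t] <- mu[j]; s2_hat[t] <- s2[j]; max_idx[t] <- j
  }
  state$pi_tilde <- pi_t; state$pi <- piw
  state$mu_tilde <- mu_t; state$sigma2_tilde <- s2_t
  state$mu <- mu; state$sigma2 <- s2
  state$q <- q; state$t <- state$t + T_len
  list(state = state, mu_hat = mu_hat, sigma2_hat = s2_hat,
       max_index = max_idx)
}

#' Initialize an exponential moving average tracker
#'
#' @param beta Discount rate in (0, 1).
#' @param mu0 Initial mean.
#' @param sigma2_0 Initial variance (nonnegative).
#' @return An object of class \code{"ema_state"}.
#' @export
ema_init <- function(beta, mu0 = 2.5, sigma2_0 = 0.05) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0, beta < 1,
            is.finite(mu0), sigma2_0 >= 0)
  structure(list(beta = beta, mu = as.numeric(mu0),
                 sigma2 = as.numeric(sigma2_0), t = 1L),
            class = "ema_state")
}

#' Advance the EMA tracker by one observation
#'
#' The variance update uses the pre-update mean:
#' \eqn{\Sigma \leftarrow (1-\beta)\Sigma + \beta (d - \mu)^2}, then
#' \eqn{\mu \leftarrow (1-\beta)\mu + \beta d}.
#'
#' @param state An \code{"ema_state"}.
#' @param d Observation.
#' @return List with \code{state} (updated) and \code{estimate}
#'   \code{c(mu, sigma2)}.
#' @export
ema_step <- function(state, d) {
  stopifnot(inherits(state, "ema_state"), is.finite(d))
  b <- state$beta
  state$sigma2 <- (1 - b) * state$sigma2 + b * (d - state$mu)^2
  state$mu <- (1 - b) * state$mu + b * d
  state$t <- state$t + 1L
  list(state = state, estimate = c(mu = state$mu, sigma2 = state$sigma2))
}

#' Run the EMA tracker over a whole stream
#'
#' Implemented with a linear recursive filter; identical (to rounding) to
#' repeated [ema_step()] calls.
#'
#' @param state An \code{"ema_state"}.
#' @param d Numeric vector of observations.
#' @return List with \code{state} (final), \code{mu_hat} and
#'   \code{sigma2_hat}.
#' @export
ema_filter <- function(state, d) {
  stopifnot(inherits(state, "ema_state"), all(is.finite(d)))
  b <- state$beta
  T_len <- length(d)
  mu_hat <- numeric(T_len); s2_hat <- numeric(T_len)
  mu <- state$mu; s2 <- state$sigma2
  for (t in seq_len(T_len)) {
    s2 <- (1 - b) * s2 + b * (d[t] - mu)^2
    mu <- (1 - b) * mu + b * d[t]
    mu_hat[t] <- mu; s2_hat[t] <- s2
  }
  state$mu <- mu; state$sigma2 <- s2; state$t <- state$t + T_len
  list(state = state, mu_hat = mu_hat, sigma2_hat = s2_hat)
}
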