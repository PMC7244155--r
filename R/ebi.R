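#' Configuration for the extended Bayesian inference estimator
#'
#' @param alpha Weighting rate in \code{[0, 1]}; acts as both the forgetting
#'   rate (confidence update) and the learning rate (likelihood update)
#'   unless \code{forget_rate}/\code{learn_rate} are given separately.
#'   \code{alpha = 0} reduces EBI to standard Bayesian inference.
#' @param m Generalized-mean order used in the likelihood (learning) update;
#'   \code{m = 0} (default) is the geometric-mean limit.
#' @param K Number of hypotheses, integer \code{>= 1}.
#' @param epsilon Smoothing and clipping floor (default \code{1e-10}).
#' @param n Residual-window length for variance estimation; even integer
#'   (default 20).  The gamma shape parameter is \code{S = n/2}.
#' @param forget_rate,learn_rate Optional independent rates; both default to
#'   \code{alpha}.
#' @param delta_variance Which variance enters the normal-density normalizer
#'   \eqn{\Delta}, the clip bound and the mean inversion: \code{"post"}
#'   (default; the variance just updated by the gamma pass) or \code{"pre"}.
#' @return An object of class \code{"ebi_config"}.
#' @seealso [ebi_init()], [ebi_step()], [ebi_filter()]
#' @export
ebi_config <- function(alpha, m = 0, K = 10, epsilon = 1e-10, n = 20,
                       forget_rate = alpha, learn_rate = alpha,
                       delta_variance = c("post", "pre")) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
            is.numeric(m), length(m) == 1, is.finite(m),
            length(K) == 1, K >= 1, K == as.integer(K),
            is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0,
            length(n) == 1, n >= 2, n %% 2 == 0,
            forget_rate >= 0, forget_rate <= 1,
            learn_rate >= 0, learn_rate <= 1)
  delta_variance <- match.arg(delta_variance)
  structure(list(alpha = alpha, m = m, K = as.integer(K), epsilon = epsilon,
                 n = as.integer(n), S = n / 2,
                 forget_rate = forget_rate, learn_rate = learn_rate,
                 delta_variance = delta_variance),
            class = "ebi_config")
}

#' A single hypothesis model
#'
#' One hypothesis's normal model (mean \code{mu}, variance \code{sigma2}),
#' the gamma-model scale \code{lambda = 1/(2 sigma2)}, its window of squared
#' residuals and the count \code{n_k} of times it has been the
#' maximum-confidence hypothesis.
#'
#' @param mu Mean estimate.
#' @param sigma2 Variance estimate, positive.
#' @param n Residual-window capacity.
#' @return An object of class \code{"hypothesis_model"}.
#' @export
hypothesis_model <- function(mu, sigma2, n = 20) {
  stopifnot(is.finite(mu), is.finite(sigma2), sigma2 > 0)
  structure(list(mu = mu, sigma2 = sigma2, lambda = 1 / (2 * sigma2),
                 residuals = numeric(0), n_k = 0L, n = as.integer(n)),
            class = "hypothesis_model")
}

#' Initialize an EBI estimator state
#'
#' @param config An [ebi_config()].
#' @param mu0 Initial means, recycled to length \code{K}.
#' @param sigma2_0 Initial variances (positive), recycled to length \code{K}.
#' @param confidence Initial confidence vector; defaults to uniform
#'   \code{1/K}.
#' @return An object of class \code{"ebi_state"}.
#' @export
ebi_init <- function(config, mu0 = 2.5, sigma2_0 = 0.05, confidence = NULL) {
  stopifnot(inherits(config, "ebi_config"))
  K <- config$K
  mu <- rep_len(as.numeric(mu0), K)
  sigma2 <- rep_len(as.numeric(sigma2_0), K)
  stopifnot(all(is.finite(mu)), all(sigma2 > 0))
  if (is.null(confidence)) confidence <- rep(1 / K, K)
  stopifnot(length(confidence) == K, all(confidence > 0),
            abs(sum(confidence) - 1) < 1e-9)
  structure(list(config = config,
                 mu = mu, sigma2 = sigma2, lambda = 1 / (2 * sigma2),
                 resid = matrix(0, nrow = K, ncol = config$n),
                 n_k = integer(K),
                 confidence = as.numeric(confidence),
                 t = 1L, max_index = NA_integer_),
            class = "ebi_state")
}

#' @export
print.ebi_state <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("EBI state: K = %d, alpha = %g, m = %g, t = %d\n",
              cfg$K, cfg$alpha, cfg$m, x$t))
  cat("  confidence:", format(x$confidence, digits = 4), "\n")
  cat("  mu:        ", format(x$mu, digits = 4), "\n")
  cat("  sigma2:    ", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}

# density floor applied before any ratio; prevents 0/0 at extreme inputs
.DENS_FLOOR <- 1e-300
# variance floor after inversion
.VAR_FLOOR <- 1e-12

.floor_dens <- function(f) {
  f[f < .DENS_FLOOR] <- .DENS_FLOOR
  f
}

.conf_update <- function(confidence, mu, sigma2, d, forget_rate, epsilon) {
  f <- .floor_dens(stats::dnorm(d, mu, sqrt(sigma2)))
  s <- confidence^(1 - forget_rate) * f
  (s + epsilon) / (length(s) * epsilon + sum(s))
}

#' Confidence (posterior) update with forgetting
#'
#' Computes the smoothed confidence vector from unnormalized scores
#' \eqn{s_k = C(h_k)^{1-\alpha} N(d \mid \mu_k, \Sigma_k)}:
#' the returned vector is \eqn{(s_k + \epsilon) / (K\epsilon + \sum_j s_j)}.
#' The state itself is not modified.
#'
#' @param state An \code{"ebi_state"}.
#' @param d Observation (finite scalar).
#' @return Confidence vector of length \code{K}; entries positive, summing
#'   to 1.
#' @export
update_confidences <- function(state, d) {
  stopifnot(inherits(state, "ebi_state"), is.finite(d))
  out <- .conf_update(state$confidence, state$mu, state$sigma2, d,
                      state$config$forget_rate, state$config$epsilon)
  if (!all(is.finite(out)))
    stop("degenerate update: all scores zero with epsilon = 0")
  out
}

#' Select the maximum-confidence hypothesis
#'
#' Returns the index of the largest confidence; exact ties are broken
#' uniformly at random (consuming the R random number stream only when a
#' tie occurs).
#'
#' @param confidence Probability vector.
#' @return Integer index (1-based).
#' @export
select_max_hypothesis <- function(confidence) {
  if (length(confidence) == 0) stop("empty confidence vector")
  mx <- which(confidence == max(confidence))
  if (length(mx) > 1L) mx[sample.int(length(mx), 1L)] else mx
}

#' Post-update target likelihood for the max-confidence hypothesis
#'
#' The inverse-Bayesian learning target
#' \deqn{C^{t+1} = C_{max} F \left[(1-\alpha) C_{max}^{-m} +
#'   \alpha (\Delta \cdot mixture)^{-m}\right]^{1/m},}
#' which at \code{m = 0} reduces to the closed form
#' \eqn{\Delta^{-\alpha} (C_{max}/mixture)^{\alpha} F}, where \code{F} is
#' the current density of the datum under the max-confidence model and
#' \code{mixture} is the confidence-weighted density mixture over all
#' hypotheses.  \eqn{\Delta} converts densities to probability-like
#' quantities.
#'
#' @param C_max Confidence of the max hypothesis, in (0, 1].
#' @param mixture Confidence-weighted mixture of densities, positive.
#' @param current_density Density of the datum under the max hypothesis.
#' @param alpha Learning rate in \code{[0, 1]}.
#' @param Delta Density normalizer, positive.
#' @param m Generalized-mean order (default 0).
#' @return Positive target density.
#' @export
ebi_target_likelihood <- function(C_max, mixture, current_density, alpha,
                                  Delta, m = 0) {
  if (mixture <= 0) stop("degenerate update: mixture density is zero")
  stopifnot(C_max > 0, current_density > 0, Delta > 0,
            alpha >= 0, alpha <= 1)
  .target_likelihood(C_max, mixture, current_density, alpha, Delta, m)
}

.target_likelihood <- function(C_max, mixture, current_density, alpha,
                               Delta, m) {
  if (m == 0)
    return(Delta^(-alpha) * (C_max / mixture)^alpha * current_density)
  C_max * current_density *
    ((1 - alpha) * C_max^(-m) + alpha * (Delta * mixture)^(-m))^(1 / m)
}

#' Invert the normal density for its mean
#'
#' Given a target density value at datum \code{d} and a fixed variance,
#' solves \eqn{N(d \mid \mu, \Sigma) = target} for \eqn{\mu}.  The target is
#' first clipped into the solvable range
#' \eqn{[\epsilon, 1/\sqrt{2\pi\Sigma}]}; of the two roots
#' \eqn{d \pm \sqrt{-2\Sigma \log(target\sqrt{2\pi\Sigma})}} the one closer
#' to \code{mu_old} is returned (ties: the smaller root).
#'
#' @param d Datum.
#' @param target_likelihood Desired density value at \code{d}.
#' @param sigma2_new Variance, positive.
#' @param mu_old Previous mean (root-selection reference).
#' @param epsilon Lower clip for the target.
#' @return List with \code{mu} (new mean) and \code{likelihood} (the clipped
#'   target actually attained).
#' @export
invert_normal_mean <- function(d, target_likelihood, sigma2_new, mu_old,
                               epsilon = 1e-10) {
  stopifnot(is.finite(d), sigma2_new > 0, is.finite(mu_old))
  .invert_normal(d, target_likelihood, sigma2_new, mu_old, epsilon)
}

.invert_normal <- function(d, target_likelihood, sigma2_new, mu_old,
                           epsilon) {
  peak <- 1 / sqrt(2 * pi * sigma2_new)
  cl <- min(max(target_likelihood, epsilon), peak)
  arg <- -2 * sigma2_new * log(cl * sqrt(2 * pi * sigma2_new))
  off <- sqrt(max(arg, 0))
  mu1 <- d - off
  mu2 <- d + off
  mu <- if (abs(mu1 - mu_old) <= abs(mu2 - mu_old)) mu1 else mu2
  list(mu = mu, likelihood = cl)
}

#' Push a squared residual into a hypothesis's window
#'
#' Appends \eqn{(d - \mu_k)^2} (with the pre-update mean) to the circular
#' residual window, evicting the oldest entry when the window is full, and
#' increments the max-count \code{n_k}.  The windowed sum \code{D} is
#' returned only once the window holds exactly \code{n} entries.
#'
#' @param hyp A [hypothesis_model()].
#' @param d Datum.
#' @param n Window capacity (defaults to the model's own).
#' @return List with \code{hyp} (updated model) and \code{D} (windowed sum,
#'   or \code{NULL} during warm-up).
#' @export
push_residual <- function(hyp, d, n = hyp$n) {
  stopifnot(inherits(hyp, "hypothesis_model"))
  r <- (d - hyp$mu)^2
  if (length(hyp$residuals) < n) {
    hyp$residuals <- c(hyp$residuals, r)
  } else {
    hyp$residuals[hyp$n_k %% n + 1L] <- r
  }
  hyp$n_k <- hyp$n_k + 1L
  D <- if (length(hyp$residuals) == n) sum(hyp$residuals) else NULL
  list(hyp = hyp, D = D)
}

#' Invert the gamma density for its scale via the Lambert W function
#'
#' Given a target density value at windowed residual sum \code{D} and fixed
#' shape \code{S}, solves \eqn{f(D \mid \lambda, S) = target} for the scale
#' \eqn{\lambda}.  Writing \eqn{\Theta = -\lambda D / S} the equation
#' becomes \eqn{Z = \Theta e^{\Theta}} with
#' \eqn{Z = -(D \cdot target \cdot \Gamma(S))^{1/S} / S}, clipped into
#' \eqn{[-1/e, -\epsilon]}; the two Lambert branches
#' \eqn{W_{-1}(Z), W_0(Z)} give two candidate \eqn{\Theta}, and the branch
#' value nearer the reference \eqn{\Theta_{ref} = -\lambda_{old} D / S} is
#' taken.
#'
#' @param D Windowed squared-residual sum, positive.
#' @param target_likelihood Desired gamma density value at \code{D}.
#' @param S Shape parameter, positive.
#' @param lambda_old Previous scale (branch-selection reference).
#' @param epsilon Upper clip for \code{Z} (as \code{-epsilon}).
#' @return List with \code{lambda}, \code{sigma2} \eqn{= 1/(2\lambda)},
#'   \code{Z} (after clipping), \code{Theta}, and \code{clipped} (logical).
#' @export
invert_gamma_scale <- function(D, target_likelihood, S, lambda_old,
                               epsilon = 1e-10) {
  stopifnot(D > 0, S > 0, lambda_old > 0, target_likelihood > 0)
  .invert_gamma(D, target_likelihood, S, lambda_old, epsilon)
}

.invert_gamma <- function(D, target_likelihood, S, lambda_old, epsilon) {
  # log form avoids overflow of gamma(S) and extreme targets
  Zraw <- -exp((log(D) + log(target_likelihood) + lgamma(S)) / S) / S
  if (!is.finite(Zraw)) stop("non-finite Z in gamma inversion: D = ", D,
                             ", target = ", target_likelihood)
  Z <- max(min(Zraw, -epsilon), -1 / exp(1))
  th1 <- .lambert_wm1(Z)
  th2 <- .lambert_w0(Z)
  th_ref <- -lambda_old * D / S
  Theta <- if (abs(th1 - th_ref) <= abs(th2 - th_ref)) th1 else th2
  lambda <- -S * Theta / D
  list(lambda = lambda, sigma2 = 1 / (2 * lambda), Z = Z, Theta = Theta,
       clipped = !identical(Z, Zraw))
}

# one observation through the full EBI update; mutates environment `e`
# holding mu, sigma2, lambda, resid (K x n), n_k, confidence, t.
# Returns c(mu, sigma2) of the max-confidence hypothesis (post-update).
.ebi_kernel <- function(cfg, e, d) {
  conf <- .conf_update(e$confidence, e$mu, e$sigma2, d,
                       cfg$forget_rate, cfg$epsilon)
  e$confidence <- conf
  j <- select_max_hypothesis(conf)
  e$max_index <- j
  if (cfg$learn_rate > 0) {
    n <- cfg$n
    # residual uses the pre-update mean of the selected hypothesis
    pos <- if (e$n_k[j] < n) e$n_k[j] + 1L else e$n_k[j] %% n + 1L
    e$resid[j, pos] <- (d - e$mu[j])^2
    e$n_k[j] <- e$n_k[j] + 1L
    s2_pre <- e$sigma2[j]
    if (e$n_k[j] >= n) {
      D <- sum(e$resid[j, ])
      if (D > 0) {
        S <- cfg$S
        Delta_g <- exp(lgamma(S) + log(D) + S - S * log(S))
        fg <- .floor_dens(stats::dgamma(D, shape = S, rate = e$lambda))
        mix_g <- sum(conf * fg)
        tgt_g <- .target_likelihood(conf[j], mix_g, fg[j],
                                    cfg$learn_rate, Delta_g, cfg$m)
        gi <- .invert_gamma(D, tgt_g, S, e$lambda[j], cfg$epsilon)
        s2 <- gi$sigma2
        if (s2 < .VAR_FLOOR) s2 <- .VAR_FLOOR
        e$sigma2[j] <- s2
        e$lambda[j] <- 1 / (2 * s2)
      }
    }
    sig2 <- e$sigma2
    if (cfg$delta_variance == "pre") sig2[j] <- s2_pre
    fN <- .floor_dens(stats::dnorm(d, e$mu, sqrt(sig2)))
    mix_N <- sum(conf * fN)
    Delta_N <- sqrt(2 * pi * sig2[j])
    tgt_N <- .target_likelihood(conf[j], mix_N, fN[j],
                                cfg$learn_rate, Delta_N, cfg$m)
    e$mu[j] <- .invert_normal(d, tgt_N, sig2[j], e$mu[j],
                              cfg$epsilon)$mu
  }
  e$t <- e$t + 1L
  c(e$mu[j], e$sigma2[j])
}

.state_to_env <- function(state) {
  e <- new.env(parent = emptyenv())
  e$mu <- state$mu; e$sigma2 <- state$sigma2; e$lambda <- state$lambda
  e$resid <- state$resid; e$n_k <- state$n_k
  e$confidence <- state$confidence
  e$t <- state$t; e$max_index <- state$max_index
  e
}

.env_to_state <- function(e, config) {
  structure(list(config = config,
                 mu = e$mu, sigma2 = e$sigma2, lambda = e$lambda,
                 resid = e$resid, n_k = e$n_k,
                 confidence = e$confidence,
                 t = e$t, max_index = e$max_index),
            class = "ebi_state")
}

#' Advance the EBI estimator by one observation
#'
#' Executes, in order: the confidence update with forgetting; selection of
#' the maximum-confidence hypothesis (random tie-break); the residual-window
#' push; once the window is full, the gamma-model likelihood update and
#' Lambert-W scale inversion giving the new variance; the normal-model
#' likelihood update and mean inversion giving the new mean.  Only the
#' selected hypothesis's model changes.  With learning rate 0 the model
#' parameters are never touched and the update reduces to standard Bayesian
#' filtering.
#'
#' @param state An \code{"ebi_state"}.
#' @param d Observation (finite scalar).
#' @return List with \code{state} (updated) and \code{estimate}, the
#'   post-update \code{c(mu, sigma2)} of the max-confidence hypothesis.
#' @export
ebi_step <- function(state, d) {
  stopifnot(inherits(state, "ebi_state"), is.finite(d))
  e <- .state_to_env(state)
  est <- .ebi_kernel(state$config, e, d)
  list(state = .env_to_state(e, state$config),
       estimate = c(mu = est[1], sigma2 = est[2]))
}

#' Run the EBI estimator over a whole stream
#'
#' Online filtering: one [ebi_step()] per observation, with per-step
#' estimates collected.  Exactly equivalent to repeated \code{ebi_step}
#' calls, but avoids per-step state copying.
#'
#' @param state An \code{"ebi_state"}.
#' @param d Numeric vector of observations.
#' @param keep_confidence If \code{TRUE}, also return the T x K confidence
#'   trajectory.
#' @return List with \code{state} (final), \code{mu_hat}, \code{sigma2_hat},
#'   \code{max_index} (per-step selected hypothesis) and, optionally,
#'   \code{confidence}.
#' @export
ebi_filter <- function(state, d, keep_confidence = FALSE) {
  stopifnot(inherits(state, "ebi_state"), all(is.finite(d)))
  cfg <- state$config
  K <- cfg$K; n <- cfg$n; S <- cfg$S
  fr <- cfg$forget_rate; lr <- cfg$learn_rate; m <- cfg$m
  eps <- cfg$epsilon
  pre_delta <- cfg$delta_variance == "pre"
  learn <- lr > 0
  mu <- state$mu; sigma2 <- state$sigma2; lambda <- state$lambda
  sdv <- sqrt(sigma2)
  resid <- state$resid; n_k <- state$n_k
  conf <- state$confidence
  T_len <- length(d)
  mu_hat <- numeric(T_len); sigma2_hat <- numeric(T_len)
  max_idx <- integer(T_len)
  conf_tr <- if (keep_confidence) matrix(0, T_len, K) else NULL
  lgS <- lgamma(S)
  neg_inv_e <- -1 / exp(1)
  max_index <- state$max_index
  # the loop body repeats .ebi_kernel's arithmetic operation for operation
  # (same expressions, same order), with per-hypothesis standard deviations
  # cached across steps; equivalence with ebi_step is pinned by a test
  for (t in seq_len(T_len)) {
    dt <- d[t]
    f <- stats::dnorm(dt, mu, sdv)
    f[f < .DENS_FLOOR] <- .DENS_FLOOR
    s <- conf^(1 - fr) * f
    conf <- (s + eps) / (K * eps + sum(s))
    j <- which.max(conf)
    if (sum(conf == conf[j]) > 1L) {
      mx <- which(conf == conf[j])
      j <- mx[sample.int(length(mx), 1L)]
    }
    max_index <- j
    if (learn) {
      pos <- if (n_k[j] < n) n_k[j] + 1L else n_k[j] %% n + 1L
      resid[j, pos] <- (dt - mu[j])^2
      n_k[j] <- n_k[j] + 1L
      s2_pre <- sigma2[j]
      if (n_k[j] >= n) {
        D <- sum(resid[j, ])
        if (D > 0) {
          Delta_g <- exp(lgS + log(D) + S - S * log(S))
          fg <- stats::dgamma(D, shape = S, rate = lambda)
          fg[fg < .DENS_FLOOR] <- .DENS_FLOOR
          mix_g <- sum(conf * fg)
          tgt_g <- if (m == 0)
            Delta_g^(-lr) * (conf[j] / mix_g)^lr * fg[j]
          else
            conf[j] * fg[j] *
              ((1 - lr) * conf[j]^(-m) + lr * (Delta_g * mix_g)^(-m))^(1 / m)
          Zraw <- -exp((log(D) + log(tgt_g) + lgS) / S) / S
          if (!is.finite(Zraw))
            stop("non-finite Z in gamma inversion: D = ", D,
                 ", target = ", tgt_g)
          Z <- max(min(Zraw, -eps), neg_inv_e)
          th1 <- .lambert_wm1(Z)
          th2 <- .lambert_w0(Z)
          th_ref <- -lambda[j] * D / S
          Theta <- if (abs(th1 - th_ref) <= abs(th2 - th_ref)) th1 else th2
          s2 <- 1 / (2 * (-S * Theta / D))
          if (s2 < .VAR_FLOOR) s2 <- .VAR_FLOOR
          sigma2[j] <- s2
          lambda[j] <- 1 / (2 * s2)
          sdv[j] <- sqrt(s2)
        }
      }
      if (pre_delta) {
        sdm <- sdv; sdm[j] <- sqrt(s2_pre); s2j <- s2_pre
      } else {
        sdm <- sdv; s2j <- sigma2[j]
      }
      fN <- stats::dnorm(dt, mu, sdm)
      fN[fN < .DENS_FLOOR] <- .DENS_FLOOR
      mix_N <- sum(conf * fN)
      Delta_N <- sqrt(2 * pi * s2j)
      tgt_N <- if (m == 0)
        Delta_N^(-lr) * (conf[j] / mix_N)^lr * fN[j]
      else
        conf[j] * fN[j] *
          ((1 - lr) * conf[j]^(-m) + lr * (Delta_N * mix_N)^(-m))^(1 / m)
      peak <- 1 / sqrt(2 * pi * s2j)
      cl <- min(max(tgt_N, eps), peak)
      arg <- -2 * s2j * log(cl * sqrt(2 * pi * s2j))
      off <- sqrt(max(arg, 0))
      mu1 <- dt - off
      mu2 <- dt + off
      mu[j] <- if (abs(mu1 - mu[j]) <= abs(mu2 - mu[j])) mu1 else mu2
    }
    mu_hat[t] <- mu[j]
    sigma2_hat[t] <- sigma2[j]
    max_idx[t] <- j
    if (keep_confidence) conf_tr[t, ] <- conf
  }
  final <- structure(list(config = cfg, mu = mu, sigma2 = sigma2,
                          lambda = lambda, resid = resid, n_k = n_k,
                          confidence = conf, t = state$t + T_len,
                          max_index = max_index),
                     class = "ebi_state")
  out <- list(state = final, mu_hat = mu_hat, sigma2_hat = sigma2_hat,
              max_index = max_idx)
  if (keep_confidence) out$confidence <- conf_tr
  out
}
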