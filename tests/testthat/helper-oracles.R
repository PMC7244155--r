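# Independent scalar oracles coded directly from the update equations;
# deliberately share no code with the package internals.

# Standard Bayesian filter over fixed normal models (no learning), with the
# same additive-epsilon smoothing the estimator applies each step.
bayes_filter_oracle <- function(mu, sigma2, conf, d, epsilon = 1e-10) {
  K <- length(mu)
  out <- matrix(0, length(d), K)
  for (t in seq_along(d)) {
    post <- conf * stats::dnorm(d[t], mu, sqrt(sigma2))
    conf <- (post + epsilon) / (K * epsilon + sum(post))
    out[t, ] <- conf
  }
  out
}

# EMA recursion, one scalar at a time (variance first, with the old mean).
ema_oracle <- function(beta, mu0, sigma2_0, d) {
  mu <- mu0; s2 <- sigma2_0
  mu_tr <- s2_tr <- numeric(length(d))
  for (t in seq_along(d)) {
    s2 <- (1 - beta) * s2 + beta * (d[t] - mu)^2
    mu <- (1 - beta) * mu + beta * d[t]
    mu_tr[t] <- mu; s2_tr[t] <- s2
  }
  list(mu = mu_tr, sigma2 = s2_tr)
}

# SDEM recursion written out longhand for a short stream.
sdem_oracle <- function(beta, gam, mu, s2, d) {
  K <- length(mu)
  pi_t <- rep(1 / K, K)
  piw <- pi_t
  mu_t <- pi_t * mu
  s2_t <- pi_t * s2
  for (t in seq_along(d)) {
    f <- stats::dnorm(d[t], mu, sqrt(s2))
    q <- piw * f / sum(piw * f)
    pi_t <- (1 - beta) * pi_t + beta * q
    mu_t <- (1 - beta) * mu_t + beta * q * d[t]
    s2_t <- (1 - beta) * s2_t + beta * q * (d[t] - mu)^2
    mu <- mu_t / pi_t
    s2 <- s2_t / pi_t
    piw <- (pi_t + gam) / (K * gam + sum(pi_t))
  }
  list(pi_tilde = pi_t, pi = piw, mu = mu, sigma2 = s2, q = q)
}

# build an EBI state with fully specified fields (bypassing warm-up etc.)
make_ebi_state <- function(cfg, mu, sigma2, confidence,
                           resid = NULL, n_k = NULL) {
  st <- ebi_init(cfg, mu, sigma2, confidence)
  if (!is.null(resid)) st$resid <- resid
  if (!is.null(n_k)) st$n_k <- as.integer(n_k)
  st
}
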