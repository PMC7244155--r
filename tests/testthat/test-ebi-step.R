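test_that("one step matches an independent scalar computation (warm-up, K = 2)", {
  a <- 0.2; eps <- 1e-10
  mu <- c(1, 3); s2 <- c(0.5, 0.2); conf <- c(0.6, 0.4)
  d <- 1.5
  st <- make_ebi_state(ebi_config(alpha = a, K = 2, epsilon = eps),
                       mu, s2, conf)
  got <- ebi_step(st, d)

  # --- longhand recomputation ---
  f <- dnorm(d, mu, sqrt(s2))
  s <- conf^(1 - a) * f
  confN <- (s + eps) / (2 * eps + sum(s))
  j <- which.max(confN)
  # residual window not yet full: variance untouched, mean pass only
  fN <- dnorm(d, mu, sqrt(s2))
  mix <- sum(confN * fN)
  Delta <- sqrt(2 * pi * s2[j])
  tgt <- Delta^(-a) * (confN[j] / mix)^a * fN[j]
  cl <- min(max(tgt, eps), 1 / Delta)
  off <- sqrt(-2 * s2[j] * log(cl * Delta))
  roots <- c(d - off, d + off)
  mu_new <- roots[which.min(abs(roots - mu[j]))]

  expect_equal(got$state$confidence, confN, tolerance = 1e-12)
  expect_identical(got$state$max_index, j)
  expect_equal(got$state$mu[j], mu_new, tolerance = 1e-12)
  expect_equal(unname(got$estimate["mu"]), mu_new, tolerance = 1e-12)
  # untouched hypothesis is bit-identical
  k <- 3 - j
  expect_identical(got$state$mu[k], mu[k])
  expect_identical(got$state$sigma2, s2)  # no variance update in warm-up
  expect_identical(got$state$n_k[j], 1L)
  expect_identical(got$state$n_k[k], 0L)
})

test_that("one step with a full residual window matches the longhand gamma pass", {
  a <- 0.15; eps <- 1e-10
  mu0 <- 2; s20 <- 0.3
  st <- make_ebi_state(ebi_config(alpha = a, K = 1, n = 2), mu0, s20, 1,
                       resid = matrix(c(0.04, 0.09), 1, 2), n_k = 2)
  d <- 2.4
  got <- ebi_step(st, d)

  # --- longhand: S = 1, K = 1 (confidence stays 1) ---
  S <- 1; lam <- 1 / (2 * s20)
  resid <- c(0.04, 0.09)
  resid[2 %% 2 + 1] <- (d - mu0)^2      # circular overwrite of slot 1
  D <- sum(resid)
  Delta_g <- gamma(S) * D * exp(S) / S^S
  fg <- dgamma(D, shape = S, rate = lam)
  tgt_g <- Delta_g^(-a) * (1 / fg)^a * fg
  Z <- max(min(-(D * tgt_g * gamma(S))^(1 / S) / S, -eps), -1 / exp(1))
  th <- c(ebitrack:::.lambert_wm1(Z), ebitrack:::.lambert_w0(Z))
  Theta <- th[which.min(abs(th - (-lam * D / S)))]
  lam_new <- -S * Theta / D
  s2_new <- 1 / (2 * lam_new)
  fN <- dnorm(d, mu0, sqrt(s2_new))
  Delta_N <- sqrt(2 * pi * s2_new)
  tgt_N <- Delta_N^(-a) * (1 / fN)^a * fN
  cl <- min(max(tgt_N, eps), 1 / Delta_N)
  off <- sqrt(-2 * s2_new * log(cl * Delta_N))
  roots <- c(d - off, d + off)
  mu_new <- roots[which.min(abs(roots - mu0))]

  expect_equal(got$state$sigma2, s2_new, tolerance = 1e-12)
  expect_equal(got$state$lambda, 1 / (2 * s2_new), tolerance = 1e-12)
  expect_equal(got$state$mu, mu_new, tolerance = 1e-12)
  expect_equal(as.numeric(got$state$resid), resid, tolerance = 1e-15)
})

test_that("alpha = 0 reproduces the standard Bayesian filter and freezes models", {
  set.seed(51)
  K <- 3
  mu0 <- runif(K, 0, 5); s20 <- runif(K, 0.01, 0.1)
  st <- make_ebi_state(ebi_config(alpha = 0, K = K), mu0, s20, rep(1 / K, K))
  d <- rnorm(200, 2, 0.5)
  fit <- ebi_filter(st, d, keep_confidence = TRUE)
  oracle <- bayes_filter_oracle(mu0, s20, rep(1 / K, K), d)
  expect_lt(max(abs(fit$confidence - oracle)), 1e-10)
  expect_identical(fit$state$mu, st$mu)
  expect_identical(fit$state$sigma2, st$sigma2)
})

test_that("confidences stay a smoothed probability vector along a run", {
  set.seed(52)
  K <- 5; eps <- 1e-10
  st <- make_ebi_state(ebi_config(alpha = 0.2, m = -0.5, K = K),
                       runif(K, 0, 5), runif(K, 0.01, 0.1), rep(1 / K, K))
  d <- rnorm(500, 2.5, 0.3)
  fit <- ebi_filter(st, d, keep_confidence = TRUE)
  sums <- rowSums(fit$confidence)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # smoothing floor: epsilon relative to the largest possible score sum
  # (unnormalized scores are densities, bounded by the per-step peak)
  peak_sum <- K / sqrt(2 * pi * min(fit$state$sigma2))
  expect_gte(min(fit$confidence), eps / (K * eps + peak_sum) - 1e-15)
  expect_gt(min(fit$confidence), 0)
})

test_that("only the selected hypothesis's model is modified", {
  set.seed(53)
  K <- 4
  st <- make_ebi_state(ebi_config(alpha = 0.3, K = K),
                       runif(K, 0, 5), runif(K, 0.01, 0.1), rep(1 / K, K))
  for (i in 1:100) {
    prev <- st
    r <- ebi_step(st, rnorm(1, 2, 1))
    st <- r$state
    j <- st$max_index
    for (k in setdiff(seq_len(K), j)) {
      expect_identical(st$mu[k], prev$mu[k])
      expect_identical(st$sigma2[k], prev$sigma2[k])
      expect_identical(st$resid[k, ], prev$resid[k, ])
      expect_identical(st$n_k[k], prev$n_k[k])
    }
  }
})

test_that("constant stream drives the model to the observation (fixed point)", {
  c0 <- 2
  st <- ebi_init(ebi_config(alpha = 0.1, K = 1), mu0 = 2.5, sigma2_0 = 0.05)
  fit <- ebi_filter(st, rep(c0, 500))
  expect_lt(abs(fit$state$mu - c0), 1e-3)
  # likelihood at the datum approaches the density peak 1/sqrt(2 pi Sigma)
  lik <- dnorm(c0, fit$state$mu, sqrt(fit$state$sigma2))
  expect_lt(abs(lik * sqrt(2 * pi * fit$state$sigma2) - 1), 1e-2)
})

test_that("fast filter and single steps are interchangeable", {
  set.seed(54)
  d <- rnorm(300, 2.5, 0.7)
  for (init in list(list(mu = runif(6, 0, 5), s2 = runif(6, 0.01, 0.1)),
                    list(mu = rep(2.5, 6), s2 = rep(0.05, 6)))) {
    cfg <- ebi_config(alpha = 0.1, m = -0.5, K = 6)
    set.seed(99)
    fA <- ebi_filter(ebi_init(cfg, init$mu, init$s2), d)
    set.seed(99)
    stB <- ebi_init(cfg, init$mu, init$s2)
    muB <- numeric(length(d))
    for (t in seq_along(d)) {
      r <- ebi_step(stB, d[t]); stB <- r$state
      muB[t] <- r$estimate[["mu"]]
    }
    expect_identical(fA$mu_hat, muB)
    expect_identical(fA$state$mu, stB$mu)
    expect_identical(fA$state$confidence, stB$confidence)
    expect_identical(fA$state$resid, stB$resid)
  }
})

test_that("lambda stays consistent with sigma2 along a run", {
  set.seed(55)
  st <- make_ebi_state(ebi_config(alpha = 0.25, K = 3),
                       runif(3, 0, 5), runif(3, 0.01, 0.1), rep(1 / 3, 3))
  fit <- ebi_filter(st, rnorm(400, 1, 0.5))
  expect_equal(fit$state$lambda, 1 / (2 * fit$state$sigma2),
               tolerance = 1e-12)
  expect_true(all(fit$state$sigma2 > 0))
})

test_that("JSON serialization resumes a run exactly", {
  set.seed(56)
  d <- rnorm(200, 2, 0.6)
  cfg <- ebi_config(alpha = 0.1, K = 4)
  set.seed(57)
  st <- ebi_init(cfg, runif(4, 0, 5), runif(4, 0.01, 0.1))
  straight <- ebi_filter(st, d)
  set.seed(57)
  st2 <- ebi_init(cfg, runif(4, 0, 5), runif(4, 0.01, 0.1))
  half <- ebi_filter(st2, d[1:100])
  restored <- state_from_json(state_to_json(half$state))
  rest <- ebi_filter(restored, d[101:200])
  expect_equal(rest$mu_hat, straight$mu_hat[101:200], tolerance = 1e-15)
  expect_equal(rest$state$sigma2, straight$state$sigma2, tolerance = 1e-15)

  # baselines roundtrip too
  sd_st <- sdem_filter(sdem_init(sdem_config(0.05, 3), c(1, 2, 3), 0.05),
                       d[1:50])$state
  sd_rt <- state_from_json(state_to_json(sd_st))
  expect_equal(sd_rt$mu, sd_st$mu, tolerance = 1e-15)
  expect_equal(sd_rt$pi_tilde, sd_st$pi_tilde, tolerance = 1e-15)
  em_st <- ema_filter(ema_init(0.05, 2, 0.05), d)$state
  em_rt <- state_from_json(state_to_json(em_st))
  expect_equal(em_rt$mu, em_st$mu, tolerance = 1e-15)
})
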