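#' Root-mean-square error over a window
#'
#' \eqn{\sqrt{\sum_{t=j}^{j+T-1} (\hat\mu^t - \mu^t)^2 / T}}.
#'
#' @param mu_hat Estimated sequence.
#' @param mu_correct Ground-truth sequence (same length).
#' @param j Start index (1-based, default 1).
#' @param T Window length (default: through the end of the sequences).
#' @return Nonnegative scalar.
#' @export
rmse <- function(mu_hat, mu_correct, j = 1, T = length(mu_hat) - j + 1) {
  stopifnot(length(mu_hat) == length(mu_correct), T >= 1,
            j >= 1, j + T - 1 <= length(mu_hat))
  idx <- j:(j + T - 1)
  sqrt(sum((mu_hat[idx] - mu_correct[idx])^2) / T)
}

#' Followability / accuracy RMSE split over segments
#'
#' Each stationary segment is divided into two halves: the RMSE of the
#' first half measures the inability to follow the abrupt change
#' (followability error) and that of the second half the estimation noise
#' during stationarity (accuracy error).  Per-segment half-window RMSEs are
#' averaged across segments; \code{total} is the RMSE over the whole
#' trace.  Only complete segments enter the half-window averages.
#'
#' @param mu_hat Estimated mean sequence.
#' @param trace A \code{"task_trace"} with ground truth (or a list with
#'   \code{mu_correct}).
#' @param segment_length Segment length (even; defaults to the trace's
#'   config).
#' @return An object of class \code{"rmse_result"}: list with
#'   \code{followability}, \code{accuracy}, \code{total},
#'   \code{n_segments}, \code{T_eval}.
#' @export
split_halves_rmse <- function(mu_hat, trace,
                              segment_length =
                                trace$config$segment_length) {
  mu_c <- trace$mu_correct
  stopifnot(length(mu_hat) == length(mu_c), segment_length %% 2 == 0)
  T_len <- length(mu_hat)
  L <- segment_length
  half <- L %/% 2
  n_seg <- T_len %/% L
  stopifnot(n_seg >= 1)
  foll <- acc <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    j <- (s - 1L) * L + 1L
    foll[s] <- rmse(mu_hat, mu_c, j, half)
    acc[s] <- rmse(mu_hat, mu_c, j + half, half)
  }
  structure(list(followability = mean(foll), accuracy = mean(acc),
                 total = rmse(mu_hat, mu_c, 1, T_len),
                 n_segments = n_seg, T_eval = half),
            class = "rmse_result")
}

#' @export
print.rmse_result <- function(x, ...) {
  cat(sprintf(
    "RMSE: followability %.4f, accuracy %.4f, total %.4f (%d segments)\n",
    x$followability, x$accuracy, x$total, x$n_segments))
  invisible(x)
}

# offset separating the estimator RNG stream (initialization draws and
# tie-breaks) from the data-generation stream of the same trial
.EST_SEED_OFFSET <- 104729L

.draw_init <- function(K, init, task_cfg) {
  if (init == "fixed") {
    list(mu0 = rep(2.5, K), sigma2_0 = rep(0.05, K))
  } else {
    mu0 <- task_cfg$mean_range[1] +
      diff(task_cfg$mean_range) * stats::runif(K)
    s2 <- task_cfg$var_range[1] +
      diff(task_cfg$var_range) * stats::runif(K)
    list(mu0 = mu0, sigma2_0 = s2)
  }
}

#' Run one estimator over one generated trace
#'
#' Generates the stream from \code{seed}, runs the named estimator online
#' (one observation per step, no lookahead), and computes the
#' followability/accuracy RMSE split.  The estimator's own randomness
#' (initialization draws under the \code{"uniform"} policy, tie-breaks) is
#' driven by an independent stream seeded from \code{seed} plus a fixed
#' offset, so the estimator is reproducible independent of the data.
#'
#' @param method_spec List naming the method and its parameters:
#'   \code{method} one of \code{"ebi"}, \code{"sdem"}, \code{"ema"};
#'   \code{alpha}, \code{m}, \code{K} for EBI; \code{beta}, \code{K} for
#'   SDEM; \code{beta} for EMA; \code{init} either \code{"uniform"}
#'   (means ~ U(mean_range), variances ~ U(var_range), the default) or
#'   \code{"fixed"} (mean 2.5, variance 0.05).
#' @param task_cfg A [task_config()] (its \code{seed} field is ignored).
#' @param seed Integer trial seed.
#' @param trace Optional pre-generated \code{"task_trace"} to use instead
#'   of generating one (for replaying external streams).
#' @return List with \code{estimate} (fields \code{mu_hat},
#'   \code{sigma2_hat}, \code{method_label}, \code{params}) and
#'   \code{rmse} (an \code{"rmse_result"}, or \code{NULL} when the trace
#'   has no ground truth).
#' @export
run_trial <- function(method_spec, task_cfg, seed, trace = NULL) {
  stopifnot(is.list(method_spec), !is.null(method_spec[["method"]]))
  method <- match.arg(method_spec[["method"]], c("ebi", "sdem", "ema"))
  init <- if (is.null(method_spec[["init"]])) "uniform" else
    match.arg(method_spec[["init"]], c("uniform", "fixed"))
  if (is.null(trace)) {
    cfg <- task_cfg
    cfg$seed <- as.integer(seed)
    trace <- generate_task(cfg)
  }
  set.seed(as.integer(seed) + .EST_SEED_OFFSET)
  if (method == "ebi") {
    K <- if (is.null(method_spec[["K"]])) 10L else as.integer(method_spec[["K"]])
    m <- if (is.null(method_spec[["m"]])) 0 else method_spec[["m"]]
    ini <- .draw_init(K, init, task_cfg)
    st <- ebi_init(ebi_config(alpha = method_spec[["alpha"]], m = m, K = K),
                   ini$mu0, ini$sigma2_0)
    fit <- ebi_filter(st, trace$d)
    params <- list(alpha = method_spec[["alpha"]], m = m, K = K, init = init)
    label <- sprintf("EBI(alpha=%g,m=%g,K=%d)", method_spec[["alpha"]], m, K)
  } else if (method == "sdem") {
    K <- if (is.null(method_spec[["K"]])) 10L else as.integer(method_spec[["K"]])
    ini <- .draw_init(K, init, task_cfg)
    st <- sdem_init(sdem_config(beta = method_spec[["beta"]], K = K),
                    ini$mu0, ini$sigma2_0)
    fit <- sdem_filter(st, trace$d)
    params <- list(beta = method_spec[["beta"]], K = K, init = init)
    label <- sprintf("SDEM(beta=%g,K=%d)", method_spec[["beta"]], K)
  } else {
    ini <- .draw_init(1L, init, task_cfg)
    st <- ema_init(beta = method_spec[["beta"]], ini$mu0, ini$sigma2_0)
    fit <- ema_filter(st, trace$d)
    params <- list(beta = method_spec[["beta"]], init = init)
    label <- sprintf("EMA(beta=%g)", method_spec[["beta"]])
  }
  estimate <- list(mu_hat = fit$mu_hat, sigma2_hat = fit$sigma2_hat,
                   method_label = label, params = params)
  res <- if (all(is.finite(trace$mu_correct)))
    split_halves_rmse(fit$mu_hat, trace) else NULL
  list(estimate = estimate, rmse = res)
}

.trial_means <- function(method_spec, task_cfg, n_trials, seed_base) {
  f <- a <- tot <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    r <- run_trial(method_spec, task_cfg, seed_base + i - 1L)$rmse
    f[i] <- r$followability; a[i] <- r$accuracy; tot[i] <- r$total
  }
  c(followability = mean(f), accuracy = mean(a), total = mean(tot))
}

#' Discount-rate sweep over methods
#'
#' For every (method, discount rate, K) combination, averages the
#' followability and accuracy RMSEs over \code{n_trials} trials with seeds
#' \code{seed_base .. seed_base + n_trials - 1}.  The swept rate is
#' \code{alpha} for EBI (with fixed \code{m}) and \code{beta} for SDEM and
#' EMA.  The EMA has no component count, so it contributes one row per
#' rate.
#'
#' @param task_cfg A [task_config()].
#' @param rates Discount rates (default the 48-point grid 0.009 to 0.15 in
#'   steps of 0.003).
#' @param K_list Component counts for EBI and SDEM (default
#'   \code{c(1, 2, 5, 10)}).
#' @param n_trials Trials per cell (default 100).
#' @param seed_base First trial seed.
#' @param methods Subset of \code{c("ebi", "sdem", "ema")}.
#' @param m EBI generalized-mean order (default 0).
#' @param init Initialization policy passed to [run_trial()].
#' @return Data frame (class \code{"sweep_result"}) with one row per cell:
#'   \code{method}, \code{discount}, \code{K}, \code{followability},
#'   \code{accuracy}, \code{total}, \code{n_trials}, \code{seed_base}.
#' @export
sweep_discount <- function(task_cfg, rates = seq(0.009, 0.15, by = 0.003),
                           K_list = c(1, 2, 5, 10), n_trials = 100,
                           seed_base = 0,
                           methods = c("ebi", "sdem", "ema"), m = 0,
                           init = "uniform") {
  stopifnot(length(rates) >= 1, n_trials >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (method in methods) {
    Ks <- if (method == "ema") NA_integer_ else as.integer(K_list)
    for (K in Ks) {
      for (r in rates) {
        spec <- switch(method,
          ebi = list(method = "ebi", alpha = r, m = m, K = K, init = init),
          sdem = list(method = "sdem", beta = r, K = K, init = init),
          ema = list(method = "ema", beta = r, init = init))
        v <- .trial_means(spec, task_cfg, n_trials, as.integer(seed_base))
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, discount = r, K = K,
          followability = v[["followability"]],
          accuracy = v[["accuracy"]], total = v[["total"]],
          n_trials = n_trials, seed_base = seed_base)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' (alpha, m) grid for EBI
#'
#' Trial-averaged total RMSE (plus the followability/accuracy split) of the
#' EBI estimator over a grid of weighting rates \code{alpha} and
#' generalized-mean orders \code{m}.
#'
#' @param task_cfg A [task_config()].
#' @param alpha_grid Alphas (default 0.05 to 0.5 in steps of 0.05).
#' @param m_grid Mean orders (default -2 to 2 in steps of 0.1).
#' @param K Component count (default 10).
#' @param n_trials Trials per cell (default 100).
#' @param seed_base First trial seed.
#' @param init Initialization policy.
#' @return Data frame (class \code{"sweep_result"}) with one row per
#'   (alpha, m) cell.
#' @export
grid_alpha_m <- function(task_cfg, alpha_grid = seq(0.05, 0.5, by = 0.05),
                         m_grid = seq(-2, 2, by = 0.1), K = 10,
                         n_trials = 100, seed_base = 0, init = "uniform") {
  stopifnot(length(alpha_grid) >= 1, length(m_grid) >= 1, n_trials >= 1)
  rows <- list()
  for (a in alpha_grid) {
    for (mm in m_grid) {
      spec <- list(method = "ebi", alpha = a, m = mm, K = K, init = init)
      v <- .trial_means(spec, task_cfg, n_trials, as.integer(seed_base))
      rows[[length(rows) + 1L]] <- data.frame(
        method = "ebi", alpha = a, m = mm, K = as.integer(K),
        followability = v[["followability"]],
        accuracy = v[["accuracy"]], total = v[["total"]],
        n_trials = n_trials, seed_base = seed_base)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
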