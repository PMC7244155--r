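#' Configuration for the non-stationary Gaussian task
#'
#' A univariate Gaussian stream whose mean and variance are re-drawn from
#' uniform distributions at the start of every segment and held constant
#' within it.
#'
#' @param segment_length Steps between re-draws (default 1000).
#' @param total_steps Stream length (default 10000).
#' @param mean_range Interval for the mean (default \code{c(0, 5)}).
#' @param var_range Interval for the variance (default \code{c(0, 0.1)}).
#' @param seed Optional integer seed for the data random source.
#' @return An object of class \code{"task_config"}.
#' @export
task_config <- function(segment_length = 1000, total_steps = 10000,
                        mean_range = c(0, 5), var_range = c(0, 0.1),
                        seed = NULL) {
  stopifnot(segment_length >= 1, total_steps >= 1,
            length(mean_range) == 2, diff(mean_range) >= 0,
            length(var_range) == 2, var_range[1] >= 0, diff(var_range) >= 0)
  structure(list(segment_length = as.integer(segment_length),
                 total_steps = as.integer(total_steps),
                 mean_range = as.numeric(mean_range),
                 var_range = as.numeric(var_range),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "task_config")
}

#' Generate a non-stationary Gaussian stream
#'
#' At every step \code{t} with \code{(t - 1) \%\% segment_length == 0}
#' (including the first step) a new ground-truth mean and variance are
#' drawn — mean first, then variance, each as \code{low + width * U(0,1)} —
#' and observations are drawn from the current normal distribution.
#' Deterministic given \code{config$seed}.
#'
#' @param config A [task_config()].
#' @return An object of class \code{"task_trace"}: list with \code{d},
#'   \code{mu_correct}, \code{sigma2_correct} (each of length
#'   \code{total_steps}) and the \code{config}.
#' @export
generate_task <- function(config) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  T_len <- config$total_steps
  L <- config$segment_length
  d <- numeric(T_len)
  mu_c <- numeric(T_len)
  s2_c <- numeric(T_len)
  t <- 1L
  while (t <= T_len) {
    mu <- config$mean_range[1] + diff(config$mean_range) * stats::runif(1)
    s2 <- config$var_range[1] + diff(config$var_range) * stats::runif(1)
    idx <- t:min(t + L - 1L, T_len)
    mu_c[idx] <- mu
    s2_c[idx] <- s2
    d[idx] <- stats::rnorm(length(idx), mu, sqrt(s2))
    t <- t + L
  }
  structure(list(d = d, mu_correct = mu_c, sigma2_correct = s2_c,
                 config = config),
            class = "task_trace")
}

#' @export
print.task_trace <- function(x, ...) {
  cat(sprintf(
    "Non-stationary Gaussian stream: %d steps, segment length %d (%d segments)\n",
    x$config$total_steps, x$config$segment_length,
    ceiling(x$config$total_steps / x$config$segment_length)))
  invisible(x)
}

#' Write a task trace to CSV
#'
#' Three columns \code{d}, \code{mu_correct}, \code{sigma2_correct} with a
#' header row; values formatted at full double precision so a read-back
#' reproduces the trace exactly.
#'
#' @param trace A \code{"task_trace"} (or any list with those three
#'   fields).
#' @param path Output file path.
#' @export
write_task_csv <- function(trace, path) {
  df <- data.frame(
    d = formatC(trace$d, digits = 17, format = "g"),
    mu_correct = formatC(trace$mu_correct, digits = 17, format = "g"),
    sigma2_correct = formatC(trace$sigma2_correct, digits = 17,
                             format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stream from CSV
#'
#' Accepts either the three-column format written by [write_task_csv()] or
#' a one-column CSV of observations (column \code{d}, or a single unnamed
#' column), in which case the ground-truth columns are absent (\code{NA}).
#'
#' @param path CSV file path.
#' @param segment_length,total_steps Optional overrides for the resulting
#'   trace's config; \code{total_steps} defaults to the number of rows.
#' @return A \code{"task_trace"}.
#' @export
read_task_csv <- function(path, segment_length = 1000, total_steps = NULL) {
  df <- utils::read.csv(path)
  if (!"d" %in% names(df)) {
    if (ncol(df) == 1) names(df) <- "d"
    else stop("CSV must contain a 'd' column")
  }
  n <- nrow(df)
  cfg <- task_config(segment_length = segment_length,
                     total_steps = if (is.null(total_steps)) n else
                       total_steps)
  structure(list(d = as.numeric(df$d),
                 mu_correct = if ("mu_correct" %in% names(df))
                   as.numeric(df$mu_correct) else rep(NA_real_, n),
                 sigma2_correct = if ("sigma2_correct" %in% names(df))
                   as.numeric(df$sigma2_correct) else rep(NA_real_, n),
                 config = cfg),
            class = "task_trace")
}
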