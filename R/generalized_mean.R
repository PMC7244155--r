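#' Generalized weighted mean of two positive numbers
#'
#' Computes the power mean \eqn{\mu(x, y \mid \alpha, m) = [(1-\alpha) x^m +
#' \alpha y^m]^{1/m}} that interpolates between conditional-probability
#' weighting and causal (dual-factor heuristics) weighting.  \code{m = 1}
#' gives the arithmetic mean, \code{m = -1} the harmonic mean, and
#' \code{m = 0} is defined as the limit \eqn{x^{1-\alpha} y^{\alpha}}
#' (the geometric mean when \code{alpha = 0.5}).
#'
#' All arguments are recycled to a common length.
#'
#' @param x,y Positive finite numerics.
#' @param alpha Weight on \code{y}, in \code{[0, 1]}.
#' @param m Mean order, any finite real; \code{m = 0} means the geometric
#'   limit.
#' @return Numeric vector of means; each value lies between \code{min(x, y)}
#'   and \code{max(x, y)}.
#' @examples
#' generalized_weighted_mean(2, 8, 0.5, 1)   # arithmetic: 5
#' generalized_weighted_mean(2, 8, 0.5, -1)  # harmonic: 3.2
#' generalized_weighted_mean(4, 9, 0.5, 0)   # geometric: 6
#' @export
generalized_weighted_mean <- function(x, y, alpha, m) {
  if (!all(is.finite(x)) || !all(is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("'x' and 'y' must be finite and strictly positive")
  if (!all(is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("'alpha' must lie in [0, 1]")
  if (!all(is.finite(m)))
    stop("'m' must be finite")
  k <- max(length(x), length(y), length(alpha), length(m))
  x <- rep_len(x, k); y <- rep_len(y, k)
  alpha <- rep_len(alpha, k); m <- rep_len(m, k)
  out <- numeric(k)
  z <- m == 0
  if (any(z))
    out[z] <- x[z]^(1 - alpha[z]) * y[z]^alpha[z]
  if (any(!z)) {
    mm <- m[!z]
    out[!z] <- ((1 - alpha[!z]) * x[!z]^mm + alpha[!z] * y[!z]^mm)^(1 / mm)
  }
  out
}
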