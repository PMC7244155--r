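# Lambert W on the negative real domain [-1/e, 0), both branches, via a
# branch-point series start and a guarded Halley iteration.  The step-based
# stopping rule is relative and iteration is capped, so the computation
# terminates for arguments arbitrarily close to the branch point (where
# naive absolute-residual loops can stall).

.lambert_w <- function(z, branch = 0L) {
  if (length(z) != 1 || !is.finite(z)) stop("'z' must be a finite scalar")
  bp <- -exp(-1)
  if (z < bp) {
    if (z > bp - 1e-15) z <- bp  # rounding slop from upstream clipping
    else stop("Lambert W undefined for z < -1/e: z = ", z)
  }
  if (z >= 0) {
    if (branch == 0L && z == 0) return(0)
    stop("negative-domain Lambert W requires z < 0")
  }
  # series about the branch point: w = -1 + p - p^2/3 + 11 p^3/72 - ...
  # with p = +sqrt(2(ez+1)) on the principal branch, -p on W_{-1}
  p2 <- 2 * (exp(1) * z + 1)
  p <- if (branch == 0L) sqrt(p2) else -sqrt(p2)
  if (p2 < 1e-4) {
    return(-1 + p - p2 / 3 + 11 / 72 * p^3 - 43 / 540 * p2^2)
  }
  w <- if (abs(p) < 1) {
    -1 + p - p2 / 3 + 11 / 72 * p^3
  } else if (branch == 0L) {
    z  # W0(z) ~ z for z near 0-; adequate Halley start on (-0.19, 0)
  } else {
    L1 <- log(-z)
    L2 <- log(-L1)
    L1 - L2 + L2 / L1
  }
  # keep the iterate on its branch
  w <- if (branch == 0L) max(w, -1) else min(w, -1)
  for (i in 1:100) {
    ew <- exp(w)
    f <- w * ew - z
    if (f == 0) break
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    if (!is.finite(denom) || denom == 0) break
    step <- f / denom
    w_new <- w - step
    w_new <- if (branch == 0L) max(w_new, -1) else min(w_new, -1)
    if (abs(w_new - w) <= 4 * .Machine$double.eps * (1 + abs(w))) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}

.lambert_w0 <- function(z) .lambert_w(z, 0L)
.lambert_wm1 <- function(z) .lambert_w(z, -1L)
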