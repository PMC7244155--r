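#' Serialize an estimator state to JSON
#'
#' All scalars, vectors and the residual window are written at full double
#' precision, so a state restored with [state_from_json()] resumes exactly
#' where the original left off.
#'
#' @param state An \code{"ebi_state"}, \code{"sdem_state"} or
#'   \code{"ema_state"}.
#' @return A JSON string.
#' @export
state_to_json <- function(state) {
  kind <- intersect(class(state), c("ebi_state", "sdem_state", "ema_state"))
  if (length(kind) != 1) stop("not a serializable estimator state")
  x <- unclass(state)
  x$.kind <- kind
  if (kind == "ebi_state") {
    x$config <- unclass(x$config)
    x$resid <- as.numeric(x$resid)  # column-major; K x n restored below
  } else if (kind == "sdem_state") {
    x$config <- unclass(x$config)
  }
  # I(17) significant digits: lossless for IEEE doubles
  jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE, null = "null")
}

#' Restore an estimator state from JSON
#'
#' @param json A JSON string produced by [state_to_json()].
#' @return The restored state object.
#' @export
state_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  kind <- x$.kind
  x$.kind <- NULL
  if (kind == "ebi_state") {
    cfg <- x$config
    config <- ebi_config(alpha = cfg$alpha, m = cfg$m, K = cfg$K,
                         epsilon = cfg$epsilon, n = cfg$n,
                         forget_rate = cfg$forget_rate,
                         learn_rate = cfg$learn_rate,
                         delta_variance = cfg$delta_variance)
    st <- structure(list(
      config = config,
      mu = as.numeric(x$mu), sigma2 = as.numeric(x$sigma2),
      lambda = as.numeric(x$lambda),
      resid = matrix(as.numeric(x$resid), nrow = config$K,
                     ncol = config$n),
      n_k = as.integer(x$n_k),
      confidence = as.numeric(x$confidence),
      t = as.integer(x$t),
      max_index = if (is.null(x$max_index) || is.na(x$max_index))
        NA_integer_ else as.integer(x$max_index)),
      class = "ebi_state")
    return(st)
  }
  if (kind == "sdem_state") {
    cfg <- x$config
    config <- sdem_config(beta = cfg$beta, K = cfg$K,
                          gamma_smooth = cfg$gamma_smooth)
    return(structure(list(
      config = config,
      pi_tilde = as.numeric(x$pi_tilde), pi = as.numeric(x$pi),
      mu_tilde = as.numeric(x$mu_tilde),
      sigma2_tilde = as.numeric(x$sigma2_tilde),
      mu = as.numeric(x$mu), sigma2 = as.numeric(x$sigma2),
      q = as.numeric(x$q), t = as.integer(x$t)),
      class = "sdem_state"))
  }
  structure(list(beta = x$beta, mu = as.numeric(x$mu),
                 sigma2 = as.numeric(x$sigma2), t = as.integer(x$t)),
            class = "ema_state")
}
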