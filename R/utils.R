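# Internal numeric and data-marshalling helpers.

# Resolve a vector of positive lifetimes from a data frame (first numeric
# column, or the column named by `time`) or from a bare numeric vector.
resolve_lifetimes <- function(data, time = NULL, arg = "data") {
  if (is.numeric(data)) {
    values <- as.numeric(data)
  } else if (is.data.frame(data)) {
    quo <- rlang::enquo(time)
    if (rlang::quo_is_null(quo)) {
      num <- vapply(data, is.numeric, logical(1))
      if (!any(num)) {
        abort(sprintf("`%s` contains no numeric column.", arg),
              class = "ggfit_error_input")
      }
      values <- as.numeric(data[[which(num)[1L]]])
    } else {
      values <- as.numeric(dplyr::pull(data, !!quo))
    }
  } else {
    abort(sprintf("`%s` must be a data frame or a numeric vector.", arg),
          class = "ggfit_error_input")
  }
  validate_lifetimes(values)
}

#' Validate a sample of positive lifetimes
#'
#' Checks that every value is finite and strictly positive and returns the
#' sample with its order statistics attached.  All fitting functions run
#' their inputs through this validator.
#'
#' @param values Numeric vector of durations (time units, e.g. days).
#' @return A numeric vector of class `lifetime_sample` with attributes `n`
#'   and `sorted` (the order statistics).
#' @examples
#' validate_lifetimes(c(4, 23, 67, 12))
#' @export
validate_lifetimes <- function(values) {
  if (length(values) < 1L) {
    abort("The lifetime sample is empty.", class = "ggfit_error_input")
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "Lifetimes must be positive and finite; offending rows: %s.",
        paste(head(bad, 10L), collapse = ", ")
      ),
      class = "ggfit_error_input"
    )
  }
  structure(values,
            n = length(values),
            sorted = sort(values),
            class = "lifetime_sample")
}

# Strip lifetime_sample attributes for plain numeric work.
lifetime_values <- function(x) as.numeric(unclass(x))

check_gg_params <- function(phi, mu, alpha) {
  ok <- is.numeric(phi) && is.numeric(mu) && is.numeric(alpha) &&
    all(is.finite(phi)) && all(is.finite(mu)) && all(is.finite(alpha)) &&
    all(phi > 0) && all(mu > 0) && all(alpha > 0)
  if (!ok) {
    abort("GG parameters (phi, mu, alpha) must be strictly positive and finite.",
          class = "ggfit_error_domain")
  }
  invisible(TRUE)
}

# Deterministic per-replicate seed stream, kept below 2^31 - 1.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) + 104729 * as.double(index)) %% 2147483629L + 1)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Damped Newton iteration on a (small) nonlinear system, with numeric
# Jacobian.  Returns the best point visited by residual norm.
newton_polish <- function(score_fun, x0, tol = 1e-11, max_iter = 30L) {
  x <- x0
  s <- tryCatch(score_fun(x), error = function(e) NULL)
  if (is.null(s) || !all(is.finite(s))) {
    return(list(x = x0, score = s, converged = FALSE))
  }
  best_x <- x
  best_norm <- max(abs(s))
  for (i in seq_len(max_iter)) {
    if (best_norm < tol) break
    J <- tryCatch(pracma::jacobian(score_fun, x), error = function(e) NULL)
    if (is.null(J) || !all(is.finite(J))) break
    dx <- tryCatch(solve(J, s), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) break
    # damp long steps (coordinates are on the log scale)
    if (max(abs(dx)) > 1) dx <- dx / max(abs(dx))
    step <- 1
    improved <- FALSE
    for (k in 1:4) {
      xn <- x - step * dx
      sn <- tryCatch(score_fun(xn), error = function(e) NULL)
      if (!is.null(sn) && all(is.finite(sn)) && max(abs(sn)) < max(abs(s))) {
        x <- xn
        s <- sn
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    if (max(abs(s)) < best_norm) {
      best_norm <- max(abs(s))
      best_x <- x
    }
  }
  list(x = best_x, score = score_fun(best_x), converged = best_norm < tol)
}
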