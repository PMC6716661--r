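#' @export
print.gg_fit <- function(x, ...) {
  cat("Generalized Gamma fit (", x$method, ")\n", sep = "")
  if (x$failed) {
    cat("  FAILED:", x$failure_reason, "\n")
  }
  est <- x$params
  cat(sprintf("  phi = %.4g, mu = %.4g, alpha = %.4g\n",
              est[1], est[2], est[3]))
  cat(sprintf("  n = %d, logLik = %.4f, criterion = %.6g, score = %.3g\n",
              x$n, x$loglik, x$objective, x$score_norm))
  invisible(x)
}

#' Tidy a Generalized Gamma fit
#'
#' @param x A `gg_fit` object.
#' @param conf.int Add a confidence interval?
#' @param conf.level Confidence level.
#' @param conf.type `"asymptotic"` (Wald, from the Fisher information) or
#'   `"bootstrap"` (nonparametric, see [gg_bootstrap_ci()]).
#' @param ... Passed on to [gg_bootstrap_ci()] when `conf.type = "bootstrap"`
#'   (e.g. `B`, `seed`).
#' @return A tibble with columns `term`, `estimate` and, if requested,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy gg_fit
#' @export
tidy.gg_fit <- function(x, conf.int = FALSE, conf.level = 0.95,
                        conf.type = c("asymptotic", "bootstrap"), ...) {
  conf.type <- match.arg(conf.type)
  out <- tibble(term = c("phi", "mu", "alpha"),
                estimate = as.numeric(x$params))
  if (!conf.int) return(out)
  if (conf.type == "asymptotic") {
    ci <- confint(x, level = conf.level)
    out$std.error <- attr(ci, "std.error")
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  } else {
    ci <- gg_bootstrap_ci(x$data, method = tolower(x$method),
                          level = conf.level, ...)
    out$conf.low <- ci$conf.low
    out$conf.high <- ci$conf.high
  }
  out
}

#' One-row summary of a Generalized Gamma fit
#'
#' @param x A `gg_fit` object.
#' @param ... Unused.
#' @return A tibble with the method tag, sample size, log-likelihood, AIC,
#'   AICc, criterion value, score residual norm and failure flag.
#' @method glance gg_fit
#' @export
glance.gg_fit <- function(x, ...) {
  ic <- if (is.finite(x$loglik)) aic_aicc(x$loglik, 3L, x$n) else
    tibble(AIC = NA_real_, AICc = NA_real_)
  tibble(method = x$method, n = x$n, logLik = x$loglik,
         AIC = ic$AIC, AICc = ic$AICc, objective = x$objective,
         score_norm = x$score_norm, failed = x$failed)
}

#' @export
logLik.gg_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' Plot a fitted GG survival curve over the empirical survival function
#'
#' @param object A `gg_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gg_fit
#' @export
autoplot.gg_fit <- function(object, ...) {
  x <- sort(object$data)
  n <- length(x)
  emp <- tibble(t = c(0, x), surv = c(1, 1 - seq_len(n) / n))
  grid <- seq(0, max(x) * 1.1, length.out = 200)
  p <- object$params
  fitted <- tibble(t = grid, surv = sgengam(grid, p[1], p[2], p[3]))
  ggplot(emp, aes(x = .data$t, y = .data$surv)) +
    geom_step(colour = "grey40") +
    geom_line(data = fitted, colour = "#2166ac", linewidth = 0.8) +
    labs(x = "time", y = "S(t)",
         title = sprintf("Generalized Gamma fit (%s)", object$method)) +
    theme_minimal()
}
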