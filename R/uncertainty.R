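#' Fisher information matrix of the GG distribution
#'
#' Expected information for a sample of size `n`, in the parameter order
#' `(phi, mu, alpha)`.  The per-observation matrix has entries
#' \deqn{I_{\phi\phi} = \psi'(\phi),\; I_{\phi\mu} = -\alpha/\mu,\;
#'   I_{\phi\alpha} = -\psi(\phi)/\alpha,\; I_{\mu\mu} = \phi\alpha^2/\mu^2,}
#' \deqn{I_{\mu\alpha} = (1 + \phi\psi(\phi))/\mu,\;
#'   I_{\alpha\alpha} = (1 + 2\psi(\phi) + \phi\psi'(\phi) +
#'   \phi\psi(\phi)^2)/\alpha^2,}
#' derived from the expected negative Hessian of the log-density (its
#' determinant is the Jeffreys-penalty radicand divided by \eqn{\mu^2}).
#'
#' With `penalized = TRUE` the exact curvature of the Jeffreys penalty is
#' added: the `(phi, phi)` entry gains the second derivative of half the
#' log-radicand (computed with polygamma functions up to third order) and
#' the `(mu, mu)` and `(alpha, alpha)` entries gain `-1/mu^2` and
#' `-1/alpha^2` from the penalty's log-scale terms.  The penalty curvature
#' is O(1) while the likelihood information grows like `n`, so the two
#' matrices agree asymptotically.
#'
#' @inheritParams gengam
#' @param n Sample size multiplier.
#' @param penalized Add the penalty curvature?
#' @return A symmetric 3x3 matrix with attribute `penalized`.
#' @examples
#' gg_fisher_info(0.5, 0.5, 3, n = 20)
#' @export
gg_fisher_info <- function(phi, mu, alpha, n = 1L, penalized = FALSE) {
  check_gg_params(phi, mu, alpha)
  stopifnot(n >= 1)
  ps <- digamma(phi)
  ps1 <- trigamma(phi)
  if (!all(is.finite(c(ps, ps1)))) {
    abort("Polygamma functions are not finite at `phi`.",
          class = "ggfit_error_domain")
  }
  I1 <- matrix(c(
    ps1, -alpha / mu, -ps / alpha,
    -alpha / mu, phi * alpha^2 / mu^2, (1 + phi * ps) / mu,
    -ps / alpha, (1 + phi * ps) / mu,
    (1 + 2 * ps + phi * ps1 + phi * ps^2) / alpha^2
  ), 3, 3, dimnames = list(c("phi", "mu", "alpha"), c("phi", "mu", "alpha")))
  out <- n * I1
  if (penalized) {
    out[1, 1] <- out[1, 1] + penalty_info_phi(phi)
    out[2, 2] <- out[2, 2] - 1 / mu^2
    out[3, 3] <- out[3, 3] - 1 / alpha^2
  }
  structure(out, penalized = penalized)
}

# Negative second derivative of half the log penalty radicand:
#   (r'/2r)^2 * 2 - ... = (r')^2 / (2 r^2) - r'' / (2 r)
penalty_info_phi <- function(phi) {
  r <- penalty_radicand(phi)
  rp <- penalty_radicand_d1(phi)
  ps1 <- trigamma(phi)
  ps2 <- psigamma(phi, 2)
  ps3 <- psigamma(phi, 3)
  rpp <- 2 * ps1^2 + 8 * phi * ps1 * ps2 + 2 * phi^2 * (ps2^2 + ps1 * ps3) - ps3
  rp^2 / (2 * r^2) - rpp / (2 * r)
}

#' Wald (asymptotic normal) confidence intervals for a GG fit
#'
#' Intervals \eqn{\hat\theta_j \pm z_{(1+level)/2}\sqrt{[I^{-1}]_{jj}}} from
#' the Fisher information evaluated at the estimates.  The normal
#' approximation for `phi` is known to be poor even for samples of several
#' hundred observations, so a warning is emitted for `n < 400`; prefer the
#' bootstrap ([gg_bootstrap_ci()]) for small samples.
#'
#' @param object A non-failed `gg_fit`.
#' @param parm Ignored (all three parameters are returned).
#' @param level Confidence level.
#' @param penalized Use the penalized information matrix; defaults to `TRUE`
#'   for PML fits.
#' @param ... Unused.
#' @return A 3x2 matrix of lower/upper bounds with attribute `std.error`.
#' @export
confint.gg_fit <- function(object, parm = NULL, level = 0.95,
                           penalized = NULL, ...) {
  if (object$failed) {
    abort("Cannot compute intervals from a failed fit.",
          class = "ggfit_error_input")
  }
  if (object$n < 400) {
    warn(paste("Asymptotic normality is unreliable below n = 400;",
               "consider gg_bootstrap_ci()."),
         class = "ggfit_warning_small_sample")
  }
  penalized <- penalized %||% identical(object$method, "PML")
  p <- object$params
  I <- gg_fisher_info(p[1], p[2], p[3], n = object$n, penalized = penalized)
  Iinv <- tryCatch(solve(I), error = function(e) {
    abort("Fisher information matrix is singular at the estimates.",
          class = "ggfit_error_domain")
  })
  se <- sqrt(diag(Iinv))
  z <- qnorm((1 + level) / 2)
  out <- cbind(lower = p - z * se, upper = p + z * se)
  rownames(out) <- c("phi", "mu", "alpha")
  attr(out, "std.error") <- se
  out
}

#' Nonparametric bootstrap confidence intervals for GG parameters
#'
#' Resamples the data with replacement, refits by the requested method, and
#' forms per-parameter intervals.  The default interval type is BCa
#' (bias-corrected and accelerated), falling back to the simple percentile
#' interval when the acceleration estimate is degenerate (all jackknife
#' values equal).  Bootstrap replicates whose refit fails are dropped and
#' counted; more than 50% failures is an error naming the estimator — in
#' practice this matters for the fragile methods (MM, OLS, WLS), while the
#' penalized ML default essentially never fails, which is what makes the
#' bootstrap viable at these sample sizes.
#'
#' Refits are warm-started at the full-data estimates and polished by
#' Newton steps on the score equations (with an annealing rescue when that
#' fails), which makes B = 1000 replicates fast; set `warm_start = FALSE`
#' to rerun the full global optimization per replicate.
#'
#' @param data Data frame or numeric vector of lifetimes.
#' @param time Column holding the lifetimes.
#' @param method Estimation method tag (default `"pml"`).
#' @param level Confidence level.
#' @param B Number of bootstrap replicates (at least 200).
#' @param seed Integer seed; fixed seed and `B` give identical intervals.
#' @param type `"bca"` or `"percentile"`.
#' @param warm_start See Details.
#' @param control [sann_control()] for non-warm-started refits.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`, `type`, plus attributes `B`, `level`, `n_failed`.
#' @examples
#' d <- make_tbi_sample("D3", seed = 1)
#' gg_bootstrap_ci(d, B = 200, seed = 2)
#' @export
gg_bootstrap_ci <- function(data, time = NULL, method = "pml", level = 0.95,
                            B = 1000L, seed = NULL,
                            type = c("bca", "percentile"),
                            warm_start = TRUE,
                            control = sann_control(max_iter = 3000, m = 50,
                                                   k_min = 1e-6)) {
  type <- match.arg(type)
  if (B < 200L) {
    abort("`B` must be at least 200.", class = "ggfit_error_input")
  }
  x <- lifetime_values(resolve_lifetimes(data, {{ time }}))
  n <- length(x)
  if (!is.null(seed)) set.seed(seed)
  full <- fit_gg_refit(x, method, start = runif(3, 0, 4), control = control,
                       warm = NULL)
  if (full$failed) {
    abort(sprintf("Full-data %s fit failed: %s", toupper(method),
                  full$failure_reason),
          class = "ggfit_error_fit")
  }
  theta <- full$params
  boots <- matrix(NA_real_, B, 3)
  n_failed <- 0L
  for (b in seq_len(B)) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    fb <- fit_gg_refit(xb, method, start = runif(3, 0, 4), control = control,
                       warm = if (warm_start) theta)
    if (fb$failed) n_failed <- n_failed + 1L else boots[b, ] <- fb$params
  }
  if (n_failed > B / 2) {
    abort(sprintf(
      "More than half of the bootstrap refits failed for estimator %s (%d of %d).",
      toupper(method), n_failed, B), class = "ggfit_error_fit")
  }
  boots <- boots[stats::complete.cases(boots), , drop = FALSE]
  probs <- c((1 - level) / 2, (1 + level) / 2)
  used_type <- type
  if (type == "bca") {
    jack <- jackknife_estimates(x, method, theta, control, warm_start)
    ci <- tryCatch(
      bca_interval(boots, theta, jack, probs),
      error = function(e) NULL
    )
    if (is.null(ci)) {
      used_type <- "percentile"
      ci <- apply(boots, 2, quantile, probs = probs, type = 1)
    }
  } else {
    ci <- apply(boots, 2, quantile, probs = probs, type = 1)
  }
  out <- tibble(term = c("phi", "mu", "alpha"),
                estimate = as.numeric(theta),
                conf.low = ci[1, ], conf.high = ci[2, ],
                type = used_type)
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "n_failed") <- n_failed
  attr(out, "replicates") <- boots
  out
}

# Warm-startable refit used by the bootstrap: Newton on the score equations
# from `warm`, falling back to the full global fit when that fails.
fit_gg_refit <- function(x, method, start, control, warm = NULL) {
  x <- validate_lifetimes(x)
  if (!is.null(warm) && method %in% c("pml", "ml")) {
    values <- lifetime_values(x)
    lt <- log(values)
    if (method == "pml") {
      score2 <- function(w) {
        phi <- pml_phi_of(lt, w[1], w[2])
        gg_penalized_score(values, phi, exp(w[1]), exp(w[2]))[c(1, 3)]
      }
      np <- newton_polish(score2, log(warm[2:3]), tol = 1e-8, max_iter = 40L)
      if (!np$converged) {
        # cheap derivative-free hop before resorting to a full anneal
        obj <- pml_objective(lt)
        nm <- tryCatch(
          optim(log(warm[2:3]), obj, method = "Nelder-Mead",
                control = list(reltol = 1e-13, maxit = 400)),
          error = function(e) NULL
        )
        if (!is.null(nm) && all(is.finite(nm$par))) {
          np <- newton_polish(score2, nm$par, tol = 1e-8, max_iter = 40L)
        }
      }
      if (np$converged) {
        mu <- exp(np$x[1]); alpha <- exp(np$x[2])
        phi <- pml_phi_of(lt, np$x[1], np$x[2])
        res <- list(params = setNames(c(phi, mu, alpha), c("phi", "mu", "alpha")),
                    method = "PML", failed = FALSE)
        res$failed <- !all(is.finite(res$params)) || any(res$params < 1e-6) ||
          any(res$params > 1e6) ||
          max(abs(gg_penalized_score(values, phi, mu, alpha))) > 1e-5
        res$failure_reason <- if (res$failed) "warm-start polish unsatisfied" else ""
        if (!res$failed) return(res)
      }
    } else {
      hfun <- function(w) ml_profile_h(lt, exp(w))
      np <- newton_polish(hfun, log(warm[3]), tol = 1e-8, max_iter = 40L)
      if (np$converged) {
        alpha <- exp(np$x)
        phi <- ml_profile_phi(lt, alpha)
        if (is.finite(phi) && phi > 0) {
          mu <- exp(ml_profile_logmu(lt, alpha, phi))
          par <- c(phi, mu, alpha)
          ok <- all(is.finite(par)) && all(par > 1e-6) && all(par < 1e6) &&
            max(abs(gg_score(values, phi, mu, alpha))) < 1e-5
          if (ok) {
            return(list(params = setNames(par, c("phi", "mu", "alpha")),
                        method = "ML", failed = FALSE, failure_reason = ""))
          }
        }
      }
    }
  }
  fit_gg_impl(x, method, start = start, seed = NULL, control = control,
              engine = "sann", polish = TRUE)
}

jackknife_estimates <- function(x, method, theta, control, warm_start) {
  n <- length(x)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    fi <- fit_gg_refit(x[-i], method, start = theta, control = control,
                       warm = if (warm_start) theta)
    if (!fi$failed) out[i, ] <- fi$params
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

bca_interval <- function(boots, theta, jack, probs) {
  B <- nrow(boots)
  sapply(1:3, function(j) {
    tb <- boots[, j]
    z0 <- qnorm((sum(tb < theta[j]) + 0.5 * sum(tb == theta[j])) / B)
    u <- mean(jack[, j]) - jack[, j]
    denom <- sum(u^2)^1.5
    if (!is.finite(z0) || denom == 0) stop("degenerate BCa correction")
    a <- sum(u^3) / (6 * denom)
    zq <- qnorm(probs)
    adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    quantile(tb, probs = adj, type = 1, names = FALSE)
  })
}
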