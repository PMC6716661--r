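#' Fit the Generalized Gamma distribution to a lifetime sample
#'
#' Estimates the GG parameters (phi, mu, alpha) by one of eight methods.
#' The recommended default is penalized maximum likelihood (`"pml"`), which
#' maximizes the likelihood multiplied by a Jeffreys-prior penalty; in small
#' samples it has smaller bias than plain maximum likelihood and, combined
#' with the simulated-annealing optimizer, converges regardless of the
#' starting values.
#'
#' Methods and their machinery:
#' * `"pml"` — penalized ML.  The scale-stationarity equation eliminates
#'   `phi` in closed form, leaving a 2-D maximization in `(mu, alpha)`
#'   solved by simulated annealing in log space, then polished by
#'   Nelder-Mead and Newton steps on the score equations.
#' * `"ml"` — maximum likelihood.  With `engine = "sann"` (default) the 1-D
#'   profile likelihood in `alpha` is annealed and polished; with
#'   `engine = "newton"` the profile estimating equation is root-found by
#'   damped Newton from the supplied random start, reproducing the fragile
#'   textbook procedure.
#' * `"mps"`, `"ad"`, `"rad"` — maximum product of spacings and
#'   (right-tail) Anderson-Darling minimum-distance estimation, annealed in
#'   log-parameter space and polished.
#' * `"mm"`, `"ols"`, `"wls"` — method of moments (Broyden quasi-Newton
#'   root-find) and ordinary/weighted least squares on the cdf (BFGS).
#'   These deliberately use a standard local solver from the random start,
#'   *without* the annealing rescue: their high failure rates under random
#'   initialization are a documented phenomenon, and a global optimizer
#'   would mask it.
#'
#' A fit is flagged `failed` if the solver errors or returns non-finite
#' values, any estimate escapes `[1e-6, 1e6]`, the method's estimating
#' equations are not satisfied to `1e-5`, or the criterion value is not
#' finite at the solution.  Samples with fewer than 4 observations (three
#' parameters plus one residual degree of freedom) or with all values equal
#' are flagged failed without fitting.
#'
#' @param data A data frame containing a column of positive lifetimes, or a
#'   numeric vector.
#' @param time Column holding the lifetimes (tidy evaluation); defaults to
#'   the first numeric column.
#' @param method Estimation method, one of `"pml"`, `"ml"`, `"mm"`,
#'   `"ols"`, `"wls"`, `"mps"`, `"ad"`, `"rad"`.
#' @param start Optional numeric starting triple `(phi0, mu0, alpha0)`.  By
#'   default a fresh `U(0, 4)` draw per coordinate, mirroring the protocol
#'   under which the estimators were compared.
#' @param seed Optional integer seed governing the random start and the
#'   annealing trajectory.
#' @param control A [sann_control()] object for the annealing-based methods.
#' @param engine For `method = "ml"`: `"sann"` or `"newton"` (see Details).
#' @param polish Logical; run the deterministic local polish (Nelder-Mead
#'   plus Newton on the score equations) after annealing.
#' @return An object of class `gg_fit`: a list with elements `params`
#'   (named estimates), `method`, `engine`, `objective` (the maximized or
#'   minimized criterion), `loglik` (unpenalized log-likelihood at the
#'   estimates), `score_norm` (max absolute estimating-equation residual),
#'   `failed`, `failure_reason`, `n`, `seed`, `start` and `data`.
#' @examples
#' d <- make_tbi_sample("D1", seed = 1)
#' fit <- fit_gg(d, method = "pml", seed = 7,
#'               control = sann_control(max_iter = 2000))
#' tidy(fit)
#' @seealso [tidy.gg_fit()], [glance.gg_fit()], [confint.gg_fit()],
#'   [gg_bootstrap_ci()]
#' @export
fit_gg <- function(data, time = NULL, method = c("pml", "ml", "mm", "ols",
                                                 "wls", "mps", "ad", "rad"),
                   start = NULL, seed = NULL, control = sann_control(),
                   engine = NULL, polish = TRUE) {
  method <- match.arg(method)
  x <- resolve_lifetimes(data, {{ time }})
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- runif(3, 0, 4)
  if (length(start) != 3L || any(!is.finite(start)) || any(start <= 0)) {
    abort("`start` must be a positive triple (phi0, mu0, alpha0).",
          class = "ggfit_error_input")
  }
  engine <- engine %||% "sann"
  fit_gg_impl(x, method, start, seed, control, engine, polish)
}

fit_gg_impl <- function(x, method, start, seed, control, engine, polish) {
  values <- lifetime_values(x)
  n <- length(values)
  base <- list(params = c(phi = NA_real_, mu = NA_real_, alpha = NA_real_),
               method = toupper(method), engine = engine,
               objective = NA_real_, loglik = NA_real_,
               score_norm = NA_real_, failed = TRUE, failure_reason = "",
               n = n, seed = seed, start = start, data = values,
               control = control)
  class(base) <- "gg_fit"
  if (n < 4L) {
    base$failure_reason <- "sample too small (n < 4)"
    return(base)
  }
  if (length(unique(values)) == 1L) {
    base$failure_reason <- "degenerate sample"
    return(base)
  }
  worker <- switch(method,
    pml = fit_worker_pml, ml = fit_worker_ml, mm = fit_worker_mm,
    ols = fit_worker_lsq, wls = fit_worker_lsq,
    mps = fit_worker_mps, ad = fit_worker_adrad, rad = fit_worker_adrad
  )
  res <- tryCatch(
    worker(values, start = start, control = control, engine = engine,
           polish = polish, method = method),
    error = function(e) list(error = conditionMessage(e))
  )
  if (!is.null(res$error)) {
    base$failure_reason <- paste("solver error:", res$error)
    return(base)
  }
  par <- res$par
  out <- base
  out$params <- setNames(par, c("phi", "mu", "alpha"))
  out$objective <- res$objective
  out$score_norm <- max(abs(res$score))
  if (all(is.finite(par)) && all(par > 0)) {
    out$loglik <- gg_loglik(values, par[1], par[2], par[3])
  }
  # failure taxonomy: non-finite solution, boundary escape, unsatisfied
  # estimating equations, or non-finite criterion
  reason <- NULL
  if (!all(is.finite(par))) {
    reason <- res$reason %||% "non-finite estimates"
  } else if (any(par < 1e-6) || any(par > 1e6)) {
    reason <- "boundary escape (estimate outside [1e-6, 1e6])"
  } else if (!is.finite(out$score_norm) || out$score_norm > 1e-5) {
    reason <- sprintf("estimating equations unsatisfied (max residual %.3g)",
                      out$score_norm)
  } else if (!is.finite(res$objective)) {
    reason <- "criterion not finite at the solution"
  } else if (pgengam(min(values), par[1], par[2], par[3]) > 1 - 1e-9 ||
             pgengam(max(values), par[1], par[2], par[3]) < 1e-9) {
    # saturated plateau: the fitted cdf is numerically 0 or 1 on the whole
    # sample, so the estimating equations vanish identically rather than
    # being solved
    reason <- "fitted distribution degenerate on the sample (cdf saturated)"
  }
  if (!is.null(res$reason) && is.null(reason)) reason <- res$reason
  out$failed <- !is.null(reason)
  out$failure_reason <- reason %||% ""
  out
}

# ---- penalized maximum likelihood --------------------------------------
fit_worker_pml <- function(x, start, control, engine, polish, method) {
  n <- length(x)
  lt <- log(x)
  obj <- pml_objective(lt)
  x0 <- log(start[2:3])
  if (!is.finite(obj(x0))) x0 <- c(-mean(lt), 0)  # deterministic fallback start
  sres <- sann_minimize(obj, x0, control)
  z <- sres$x_opt
  if (polish) {
    nm <- optim(z, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 500))
    if (nm$value <= sres$f_opt) z <- nm$par
    score2 <- function(w) {
      mu <- exp(w[1]); alpha <- exp(w[2])
      phi <- pml_phi_of(lt, w[1], w[2])
      gg_penalized_score(x, phi, mu, alpha)[c(1, 3)]
    }
    z <- newton_polish(score2, z)$x
  }
  mu <- exp(z[1]); alpha <- exp(z[2])
  phi <- pml_phi_of(lt, z[1], z[2])
  list(par = c(phi, mu, alpha),
       objective = -obj(z),
       score = gg_penalized_score(x, phi, mu, alpha))
}

# ---- maximum likelihood -------------------------------------------------
fit_worker_ml <- function(x, start, control, engine, polish, method) {
  lt <- log(x)
  if (identical(engine, "newton")) {
    return(fit_worker_ml_newton(x, lt, start))
  }
  obj <- function(la) {
    if (!is.finite(la) || abs(la) > 30) return(Inf)
    v <- -ml_profile_loglik(lt, exp(la))
    if (!is.finite(v)) Inf else v
  }
  la0 <- log(start[3])
  if (!is.finite(obj(la0))) la0 <- 0
  sres <- sann_minimize(obj, la0, control)
  la <- sres$x_opt
  if (polish) {
    op <- suppressWarnings(optimize(obj, interval = la + c(-0.5, 0.5)))
    if (op$objective <= sres$f_opt) la <- op$minimum
    hfun <- function(w) ml_profile_h(lt, exp(w))
    la <- newton_polish(hfun, la)$x
  }
  alpha <- exp(la)
  phi <- ml_profile_phi(lt, alpha)
  mu <- exp(ml_profile_logmu(lt, alpha, phi))
  list(par = c(phi, mu, alpha),
       objective = ml_profile_loglik(lt, alpha),
       score = gg_score(x, phi, mu, alpha))
}

# Profile-equation root-find by damped Newton from the random start, the
# initialization-sensitive variant whose failure rate the simulation
# harness documents.
fit_worker_ml_newton <- function(x, lt, start) {
  alpha <- start[3]
  h <- function(a) ml_profile_h(lt, a)
  ok <- FALSE
  for (i in 1:50) {
    hv <- h(alpha)
    if (!is.finite(hv)) break
    if (abs(hv) < 1e-12) { ok <- TRUE; break }
    eps <- 1e-6 * max(alpha, 1e-3)
    hp <- (h(alpha + eps) - h(alpha - eps)) / (2 * eps)
    if (!is.finite(hp) || hp == 0) break
    step <- hv / hp
    if (abs(step) > alpha / 2) step <- sign(step) * alpha / 2
    alpha <- alpha - step
    if (alpha <= 1e-8 || alpha > 1e7) break
  }
  if (!ok) {
    # Newton shot off (the profile equation is nearly flat towards the
    # lognormal boundary); expand a bracket geometrically from the start
    # and bisect.  Samples whose profile maximum sits on the boundary have
    # no sign change and stay failed: the MLE does not exist there.
    a_lo <- a_hi <- start[3]
    h0 <- h(start[3])
    root <- NULL
    if (is.finite(h0)) {
      for (i in 1:40) {
        a_new <- if (i %% 2 == 1) a_hi * 2 else a_lo / 2
        hv <- h(a_new)
        if (is.finite(hv) && hv * h0 < 0) {
          br <- sort(c(a_new, if (i %% 2 == 1) a_hi else a_lo))
          root <- tryCatch(
            stats::uniroot(h, br, tol = 1e-12)$root,
            error = function(e) NULL
          )
          break
        }
        if (i %% 2 == 1) a_hi <- a_new else a_lo <- a_new
        if (a_hi > 1e7 && a_lo < 1e-8) break
      }
    }
    if (is.null(root)) {
      return(list(par = c(NA_real_, NA_real_, alpha), objective = NA_real_,
                  score = Inf,
                  reason = "no interior profile root (the MLE may not exist)"))
    }
    alpha <- root
    ok <- TRUE
  }
  if (!is.finite(alpha)) {
    return(list(par = c(NA_real_, NA_real_, alpha), objective = NA_real_,
                score = Inf, reason = "profile equation root-find diverged"))
  }
  phi <- ml_profile_phi(lt, alpha)
  if (!is.finite(phi) || phi <= 0) {
    return(list(par = c(phi, NA_real_, alpha), objective = NA_real_,
                score = Inf, reason = "profile produced nonpositive phi"))
  }
  mu <- exp(ml_profile_logmu(lt, alpha, phi))
  # require a profile maximum, not merely a stationary point
  eps <- 1e-4 * alpha
  curv <- ml_profile_loglik(lt, alpha + eps) - 2 * ml_profile_loglik(lt, alpha) +
    ml_profile_loglik(lt, alpha - eps)
  reason <- if (is.finite(curv) && curv > 0) "profile stationary point is not a maximum"
  list(par = c(phi, mu, alpha), objective = ml_profile_loglik(lt, alpha),
       score = gg_score(x, phi, mu, alpha), reason = reason)
}

# ---- method of moments --------------------------------------------------
# First two moment equations in (mu, alpha), with phi substituted by its
# sample counterpart mean((mu t)^alpha); solved by Broyden's quasi-Newton
# method from the random start.
mm_residuals <- function(x) {
  n <- length(x)
  tb <- mean(x)
  s2 <- var(x)
  function(p) {
    mu <- p[1]; alpha <- p[2]
    if (!all(is.finite(p)) || mu <= 0 || alpha <= 0) return(c(1e8, 1e8))
    phi <- mean(exp(alpha * (log(mu) + log(x))))
    if (!is.finite(phi) || phi <= 0) return(c(1e8, 1e8))
    g1 <- exp(lgamma(phi + 1 / alpha) - lgamma(phi))
    g2 <- exp(lgamma(phi + 2 / alpha) - lgamma(phi))
    e1 <- tb - g1 / mu
    e2 <- s2 / (n * tb^2) - (g2 - g1^2) / (g2 + (n - 1) * g1^2)
    if (!all(is.finite(c(e1, e2)))) return(c(1e8, 1e8))
    c(e1, e2)
  }
}

fit_worker_mm <- function(x, start, control, engine, polish, method) {
  res <- mm_residuals(x)
  sol <- tryCatch(
    suppressWarnings(pracma::broyden(res, start[2:3], maxiter = 100, tol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(sol) || !all(is.finite(sol$zero))) {
    return(list(par = rep(NA_real_, 3), objective = NA_real_, score = Inf,
                reason = "moment equations: root-finder diverged"))
  }
  mu <- sol$zero[1]; alpha <- sol$zero[2]
  phi <- if (mu > 0 && alpha > 0) mean((mu * x)^alpha) else NA_real_
  r <- res(sol$zero)
  list(par = c(phi, mu, alpha), objective = sum(r^2), score = r)
}

# ---- ordinary / weighted least squares on the cdf ----------------------
lsq_objective <- function(x, weighted) {
  ts <- sort(x)
  n <- length(ts)
  pp <- seq_len(n) / (n + 1)
  w <- if (weighted) (n + 1)^2 * (n + 2) / (seq_len(n) * (n - seq_len(n) + 1)) else rep(1, n)
  function(p) {
    if (!all(is.finite(p)) || any(p <= 0)) return(1e10)
    v <- sum(w * (pgengam(ts, p[1], p[2], p[3]) - pp)^2)
    if (!is.finite(v)) 1e10 else v
  }
}

lsq_score <- function(x, weighted, p) {
  ts <- sort(x)
  n <- length(ts)
  pp <- seq_len(n) / (n + 1)
  w <- if (weighted) (n + 1)^2 * (n + 2) / (seq_len(n) * (n - seq_len(n) + 1)) else rep(1, n)
  resid <- pgengam(ts, p[1], p[2], p[3]) - pp
  D <- gg_delta_matrix(ts, p[1], p[2], p[3])
  as.numeric(crossprod(D, w * resid))
}

fit_worker_lsq <- function(x, start, control, engine, polish, method) {
  weighted <- identical(method, "wls")
  obj <- lsq_objective(x, weighted)
  sol <- tryCatch(
    suppressWarnings(optim(start, obj, method = "BFGS",
                           control = list(maxit = 200, reltol = 1e-12))),
    error = function(e) NULL
  )
  if (is.null(sol) || !all(is.finite(sol$par))) {
    return(list(par = rep(NA_real_, 3), objective = NA_real_, score = Inf,
                reason = "least-squares optimizer diverged"))
  }
  p <- sol$par
  if (polish && all(p > 0)) {
    # local Newton refinement of the stationarity system; cannot rescue a
    # diverged or saturated run, only sharpen a genuine local minimum
    np <- newton_polish(function(w) lsq_score(x, weighted, exp(w)), log(p),
                        tol = 1e-10)
    if (all(is.finite(np$x)) && obj(exp(np$x)) <= sol$value + 1e-12) {
      p <- exp(np$x)
    }
  }
  score <- if (all(p > 0)) lsq_score(x, weighted, p) else Inf
  list(par = p, objective = obj(p), score = score)
}

# ---- maximum product of spacings ---------------------------------------
fit_worker_mps <- function(x, start, control, engine, polish, method) {
  if (length(unique(x)) == 1L) {
    return(list(par = rep(NA_real_, 3), objective = NA_real_, score = Inf,
                reason = "all observations tied"))
  }
  obj <- function(lp) {
    if (any(!is.finite(lp)) || any(abs(lp) > 30)) return(Inf)
    v <- -mps_objective_value(x, exp(lp[1]), exp(lp[2]), exp(lp[3]))
    if (!is.finite(v)) Inf else v
  }
  anneal_polish_3d(x, obj, start, control, polish,
                   score_fun = function(p) mps_score(x, p),
                   criterion = function(v) -v)  # objective H is maximized
}

# Estimating equations of the spacings criterion: numeric gradient of H in
# raw parameter scale (identical to the Delta-based display when there are
# no ties, and the correct gradient of the substituted objective when there
# are).
mps_score <- function(x, p) {
  f <- function(q) mps_objective_value(x, q[1], q[2], q[3])
  vapply(1:3, function(j) {
    h <- 1e-6 * max(abs(p[j]), 1e-3)
    e <- replace(numeric(3), j, h)
    (f(p + e) - f(p - e)) / (2 * h)
  }, numeric(1))
}

# ---- Anderson-Darling and right-tail Anderson-Darling ------------------
ad_objective_value <- function(x, phi, mu, alpha, right_tail = FALSE) {
  ts <- sort(x)
  n <- length(ts)
  i <- seq_len(n)
  lF <- pgengam(ts, phi, mu, alpha, log.p = TRUE)
  lS <- pgengam(ts, phi, mu, alpha, lower.tail = FALSE, log.p = TRUE)
  if (right_tail) {
    n / 2 - 2 * sum(exp(lF)) - sum((2 * i - 1) * lS[n + 1 - i]) / n
  } else {
    -n - sum((2 * i - 1) * (lF[i] + lS[n + 1 - i])) / n
  }
}

ad_score <- function(x, p, right_tail = FALSE) {
  ts <- sort(x)
  n <- length(ts)
  i <- seq_len(n)
  Fi <- pgengam(ts, p[1], p[2], p[3])
  Si <- pgengam(ts, p[1], p[2], p[3], lower.tail = FALSE)
  D <- gg_delta_matrix(ts, p[1], p[2], p[3])
  if (right_tail) {
    sapply(1:3, function(j) {
      -2 * sum(D[, j]) + sum((2 * i - 1) * D[n + 1 - i, j] / Si[n + 1 - i]) / n
    })
  } else {
    sapply(1:3, function(j) {
      sum((2 * i - 1) * (D[i, j] / Fi[i] - D[n + 1 - i, j] / Si[n + 1 - i]))
    })
  }
}

fit_worker_adrad <- function(x, start, control, engine, polish, method) {
  right_tail <- identical(method, "rad")
  obj <- function(lp) {
    if (any(!is.finite(lp)) || any(abs(lp) > 30)) return(Inf)
    v <- ad_objective_value(x, exp(lp[1]), exp(lp[2]), exp(lp[3]), right_tail)
    if (!is.finite(v)) Inf else v
  }
  anneal_polish_3d(x, obj, start, control, polish,
                   score_fun = function(p) ad_score(x, p, right_tail))
}

# Shared 3-D anneal + polish driver in log-parameter space.
anneal_polish_3d <- function(x, obj, start, control, polish, score_fun,
                             criterion = identity) {
  lp0 <- log(start)
  if (!is.finite(obj(lp0))) lp0 <- c(0, -log(mean(x)), 0)
  if (!is.finite(obj(lp0))) {
    return(list(par = rep(NA_real_, 3), objective = NA_real_, score = Inf,
                reason = "criterion not finite at any starting point"))
  }
  sres <- sann_minimize(obj, lp0, control)
  z <- sres$x_opt
  if (polish) {
    nm <- optim(z, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 1000))
    if (nm$value <= sres$f_opt) z <- nm$par
    z <- newton_polish(function(w) score_fun(exp(w)), z, tol = 1e-10)$x
  }
  p <- exp(z)
  list(par = p, objective = criterion(obj(z)), score = score_fun(p))
}
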