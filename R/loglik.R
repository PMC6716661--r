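#' Log-likelihood and penalized log-likelihood of the GG distribution
#'
#' `gg_loglik` evaluates
#' \deqn{\ell = n\log\alpha - n\log\Gamma(\phi) + n\alpha\phi\log\mu
#'   + (\alpha\phi - 1)\sum\log t_i - \mu^\alpha \sum t_i^\alpha.}
#' `gg_penalized_loglik` adds the Jeffreys-prior penalty
#' [gg_penalty_log()], which reduces the small-sample bias of the maximum
#' likelihood estimator.
#'
#' @param x Numeric vector of positive lifetimes.
#' @inheritParams gengam
#' @return A scalar log-likelihood value.
#' @examples
#' x <- rgengam(50, 0.5, 0.5, 3)
#' gg_loglik(x, 0.5, 0.5, 3)
#' @export
gg_loglik <- function(x, phi, mu, alpha) {
  x <- lifetime_values(validate_lifetimes(x))
  check_gg_params(phi, mu, alpha)
  n <- length(x)
  lt <- log(x)
  # mu^alpha * sum(x^alpha) on the log scale to survive large alpha
  lsum <- alpha * log(mu) + logsumexp(alpha * lt)
  n * log(alpha) - n * lgamma(phi) + n * alpha * phi * log(mu) +
    (alpha * phi - 1) * sum(lt) - exp(lsum)
}

# Radicand of the Jeffreys penalty: phi^2 psi'(phi)^2 - psi'(phi) - 1.
# This equals mu^2 * det(per-observation Fisher matrix); it is strictly
# positive for all phi > 0 (limit pi^2/6 - 1 at 0+, ~ 1/(12 phi^2) at
# infinity) but suffers cancellation at very large phi, where the
# asymptotic form is substituted.
penalty_radicand <- function(phi) {
  r <- numeric(length(phi))
  small <- phi < 0.5
  if (any(small)) {
    # exact rewriting via psi'(phi) = 1/phi^2 + psi'(1 + phi): avoids the
    # 1/phi^2 blow-up, limit pi^2/6 - 1 at phi -> 0+
    t1 <- trigamma(1 + phi[small])
    r[small] <- (1 + phi[small]^2 * t1) * t1 - 1
  }
  if (any(!small)) {
    p <- phi[!small]
    v <- p^2 * trigamma(p)^2 - trigamma(p) - 1
    r[!small] <- ifelse(is.finite(v) & v > 0, v, 1 / (12 * p^2))
  }
  r
}

# d/dphi of the radicand
penalty_radicand_d1 <- function(phi) {
  2 * phi * trigamma(phi)^2 + 2 * phi^2 * trigamma(phi) * psigamma(phi, 2) -
    psigamma(phi, 2)
}

#' Log of the Jeffreys-prior penalty for the GG distribution
#'
#' The penalty is proportional to
#' \eqn{\sqrt{\phi^2\psi'(\phi)^2 - \psi'(\phi) - 1}\,/(\mu\alpha)}, where
#' \eqn{\psi'} is the trigamma function.  The radicand is exactly
#' \eqn{\mu^2} times the determinant of the per-observation Fisher
#' information matrix (so the \eqn{1/\mu} factor is the Jeffreys prior);
#' the additional \eqn{1/\alpha} factor matches the Weibull Jeffreys prior
#' in the `phi = 1` sub-model and reduces the bias of \eqn{\hat\alpha}.
#'
#' @inheritParams gengam
#' @return The log-penalty (up to an additive constant).
#' @examples
#' gg_penalty_log(0.5, 0.5, 3)
#' @export
gg_penalty_log <- function(phi, mu, alpha) {
  check_gg_params(phi, mu, alpha)
  r <- penalty_radicand(phi)
  if (any(r <= 0)) {
    abort("Penalty radicand is nonpositive; phi is outside the representable range.",
          class = "ggfit_error_domain")
  }
  0.5 * log(r) - log(mu) - log(alpha)
}

#' @rdname gg_loglik
#' @export
gg_penalized_loglik <- function(x, phi, mu, alpha) {
  gg_loglik(x, phi, mu, alpha) + gg_penalty_log(phi, mu, alpha)
}

# Score (gradient) of the log-likelihood, in the order (phi, mu, alpha).
gg_score <- function(x, phi, mu, alpha) {
  n <- length(x)
  lt <- log(x)
  ta <- exp(alpha * lt)
  ma <- exp(alpha * log(mu))
  c(
    -n * digamma(phi) + n * alpha * log(mu) + alpha * sum(lt),
    n * alpha * phi / mu - alpha * ma / mu * sum(ta),
    n / alpha + n * phi * log(mu) + phi * sum(lt) -
      ma * sum(ta * (log(mu) + lt))
  )
}

# Score of the penalized log-likelihood (order phi, mu, alpha).
gg_penalized_score <- function(x, phi, mu, alpha) {
  r <- penalty_radicand(phi)
  rp <- penalty_radicand_d1(phi)
  gg_score(x, phi, mu, alpha) + c(0.5 * rp / r, -1 / mu, -1 / alpha)
}

# --- profile structure of the ML problem --------------------------------
# Given alpha, the mu- and phi-stationarity equations have closed forms.
# With c_i = log t_i - mean(log t) and w_i = exp(alpha c_i):
#   phi_hat(alpha)  = sum(w) / (alpha * sum(w c))      (> 0 by Chebyshev)
#   log mu_hat      = (log phi_hat - B)/alpha - mean(log t),
#                     B = log(mean(w))
#   profile loglik  = n log alpha - sum(log t) + n g(phi_hat) - n phi_hat B,
#                     g(p) = p log p - p - lgamma(p)
#   h(alpha)        = psi(phi_hat) - log(phi_hat) + B
# This centered form stays accurate as alpha -> 0, where phi_hat grows like
# 1/alpha^2 and the family approaches its lognormal boundary; the naive
# evaluation cancels catastrophically there and invents spurious maxima.
ml_profile_parts <- function(lt, alpha) {
  n <- length(lt)
  m <- mean(lt)
  cc <- lt - m
  ac <- alpha * cc
  if (max(abs(ac)) < 0.5) {
    # small-deviation branch: sum(c) = 0 exactly, so work with expm1(ac)
    # to keep full relative accuracy as alpha -> 0
    w1 <- expm1(ac)
    swc <- sum(w1 * cc)
    if (swc <= 0) return(NULL)
    phi <- (n + sum(w1)) / (alpha * swc)
    B <- log1p(sum(w1) / n)
  } else {
    amax <- max(ac)
    w <- exp(ac - amax)
    swc <- sum(w * cc)
    if (swc <= 0) return(NULL)
    phi <- sum(w) / (alpha * swc)
    B <- amax + log(mean(w))
  }
  list(phi = phi, B = B, m = m)
}

ml_profile_phi <- function(lt, alpha) {
  p <- ml_profile_parts(lt, alpha)
  if (is.null(p)) NA_real_ else p$phi
}

ml_profile_logmu <- function(lt, alpha, phi) {
  p <- ml_profile_parts(lt, alpha)
  (log(phi) - p$B) / alpha - p$m
}

# p log p - p - lgamma(p), with the Stirling branch where the direct form
# cancels (it equals 0.5 log p - 0.5 log(2 pi) - 1/(12 p) + O(p^-3))
stirling_g <- function(p) {
  ifelse(p < 1e8,
         p * log(p) - p - lgamma(p),
         0.5 * log(p) - 0.5 * log(2 * pi) - 1 / (12 * p))
}

# Profile log-likelihood in alpha (phi and mu concentrated out).
ml_profile_loglik <- function(lt, alpha) {
  n <- length(lt)
  p <- ml_profile_parts(lt, alpha)
  if (is.null(p) || !is.finite(p$phi) || p$phi <= 0) return(-Inf)
  n * log(alpha) - sum(lt) + n * stirling_g(p$phi) - n * p$phi * p$B
}

# One-dimensional estimating equation for alpha (derived symbolically from
# the log-likelihood; the printed display in the source material is
# typographically unreliable).
ml_profile_h <- function(lt, alpha) {
  p <- ml_profile_parts(lt, alpha)
  if (is.null(p) || !is.finite(p$phi) || p$phi <= 0) return(NA_real_)
  digamma(p$phi) - log(p$phi) + p$B
}

# --- profile structure of the PML problem -------------------------------
# The mu-stationarity equation of the penalized log-likelihood solves for
# phi in closed form:
#   phi = (alpha mu^alpha sum(t^alpha) + 1) / (n alpha)
# Substituting it back makes the mu-score vanish identically, so the
# penalized problem is an unconstrained 2-D maximization in (mu, alpha)
# whose stationary points are exactly the joint stationary points.
pml_phi_of <- function(lt, lmu, lalpha) {
  n <- length(lt)
  alpha <- exp(lalpha)
  lsum <- alpha * lmu + logsumexp(alpha * lt)
  (alpha * exp(lsum) + 1) / (n * alpha)
}

# Negative penalized log-likelihood as a function of (log mu, log alpha).
pml_objective <- function(lt) {
  n <- length(lt)
  slt <- sum(lt)
  function(x) {
    if (any(!is.finite(x)) || any(abs(x) > 30)) return(Inf)
    lmu <- x[1]
    lalpha <- x[2]
    alpha <- exp(lalpha)
    lsum <- alpha * lmu + logsumexp(alpha * lt)
    if (!is.finite(lsum) || lsum > 700) return(Inf)
    phi <- (alpha * exp(lsum) + 1) / (n * alpha)
    if (!is.finite(phi) || phi <= 0) return(Inf)
    r <- penalty_radicand(phi)
    lp <- (n - 1) * lalpha + 0.5 * log(r) + (n * alpha * phi - 1) * lmu +
      (alpha * phi - 1) * slt - exp(lsum) - n * lgamma(phi)
    if (!is.finite(lp)) return(Inf)
    -lp
  }
}

#' Uniform spacings of a sample under a GG model
#'
#' The spacings are successive cdf increments at the order statistics,
#' \eqn{D_i = F(t_{(i)}) - F(t_{(i-1)})} for \eqn{i = 1, \dots, n+1} with
#' \eqn{F(t_{(0)}) = 0} and \eqn{F(t_{(n+1)}) = 1}; they sum to one.  Tied
#' order statistics produce zero spacings; the maximum product of spacings
#' estimator replaces those by the density at the tied value, and the `tie`
#' column flags where that substitution applies.  Ties are detected by exact
#' floating-point equality, appropriate for data recorded on a discrete
#' grid such as whole days.
#'
#' @param x Numeric vector of positive lifetimes.
#' @inheritParams gengam
#' @return A tibble with `n + 1` rows and columns `d` (the spacing) and
#'   `tie` (logical substitution flag).
#' @examples
#' sp <- gg_spacings(c(1, 2, 2, 5), 0.5, 0.5, 3)
#' sum(sp$d[!sp$tie])
#' @export
gg_spacings <- function(x, phi, mu, alpha) {
  x <- lifetime_values(validate_lifetimes(x))
  check_gg_params(phi, mu, alpha)
  ts <- sort(x)
  Fi <- c(0, pgengam(ts, phi, mu, alpha), 1)
  d <- diff(Fi)
  tie <- c(FALSE, ts[-1] == ts[-length(ts)], FALSE)
  tibble(d = d, tie = tie)
}

# Log of the mean log-spacing objective H (maximized by MPS), with the
# tie substitution: zero spacings from exact ties are replaced by the
# density at the tied value.
mps_objective_value <- function(x, phi, mu, alpha) {
  ts <- sort(x)
  n <- length(ts)
  lF <- pgengam(ts, phi, mu, alpha, log.p = TRUE)
  Fi <- exp(lF)
  Fs <- c(0, Fi, 1)
  d <- diff(Fs)
  tie <- c(FALSE, ts[-1] == ts[-n], FALSE)
  ld <- numeric(n + 1)
  pos <- d > 0 & !tie
  ld[pos] <- log(d[pos])
  if (any(tie)) {
    idx <- which(tie)
    ld[idx] <- dgengam(ts[idx - 1L], phi, mu, alpha, log = TRUE)
  }
  bad <- !tie & d <= 0
  if (any(bad)) return(-Inf)
  mean(ld)
}
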