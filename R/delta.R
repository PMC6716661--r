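#' Partial derivatives of the GG cdf with respect to the parameters
#'
#' The least-squares, maximum-product-of-spacings and Anderson-Darling
#' estimating equations all involve
#' \eqn{\Delta_j(t) = \partial F(t)/\partial \theta_j} for
#' \eqn{\theta = (\phi, \mu, \alpha)}.  The derivatives with respect to the
#' scale and the second shape have closed forms,
#' \deqn{\Delta_2 = \frac{\alpha (\mu t)^{\phi\alpha} e^{-(\mu t)^\alpha}}
#'   {\mu\,\Gamma(\phi)}, \qquad
#'   \Delta_3 = \frac{\log(\mu t) (\mu t)^{\phi\alpha} e^{-(\mu t)^\alpha}}
#'   {\Gamma(\phi)},}
#' while the derivative with respect to `phi` differentiates the regularized
#' lower incomplete gamma function in its order and is computed by
#' Richardson-extrapolated central differences.
#'
#' @param t Positive quantile(s).
#' @inheritParams gengam
#' @param j Which derivative: 1 (`phi`), 2 (`mu`) or 3 (`alpha`).
#' @return Numeric vector of derivative values.
#' @examples
#' gg_delta(1.2, 0.5, 0.5, 3, j = 2)
#' @export
gg_delta <- function(t, phi, mu, alpha, j) {
  check_gg_params(phi, mu, alpha)
  if (any(t <= 0)) {
    abort("`t` must be positive.", class = "ggfit_error_domain")
  }
  j <- as.integer(j)
  lmt <- log(mu) + log(t)
  z <- exp(alpha * lmt)
  if (j == 1L) {
    dF_dphi(z, phi)
  } else if (j == 2L) {
    exp(log(alpha) + phi * alpha * lmt - z - log(mu) - lgamma(phi))
  } else if (j == 3L) {
    lmt * exp(phi * alpha * lmt - z - lgamma(phi))
  } else {
    abort("`j` must be 1, 2 or 3.", class = "ggfit_error_input")
  }
}

# d/da P(a, z) (regularized lower incomplete gamma wrt its order) by
# central differences with one Richardson extrapolation step.
dF_dphi <- function(z, a) {
  h <- 1e-4 * pmax(a, 1e-2)
  d1 <- (pgamma(z, a + h) - pgamma(z, a - h)) / (2 * h)
  d2 <- (pgamma(z, a + h / 2) - pgamma(z, a - h / 2)) / h
  (4 * d2 - d1) / 3
}

# Delta matrix (length(t) x 3) used by the estimating equations.
gg_delta_matrix <- function(t, phi, mu, alpha) {
  cbind(gg_delta(t, phi, mu, alpha, 1L),
        gg_delta(t, phi, mu, alpha, 2L),
        gg_delta(t, phi, mu, alpha, 3L))
}
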