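# Independent oracles used across the test files.

# cdf by adaptive quadrature of the density (independent of pgamma)
quad_cdf <- function(t, phi, mu, alpha) {
  integrand <- function(w) {
    alpha * mu^(alpha * phi) * w^(alpha * phi - 1) *
      exp(-(mu * w)^alpha) / gamma(phi)
  }
  integrate(integrand, 0, t, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# brute-force Anderson-Darling statistic from the textbook formula
ad_bruteforce <- function(x, phi, mu, alpha) {
  u <- sort(pgengam(sort(x), phi, mu, alpha))
  n <- length(u)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u[i]) + log(1 - u[n + 1 - i])))
}

# high-order Richardson extrapolation of dF/dphi from the cdf alone
richardson_dF_dphi <- function(t, phi, mu, alpha, h0 = 1e-2) {
  f <- function(p) pgengam(t, p, mu, alpha)
  hs <- h0 / 2^(0:5)
  d <- sapply(hs, function(h) (f(phi + h) - f(phi - h)) / (2 * h))
  # Richardson triangle, error order h^2 per level
  for (k in 1:5) {
    d <- (4^k * d[-1] - d[-length(d)]) / (4^k - 1)
  }
  d
}

# one-pass bias/MSE recomputation oracle for the simulation study
recompute_bias_mse <- function(estimates, theta) {
  out <- list()
  for (m in unique(estimates$method)) {
    for (n in unique(estimates$n)) {
      sub <- estimates[estimates$method == m & estimates$n == n &
                         !estimates$failed, ]
      out[[paste(m, n)]] <- c(
        bias_phi = sum(sub$phi - theta[1]) / nrow(sub),
        mse_alpha = sum((sub$alpha - theta[3])^2) / nrow(sub)
      )
    }
  }
  out
}

light_control <- function(seed = NULL, max_iter = 3000) {
  sann_control(max_iter = max_iter, m = 50, stop_repeat = 200,
               k_min = 1e-6, seed = seed)
}
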