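test_that("density reduces to the closed-form sub-models", {
  tt <- c(0.05, 0.3, 0.8, 1.7, 4.2)
  # phi = 1: Weibull with shape alpha and scale 1/mu
  for (mu in c(0.5, 2)) {
    for (alpha in c(0.7, 1, 3.2)) {
      expect_equal(dgengam(tt, 1, mu, alpha),
                   stats::dweibull(tt, shape = alpha, scale = 1 / mu),
                   tolerance = 1e-10)
      expect_equal(pgengam(tt, 1, mu, alpha),
                   stats::pweibull(tt, shape = alpha, scale = 1 / mu),
                   tolerance = 1e-10)
      expect_equal(sgengam(tt, 1, mu, alpha), exp(-(mu * tt)^alpha),
                   tolerance = 1e-10)
      ref_h <- stats::dweibull(tt, alpha, 1 / mu) /
        stats::pweibull(tt, alpha, 1 / mu, lower.tail = FALSE)
      fin <- is.finite(ref_h)  # the naive ratio underflows deep in the tail
      expect_equal(hgengam(tt, 1, mu, alpha)[fin], ref_h[fin],
                   tolerance = 1e-10)
    }
  }
  # alpha = 1: Gamma with shape phi and rate mu
  for (phi in c(0.3, 1, 2.5)) {
    expect_equal(dgengam(tt, phi, 1.3, 1), dgamma(tt, phi, rate = 1.3),
                 tolerance = 1e-10)
    expect_equal(pgengam(tt, phi, 1.3, 1), pgamma(tt, phi, rate = 1.3),
                 tolerance = 1e-10)
  }
  # exponential point value
  expect_equal(dgengam(0.5, 1, 1, 1), exp(-0.5), tolerance = 1e-12)
})

test_that("density and cdf agree with an independent reference implementation", {
  # flexsurv's original-parameterization generalized gamma:
  # shape = alpha, scale = 1/mu, k = phi
  tt <- c(0.05, 0.4, 1.1, 2.7, 6)
  for (p in list(c(0.5, 0.5, 3), c(0.4, 1.5, 4), c(2.3, 0.7, 1.1))) {
    expect_equal(dgengam(tt, p[1], p[2], p[3]),
                 flexsurv::dgengamma.orig(tt, shape = p[3], scale = 1 / p[2],
                                          k = p[1]),
                 tolerance = 1e-12)
    expect_equal(pgengam(tt, p[1], p[2], p[3]),
                 flexsurv::pgengamma.orig(tt, shape = p[3], scale = 1 / p[2],
                                          k = p[1]),
                 tolerance = 1e-12)
  }
})

test_that("density normalizes to one across the parameter space", {
  set.seed(11)
  phis <- exp(runif(20, log(0.1), log(5)))
  alphas <- exp(runif(20, log(0.5), log(8)))
  mus <- exp(runif(20, log(0.2), log(4)))
  for (k in 1:20) {
    f <- function(t) dgengam(t, phis[k], mus[k], alphas[k])
    # piecewise quadrature: spiky shapes defeat a single adaptive pass
    cuts <- qgengam(c(0.5, 0.999), phis[k], mus[k], alphas[k])
    total <- integrate(f, 0, cuts[1], rel.tol = 1e-10)$value +
      integrate(f, cuts[1], cuts[2], rel.tol = 1e-10)$value +
      integrate(f, cuts[2], Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("cdf agrees with quadrature of the density and is monotone", {
  grid <- seq(0.05, 2.5, length.out = 20)
  for (t in grid) {
    expect_equal(pgengam(t, 0.4, 1.5, 4), quad_cdf(t, 0.4, 1.5, 4),
                 tolerance = 1e-8)
  }
  Fi <- pgengam(grid, 0.5, 0.5, 3)
  expect_true(all(diff(Fi) >= 0))
  expect_identical(pgengam(0, 0.5, 0.5, 3), 0)
  # complement identity
  expect_equal(Fi + sgengam(grid, 0.5, 0.5, 3), rep(1, length(grid)),
               tolerance = 1e-12)
  expect_identical(sgengam(0, 0.5, 0.5, 3), 1)
})

test_that("hazard matches its definition and known shapes", {
  grid <- seq(0.2, 5, length.out = 40)
  h <- hgengam(grid, 2, 0.7, 1.4)
  expect_equal(h, dgengam(grid, 2, 0.7, 1.4) / sgengam(grid, 2, 0.7, 1.4),
               tolerance = 1e-10)
  # exponential case: constant hazard mu
  expect_equal(hgengam(grid, 1, 0.8, 1), rep(0.8, length(grid)),
               tolerance = 1e-12)
  # increasing and decreasing shape families
  expect_true(all(diff(hgengam(grid, 3, 0.5, 1.5)) > 0))
  expect_true(all(diff(hgengam(grid, 0.5, 1, 0.8)) < 0))
})

test_that("moments and summary statistics are exact and MC-consistent", {
  expect_equal(gg_moment(0, 0.5, 0.5, 3), 1, tolerance = 1e-14)
  expect_equal(gg_moment(1, 1, 2, 1), 0.5, tolerance = 1e-14)
  st <- gg_stats(1, 2, 1)
  expect_equal(st$mean, 0.5, tolerance = 1e-14)
  expect_equal(st$variance, 0.25, tolerance = 1e-14)
  st2 <- gg_stats(0.5, 0.5, 3)
  expect_equal(st2$variance,
               gg_moment(2, 0.5, 0.5, 3) - gg_moment(1, 0.5, 0.5, 3)^2,
               tolerance = 1e-12)
  expect_error(gg_moment(-3, 0.5, 0.5, 1), class = "ggfit_error_domain")
  # Monte-Carlo cross-check of the first moment
  set.seed(21)
  draws <- rgengam(1e6, 0.5, 0.5, 3)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - gg_moment(1, 0.5, 0.5, 3)), 3 * se)
})

test_that("mean residual lifetime matches its defining integral", {
  pars <- list(c(0.410, 0.025, 3.040), c(0.268, 0.045, 4.658),
               c(0.148, 0.053, 6.065))
  for (p in pars) {
    expect_equal(gg_mrl(0, p[1], p[2], p[3]),
                 gg_stats(p[1], p[2], p[3])$mean, tolerance = 1e-12)
    for (t0 in c(5, 10, 20)) {
      oracle <- integrate(function(w) sgengam(w, p[1], p[2], p[3]),
                          t0, Inf, rel.tol = 1e-10)$value /
        sgengam(t0, p[1], p[2], p[3])
      expect_equal(gg_mrl(t0, p[1], p[2], p[3]), oracle, tolerance = 1e-6)
    }
  }
  prof <- gg_mrl_profile(pars[[1]], t_grid = c(10, 0, 5))
  expect_identical(prof$t, c(0, 5, 10))
  expect_equal(prof$mrl[1], gg_stats(0.410, 0.025, 3.040)$mean,
               tolerance = 1e-10)
})

test_that("random generation is reproducible and distributionally correct", {
  set.seed(5)
  a <- rgengam(100, 0.5, 0.5, 3)
  set.seed(5)
  b <- rgengam(100, 0.5, 0.5, 3)
  expect_identical(a, b)

  set.seed(6)
  draws <- rgengam(1e5, 0.5, 0.5, 3)
  # the gamma-power transform must be an exact Gamma(phi, 1)
  ks <- suppressWarnings(stats::ks.test((0.5 * draws)^3, "pgamma", 0.5))
  expect_gt(ks$p.value, 0.01)
  # empirical cdf within the Dvoretzky-Kiefer-Wolfowitz band of the model cdf
  n <- length(draws)
  eps <- sqrt(log(2 / 0.001) / (2 * n))
  ecdf_vals <- seq_len(n) / n
  Fi <- pgengam(sort(draws), 0.5, 0.5, 3)
  expect_lt(max(abs(ecdf_vals - Fi)), eps)
})

test_that("quantile function inverts the cdf", {
  p <- c(0.01, 0.2, 0.5, 0.9, 0.999)
  q <- qgengam(p, 0.4, 1.5, 4)
  expect_equal(pgengam(q, 0.4, 1.5, 4), p, tolerance = 1e-10)
})

test_that("domain violations raise classed errors", {
  expect_error(dgengam(1, -1, 1, 1), class = "ggfit_error_domain")
  expect_error(dgengam(-1, 1, 1, 1), class = "ggfit_error_domain")
  expect_error(gg_mrl(-1, 1, 1, 1), class = "ggfit_error_domain")
  expect_error(validate_lifetimes(c(1, -2, 3)), class = "ggfit_error_input")
  expect_error(validate_lifetimes(numeric(0)), class = "ggfit_error_input")
})
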