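test_that("log-likelihood matches the summed log-density and its gradient", {
  set.seed(2)
  x <- rgengam(60, 0.5, 0.5, 3)
  expect_equal(gg_loglik(x, 0.7, 0.4, 2.5),
               sum(dgengam(x, 0.7, 0.4, 2.5, log = TRUE)), tolerance = 1e-10)
  expect_equal(gg_loglik(1, 1, 1, 1), -1, tolerance = 1e-12)
  # analytic score vs central finite differences
  p0 <- c(0.7, 0.4, 2.5)
  fd <- vapply(1:3, function(j) {
    h <- 1e-6 * p0[j]
    e <- replace(numeric(3), j, h)
    (gg_loglik(x, (p0 + e)[1], (p0 + e)[2], (p0 + e)[3]) -
       gg_loglik(x, (p0 - e)[1], (p0 - e)[2], (p0 - e)[3])) / (2 * h)
  }, numeric(1))
  sc <- ggfit:::gg_score(x, p0[1], p0[2], p0[3])
  expect_equal(sc, fd, tolerance = 1e-6)
})

test_that("the Jeffreys penalty is well-behaved and invertible", {
  phis <- 10^seq(-3, 3, length.out = 25)
  pen <- vapply(phis, function(p) gg_penalty_log(p, 1, 1), numeric(1))
  expect_true(all(is.finite(pen)))
  # decreasing in mu and alpha
  expect_gt(gg_penalty_log(0.5, 1, 1), gg_penalty_log(0.5, 2, 1))
  expect_gt(gg_penalty_log(0.5, 1, 1), gg_penalty_log(0.5, 1, 2))
  # algebraic inversion recovers the radicand
  for (phi in c(0.148, 0.7, 3)) {
    lhs <- exp(2 * (gg_penalty_log(phi, 1.7, 2.3) + log(1.7) + log(2.3)))
    expect_equal(lhs, phi^2 * trigamma(phi)^2 - trigamma(phi) - 1,
                 tolerance = 1e-12)
  }
  # the small-phi branch joins the direct formula continuously
  direct <- function(p) p^2 * trigamma(p)^2 - trigamma(p) - 1
  for (phi in c(0.01, 0.2, 0.499)) {
    expect_equal(ggfit:::penalty_radicand(phi), direct(phi),
                 tolerance = 1e-10)
  }
})

test_that("penalized log-likelihood = log-likelihood + penalty, vanishing per obs", {
  set.seed(3)
  x200 <- rgengam(200, 0.5, 0.5, 3)
  p <- c(0.6, 0.45, 2.8)
  expect_identical(gg_penalized_loglik(x200, p[1], p[2], p[3]),
                   gg_loglik(x200, p[1], p[2], p[3]) +
                     gg_penalty_log(p[1], p[2], p[3]))
  # penalty contribution per observation shrinks on nested samples
  gaps <- vapply(c(50, 200), function(n) {
    abs(gg_penalized_loglik(x200[1:n], p[1], p[2], p[3]) -
          gg_loglik(x200[1:n], p[1], p[2], p[3])) / n
  }, numeric(1))
  expect_lt(gaps[2], gaps[1])
  # penalized score vs finite differences
  fd <- vapply(1:3, function(j) {
    h <- 1e-6 * p[j]
    e <- replace(numeric(3), j, h)
    (gg_penalized_loglik(x200, (p + e)[1], (p + e)[2], (p + e)[3]) -
       gg_penalized_loglik(x200, (p - e)[1], (p - e)[2], (p - e)[3])) / (2 * h)
  }, numeric(1))
  expect_equal(ggfit:::gg_penalized_score(x200, p[1], p[2], p[3]), fd,
               tolerance = 1e-6)
})

test_that("the profile phi is positive for any sample with two distinct values", {
  set.seed(4)
  for (k in 1:1000) {
    n <- sample(4:12, 1)
    lt <- log(rgengam(n, runif(1, 0.2, 2), runif(1, 0.2, 2), runif(1, 0.5, 5)))
    a <- runif(1, 0.1, 6)
    phi <- ggfit:::ml_profile_phi(lt, a)
    expect_true(is.finite(phi) && phi > 0)
  }
})

test_that("the profile estimating equation matches the profile maximum", {
  set.seed(5)
  x <- rgengam(150, 0.5, 0.5, 3)
  lt <- log(x)
  op <- optimize(function(a) ggfit:::ml_profile_loglik(lt, a), c(0.5, 12),
                 maximum = TRUE)
  expect_lt(abs(ggfit:::ml_profile_h(lt, op$maximum)), 1e-4)
  # h is the sign-definite reduction of the alpha-score: the full score
  # vanishes at the profile optimum
  phi <- ggfit:::ml_profile_phi(lt, op$maximum)
  mu <- exp(ggfit:::ml_profile_logmu(lt, op$maximum, phi))
  expect_lt(max(abs(ggfit:::gg_score(x, phi, mu, op$maximum))) /
              max(1, abs(gg_loglik(x, phi, mu, op$maximum))), 1e-4)
})

test_that("ML recovers the truth on average at n = 300", {
  theta <- c(0.5, 0.5, 3)
  est <- matrix(NA_real_, 120, 3)
  for (k in 1:120) {
    set.seed(4000 + k)
    x <- rgengam(300, theta[1], theta[2], theta[3])
    f <- fit_gg(x, method = "ml", start = runif(3, 0, 4),
                control = light_control(seed = k))
    if (!f$failed) est[k, ] <- f$params
  }
  est <- est[complete.cases(est), ]
  expect_gt(nrow(est), 100)
  for (j in 1:3) {
    se <- sd(est[, j]) / sqrt(nrow(est))
    # allow the residual O(1/n) finite-sample bias of ML on top of the
    # Monte-Carlo error (alpha still carries a visible positive bias here)
    expect_lt(abs(mean(est[, j]) - theta[j]), 3 * se + 0.07 * theta[j])
  }
})

test_that("fitted mean is functionally invariant on exponential data", {
  set.seed(8)
  x <- rexp(1000, rate = 2)
  f <- fit_gg(x, method = "ml", start = c(1, 1, 1),
              control = light_control(seed = 1))
  expect_false(f$failed)
  p <- f$params
  expect_lt(abs(gg_stats(p[1], p[2], p[3])$mean - mean(x)) / mean(x), 0.05)
})

test_that("PML and ML estimates converge to each other on large samples", {
  set.seed(9)
  x <- rgengam(1e4, 0.5, 0.5, 3)
  fp <- fit_gg(x, method = "pml", start = c(1, 1, 1),
               control = light_control(seed = 2))
  fm <- fit_gg(x, method = "ml", start = c(1, 1, 1),
               control = light_control(seed = 2))
  expect_false(fp$failed)
  expect_false(fm$failed)
  expect_lt(max(abs(fp$params - fm$params) / fm$params), 1e-2)
})

test_that("MPS agrees with ML asymptotically and handles ties", {
  set.seed(10)
  x <- rgengam(1e4, 0.5, 0.5, 3)
  fs <- fit_gg(x, method = "mps", start = c(1, 1, 1),
               control = light_control(seed = 3))
  fm <- fit_gg(x, method = "ml", start = c(1, 1, 1),
               control = light_control(seed = 3))
  expect_false(fs$failed)
  expect_lt(max(abs(fs$params - fm$params) / fm$params), 1e-2)

  # spacings telescope to one without ties
  xs <- rgengam(30, 0.5, 0.5, 3)
  sp <- gg_spacings(xs, 0.6, 0.4, 2.5)
  expect_equal(sum(sp$d), 1, tolerance = 1e-12)
  expect_false(any(sp$tie))

  # a duplicated value zeroes the naive product but not the substituted one
  xdup <- c(xs, xs[5])
  spd <- gg_spacings(xdup, 0.6, 0.4, 2.5)
  expect_true(any(spd$tie))
  expect_true(any(spd$d[spd$tie] == 0))
  H <- ggfit:::mps_objective_value(xdup, 0.6, 0.4, 2.5)
  expect_true(is.finite(H))
  fdup <- fit_gg(xdup, method = "mps", start = c(1, 1, 1),
                 control = light_control(seed = 4))
  expect_false(fdup$failed)
})

test_that("Anderson-Darling criterion matches an independent implementation", {
  set.seed(12)
  for (k in 1:10) {
    x <- rgengam(25, runif(1, 0.3, 2), runif(1, 0.3, 2), runif(1, 0.8, 4))
    p <- c(runif(1, 0.3, 2), runif(1, 0.3, 2), runif(1, 0.8, 4))
    expect_equal(ggfit:::ad_objective_value(x, p[1], p[2], p[3]),
                 ad_bruteforce(x, p[1], p[2], p[3]), tolerance = 1e-10)
  }
})

test_that("AD/RAD minimize their criteria and are consistent", {
  set.seed(13)
  x <- rgengam(200, 0.4, 1.5, 4)
  for (m in c("ad", "rad")) {
    f <- fit_gg(x, method = m, start = runif(3, 0, 4),
                control = light_control(seed = 14))
    expect_false(f$failed)
    # minimality at the solution relative to the truth
    truth_val <- ggfit:::ad_objective_value(x, 0.4, 1.5, 4,
                                            right_tail = m == "rad")
    expect_lte(f$objective, truth_val + 1e-10)
  }
  # consistency at larger n
  est <- matrix(NA_real_, 8, 3)
  for (k in 1:8) {
    set.seed(600 + k)
    xx <- rgengam(3000, 0.4, 1.5, 4)
    fk <- fit_gg(xx, method = "ad", start = runif(3, 0, 4),
                 control = light_control(seed = k))
    if (!fk$failed) est[k, ] <- fk$params
  }
  est <- est[complete.cases(est), ]
  expect_gte(nrow(est), 6)
  expect_lt(max(abs(colMeans(est) - c(0.4, 1.5, 4)) / c(0.4, 1.5, 4)), 0.05)
})

test_that("least squares succeeds from an informed start and satisfies its equations", {
  set.seed(15)
  x <- rgengam(100, 0.5, 0.5, 3)
  for (m in c("ols", "wls")) {
    f <- fit_gg(x, method = m, start = c(0.5, 0.5, 3))
    expect_false(f$failed)
    expect_lt(f$score_norm, 1e-6)
    # minimality probe against random points
    obj <- ggfit:::lsq_objective(x, m == "wls")
    set.seed(16)
    probes <- replicate(100, obj(runif(3, 0, 4)))
    expect_true(all(f$objective <= probes + 1e-12))
  }
  # WLS criterion equals the manually weighted sum of squares
  ts <- sort(x)
  n <- length(ts)
  i <- seq_len(n)
  w <- (n + 1)^2 * (n + 2) / (i * (n - i + 1))
  p <- c(0.6, 0.5, 2.7)
  manual <- sum(w * (pgengam(ts, p[1], p[2], p[3]) - i / (n + 1))^2)
  expect_equal(ggfit:::lsq_objective(x, TRUE)(p), manual, tolerance = 1e-12)
})

test_that("method of moments solves its equations when it converges", {
  # the first moment equation is exact at mu = 1/mean on exponential data
  set.seed(17)
  xe <- rexp(1e5)
  res <- ggfit:::mm_residuals(xe)
  expect_lt(abs(res(c(1 / mean(xe), 1))[1]), 1e-10)
  # a successful fit satisfies both residuals to 1e-8
  set.seed(18)
  ok <- NULL
  for (k in 1:40) {
    x <- rgengam(200, 0.5, 0.5, 3)
    f <- fit_gg(x, method = "mm", start = runif(3, 0, 4))
    if (!f$failed) { ok <- list(f = f, x = x); break }
  }
  expect_false(is.null(ok))
  r <- ggfit:::mm_residuals(ok$x)(ok$f$params[2:3])
  expect_lt(max(abs(r)), 1e-8)
})

test_that("penalization shrinks the small-sample bias of the shape phi", {
  # replicates where both the penalized and the plain ML fit succeed
  N <- 250
  ep <- em <- matrix(NA_real_, N, 3)
  ctl <- sann_control(max_iter = 4000, m = 50, stop_repeat = 200,
                      k_min = 1e-6)
  for (k in seq_len(N)) {
    set.seed(12000 + k)
    x <- rgengam(20, 0.5, 0.5, 3)
    sp <- runif(3, 0, 4)
    sm <- runif(3, 0, 4)
    fp <- fit_gg(x, method = "pml", start = sp, control = ctl)
    fm <- fit_gg(x, method = "ml", start = sm, engine = "newton")
    if (!fp$failed) ep[k, ] <- fp$params
    if (!fm$failed) em[k, ] <- fm$params
  }
  expect_true(all(complete.cases(ep)))  # the penalized fit never fails
  both <- complete.cases(ep) & complete.cases(em)
  expect_gt(sum(both), 100)
  expect_lt(abs(mean(ep[both, 1]) - 0.5), abs(mean(em[both, 1]) - 0.5))
})

test_that("partial cdf derivatives match their closed forms and refinements", {
  t0 <- 1.2
  p <- c(0.5, 0.5, 3)
  d2 <- gg_delta(t0, p[1], p[2], p[3], 2)
  z <- (p[2] * t0)^p[3]
  expect_equal(d2, p[3] * (p[2] * t0)^(p[1] * p[3]) * exp(-z) /
                 (p[2] * gamma(p[1])), tolerance = 1e-12)
  # Delta3 sign follows sign(log(mu t))
  expect_lt(gg_delta(1.2, 0.5, 0.5, 3, 3), 0)   # mu*t = 0.6 < 1
  expect_gt(gg_delta(3.0, 0.5, 0.5, 3, 3), 0)   # mu*t = 1.5 > 1
  # Delta1 against a high-order Richardson refinement of the cdf
  for (t0 in c(0.4, 1.2, 2.5)) {
    expect_equal(gg_delta(t0, p[1], p[2], p[3], 1),
                 richardson_dF_dphi(t0, p[1], p[2], p[3]), tolerance = 1e-8)
  }
  # Delta2 and Delta3 are the mu- and alpha-derivatives of the cdf
  h <- 1e-6
  expect_equal(gg_delta(1.2, 0.5, 0.5, 3, 2),
               (pgengam(1.2, 0.5, 0.5 + h, 3) -
                  pgengam(1.2, 0.5, 0.5 - h, 3)) / (2 * h), tolerance = 1e-6)
  expect_equal(gg_delta(1.2, 0.5, 0.5, 3, 3),
               (pgengam(1.2, 0.5, 0.5, 3 + h) -
                  pgengam(1.2, 0.5, 0.5, 3 - h)) / (2 * h), tolerance = 1e-6)
})

test_that("estimators are equivariant under time rescaling", {
  set.seed(19)
  x <- rgengam(80, 0.5, 0.5, 3)
  cc <- 10
  for (m in c("pml", "ml", "mps", "ad", "rad")) {
    f1 <- fit_gg(x, method = m, start = c(1, 1, 1),
                 control = light_control(seed = 20))
    f2 <- fit_gg(cc * x, method = m, start = c(1, 1 / cc, 1),
                 control = light_control(seed = 20))
    expect_false(f1$failed)
    expect_false(f2$failed)
    expect_equal(f2$params[["phi"]], f1$params[["phi"]], tolerance = 1e-6)
    expect_equal(f2$params[["alpha"]], f1$params[["alpha"]], tolerance = 1e-6)
    expect_equal(f2$params[["mu"]], f1$params[["mu"]] / cc, tolerance = 1e-6)
  }
})

test_that("non-failed fits satisfy their estimating equations to 1e-5", {
  set.seed(22)
  x <- rgengam(120, 0.5, 0.5, 3)
  for (m in c("pml", "ml", "mps", "ad", "rad")) {
    f <- fit_gg(x, method = m, start = runif(3, 0, 4),
                control = light_control(seed = 23))
    expect_false(f$failed)
    expect_lt(f$score_norm, 1e-5)
  }
})

test_that("degenerate inputs are flagged failed, not fatal", {
  f <- fit_gg(c(2, 2, 2, 2, 2), method = "pml")
  expect_true(f$failed)
  expect_match(f$failure_reason, "degenerate")
  f2 <- fit_gg(c(1, 2, 3), method = "ml")
  expect_true(f2$failed)
  expect_match(f2$failure_reason, "too small")
})

test_that("tidy and glance summarize fits in broom style", {
  d <- make_tbi_sample("D1", seed = 2)
  f <- fit_gg(d, method = "pml", seed = 3, control = light_control())
  td <- tidy(f)
  expect_identical(td$term, c("phi", "mu", "alpha"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(f)
  expect_identical(gl$method, "PML")
  expect_equal(gl$AIC, -2 * f$loglik + 6, tolerance = 1e-12)
  expect_s3_class(autoplot(f), "ggplot")
})
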