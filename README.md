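# ggfit

Small-sample inference for the three-parameter **Generalized Gamma (GG)
distribution**, aimed at positive duration data where only a handful of
observations exist — the motivating case being hospital length-of-stay
records of traumatic-brain-injury patients, with sample sizes under 20.

The GG density is

```
f(t | phi, mu, alpha) = alpha / Gamma(phi) * mu^(alpha*phi) *
                        t^(alpha*phi - 1) * exp(-(mu*t)^alpha),  t > 0,
```

with shapes `phi, alpha > 0` and rate-type scale `mu > 0`; it nests the
Weibull (`phi = 1`), Gamma (`alpha = 1`) and, on its boundary, the
lognormal. Flexibility is the attraction; the price is that classical
estimation is unstable at small `n`: the ML equations can have several
roots or none, and the shape estimates are strongly biased.

The package's core is a **penalized maximum likelihood (PML) estimator**
— the likelihood multiplied by a Jeffreys-prior penalty
`sqrt(phi^2 psi'(phi)^2 - psi'(phi) - 1) / (mu * alpha)`, where the
radicand is exactly `mu^2` times the determinant of the per-observation
Fisher information — maximized by a **simulated-annealing** optimizer in
log-parameter space, so results do not depend on starting values. Around
it:

* all eight classical estimation methods (`pml`, `ml`, `mm`, `ols`,
  `wls`, `mps`, `ad`, `rad`) behind one `fit_gg()` interface with a
  uniform, auditable failure taxonomy;
* Fisher-information (Wald) and nonparametric bootstrap (BCa/percentile)
  confidence intervals;
* four competitor three-parameter lifetime families (Generalized
  Weibull, Exponentiated Weibull, Marshall-Olkin Weibull, Extended
  Poisson-Weibull) with AIC/AICc/Kolmogorov-Smirnov model screening;
* mean residual lifetime prediction (`gg_mrl()`): expected further days
  in hospital given the days already spent;
* a Monte Carlo harness (`run_sim_study()`) comparing estimator bias,
  MSE and failure proportions under a common random-initialization
  protocol;
* synthetic stand-ins for the motivating data sets
  (`make_tbi_sample()`) and a small command line (`ggfit
  fit|compare|mrl|simulate|fixture`, installed under `inst/cli/`).

## Worked example

Fit a synthetic stand-in for the "total days in hospital" data set
(n = 19, whole days), get bootstrap intervals, predict remaining stay,
and screen competing families:

```r
library(ggfit)

d1 <- make_tbi_sample("D1", seed = 42)   # tibble with column `days`
d1$days
#>  [1] 36 24 48 44 22 21  1  1 45 21 23 19 22  4 33 12 15 10 35

fit <- fit_gg(d1, method = "pml", seed = 7)
fit
#> Generalized Gamma fit (PML)
#>   phi = 0.175, mu = 0.02108, alpha = 5.432
#>   n = 19, logLik = -74.9303, criterion = -73.2774, score = 2.49e-13

gg_bootstrap_ci(d1, B = 1000, seed = 8)
#> # A tibble: 3 × 5
#>   term  estimate conf.low conf.high type
#>   <chr>    <dbl>    <dbl>     <dbl> <chr>
#> 1 phi     0.175    0.0351    0.687  bca
#> 2 mu      0.0211   0.0188    0.0286 bca
#> 3 alpha   5.43     2.53     31.4    bca

gg_mrl_profile(fit, t_grid = c(0, 10))
#> # A tibble: 2 × 2
#>       t   mrl
#>   <dbl> <dbl>
#> 1     0  22.3
#> 2    10  17.9
```

Reading the output: the fitted mean stay is 22.3 days, and a patient who
has already spent 10 days in hospital is expected to stay a further 17.9
days — the mean residual lifetime `r(t)` is increasing at first for this
fit, a common pattern for heterogeneous stays. The tiny `score` value is
the largest estimating-equation residual, the package's convergence
certificate. With the published estimates for the real data set,
`gg_mrl(10, 0.410, 0.025, 3.040)` gives 17.3 — about seventeen more
days.

```r
compare_models(d1, seed = 9)
#>   family      AIC     AICc      KS_p  delta_w      support
#> 1     gg 155.8607 157.4607 0.8709366 0.000000    plausible
#> 2    mow 157.6869 159.2869 0.9526235 1.826211    plausible
#> 3    epw 158.6983 160.2983 0.8430414 2.837651 some support
```

The GG row uses the unpenalized log-likelihood at the PML estimates, so
AICs are comparable across families. Families whose likelihood runs into
a boundary on a given sample (here GW and EW on this day-rounded
fixture) are flagged as failed and dropped from the table rather than
reported at a spurious optimum.

The estimator-comparison harness reproduces the headline robustness
contrast in minutes:

```r
run_sim_study(c(0.5, 0.5, 3), n_grid = 20, n_rep = 2000,
              methods = c("pml", "mm"), seed = 1) |> tabulate_failures()
#> # A tibble: 1 × 3
#>       n    MM   PML
#> 1    20 0.875     0
```

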