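---
title: "Small-sample inference for the Generalized Gamma distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-sample inference for the Generalized Gamma distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggfit)
```

## The model

The Generalized Gamma (GG) distribution is a three-parameter family on the
positive half-line with density

$$f(t \mid \phi, \mu, \alpha) \;=\; \frac{\alpha}{\Gamma(\phi)}\,
\mu^{\alpha\phi}\, t^{\alpha\phi-1}\, e^{-(\mu t)^\alpha}, \qquad t > 0,$$

where $\phi > 0$ and $\alpha > 0$ are shape parameters and $\mu > 0$ is a
rate-type scale (units 1/time).  If $W \sim \mathrm{Gamma}(\phi, 1)$ then
$T = W^{1/\alpha}/\mu$ follows this law, which is how `rgengam()` samples
and why the cdf is the regularized incomplete gamma function
$P(\phi, (\mu t)^\alpha)$.  The family nests the Weibull ($\phi = 1$), the
Gamma ($\alpha = 1$), and — as limits on the parameter boundary — the
lognormal ($\alpha \to 0$ with $\phi \to \infty$ suitably) and other
classical lifetime models.  Its hazard can be constant, increasing,
decreasing, bathtub or unimodal, which is what makes it attractive for
heterogeneous duration data such as hospital length of stay.

All density, likelihood and cdf evaluations are carried out on the log
scale: the likelihood of even 50 observations overflows double precision
in the raw parameterization for moderately large $\alpha\phi$.

## Why estimation is hard at small $n$

Maximum likelihood for the GG family is notoriously fragile: the score
equations can have several roots or none, and for a substantial fraction of
very small samples the profile likelihood increases monotonically toward a
parameter boundary, so an interior MLE simply does not exist.  On top of
that, $\hat\phi$ and $\hat\alpha$ are strongly biased when $n$ is a few
tens.  This package combines two remedies:

1. **A Jeffreys-prior penalty.**  The determinant of the per-observation
   Fisher information is
   $\det I_1 = (\phi^2\psi'(\phi)^2 - \psi'(\phi) - 1)/\mu^2$, where
   $\psi'$ is the trigamma function (we verified this symbolically; the
   radicand is strictly positive on $\phi > 0$, decaying like
   $1/(12\phi^2)$).  The penalty multiplies the likelihood by
   $\sqrt{\phi^2\psi'(\phi)^2 - \psi'(\phi) - 1}\,/(\mu\alpha)$ — the
   Jeffreys prior times an extra $1/\alpha$ that matches the Weibull
   Jeffreys prior in the $\phi = 1$ submodel and shrinks the bias of
   $\hat\alpha$.  The penalized log-likelihood differs from the plain one
   by $O(1)$, so penalized ML (PML) and ML are asymptotically equivalent,
   but at $n = 20$ the penalty both regularizes the boundary (the
   penalized problem essentially always has an interior solution) and
   reduces bias visibly.
2. **Simulated annealing (SANN).**  All annealed fits run in
   log-parameter space, where positivity constraints vanish and the
   uniform step proposal is scale-appropriate.  The annealer accepts
   uphill moves with probability $e^{-\Delta g/k}$, retargets its step
   vector to a 50% acceptance rate every `s` iterations, and cools
   $k \leftarrow r_k k$ (default $r_k = 0.95$) every `m` iterations.  The
   returned point is the best ever visited.  A deterministic polish
   (Nelder–Mead, then damped Newton on the estimating equations with a
   numeric Jacobian) follows by default, because the acceptance checks on
   the score equations demand more precision than annealing alone
   delivers; `polish = FALSE` disables it.

For the PML fit the scale-stationarity equation is solved for $\phi$ in
closed form, $\hat\phi = (\alpha\mu^\alpha\sum t_i^\alpha + 1)/(n\alpha)$,
and substituting it back makes the $\mu$-score vanish identically — the
stationary points of the reduced two-dimensional problem in $(\mu,\alpha)$
are exactly the joint stationary points, so the annealer works on a 2-D
surface.  For ML the problem profiles all the way down to one dimension in
$\alpha$.  We evaluate that profile in a centered, cancellation-safe form
($c_i = \log t_i - \overline{\log t}$, $w_i = e^{\alpha c_i}$,
$\hat\phi(\alpha) = \sum w_i / (\alpha \sum w_i c_i)$, with `expm1`
branches as $\alpha \to 0$ and a Stirling branch for
$\phi\log\phi - \phi - \log\Gamma(\phi)$): the naive evaluation loses all
precision near the lognormal boundary and invents spurious maxima there.
The one-dimensional estimating equation we actually solve,
$h(\alpha) = \psi(\hat\phi) - \log\hat\phi + \log\bigl(\tfrac1n\sum
e^{\alpha c_i}\bigr) = 0$, was re-derived symbolically from the
log-likelihood and verified against finite differences.

## The eight estimators and the failure taxonomy

`fit_gg()` implements, besides `"pml"` (default) and `"ml"`: the method of
moments (`"mm"`, matching the mean and a finite-sample-corrected squared
coefficient of variation, with $\hat\phi = \tfrac1n\sum(\hat\mu
t_i)^{\hat\alpha}$ substituted, solved by Broyden's quasi-Newton method),
ordinary and weighted least squares on the cdf at the plotting positions
$i/(n+1)$ (`"ols"`, `"wls"`, BFGS), maximum product of spacings (`"mps"`,
with tied observations' zero spacings replaced by the density at the tie),
and the Anderson–Darling and right-tail Anderson–Darling minimum-distance
estimators (`"ad"`, `"rad"`).

MM, OLS and WLS deliberately use a standard local solver from the random
start and get no annealing rescue: their fragility under random
initialization is a real, reportable phenomenon (the simulation harness
reproduces it), and a global optimizer would erase it.

A fit is flagged `failed` iff any of: (a) the solver errors or returns
non-finite values; (b) an estimate escapes $[10^{-6}, 10^6]$; (c) the
method's estimating equations are not satisfied to $10^{-5}$ after
polishing; (d) the criterion value is not finite at the solution; or
(e) the fitted cdf is numerically 0 or 1 across the entire sample.  Clause
(e) deserves a note: BFGS on the least-squares criterion frequently
converges to the saturation plateau where every $F(t_i) = 1$; the gradient
there vanishes identically, so clause (c) alone would wrongly count it a
success even though the criterion sits at its plateau constant, far above
the true minimum.  All annealed objectives also impose a barrier outside
$|\log\theta_j| \le 30$, far beyond the admissible box, which keeps the
search away from denormal values where R's `trigamma` returns NaN.

Samples with $n < 4$ (three parameters plus one residual degree of
freedom) or with all values tied are flagged without fitting.  Ties are
detected by exact floating equality — appropriate for data recorded on a
whole-day grid, where ties are genuine.

## Uncertainty

`gg_fisher_info()` returns the expected information; `confint()` builds
Wald intervals from its inverse and warns below $n = 400$, where the
normal approximation for $\phi$ is known to be unreliable.  The penalized
variant adds the exact curvature of the penalty (polygamma functions up to
order three in the $(\phi,\phi)$ entry, $-1/\mu^2$ and $-1/\alpha^2$ on
the other diagonal entries) — we verified it against the numeric Hessian
of the penalized log-likelihood rather than trusting any printed display,
since the penalty curvature is deterministic.

For the small samples this package targets, `gg_bootstrap_ci()` is the
recommended interval: nonparametric resampling, refit per replicate,
BCa intervals with an automatic fallback to the percentile interval when
the acceleration estimate is degenerate.  Replicates whose refit fails are
dropped and counted, and more than 50% failures is an error naming the
estimator — with the PML default this essentially never triggers, which
is precisely what makes the bootstrap workable here.  Refits warm-start at
the full-data estimates (Newton on the score equations, annealing only as
fallback); this is the standard efficiency device and changes nothing
statistically, but makes $B = 1000$ replicates take seconds.

A measured caveat: in a 200-repetition check at the package's target
conditions ($n = 19$ draws from the fitted stay distribution, $B = 200$),
the BCa intervals covered the generating $(\phi, \mu, \alpha)$ in about
(95%, 84%, 96%) of repetitions while the percentile intervals covered
(94%, 91%, 93%) — the jackknife-based acceleration estimate is unstable
at these sizes and costs the scale parameter a few points.  BCa remains
the default for its better shape-parameter endpoints, but
`type = "percentile"` is the conservative choice when the scale is the
quantity of interest.

## Model screening

`compare_models()` fits the GG alongside four other three-parameter
lifetime families — Generalized Weibull, Exponentiated Weibull (EW),
Marshall–Olkin Weibull, Extended Poisson–Weibull — by maximum likelihood
(no penalty is derived for the competitors), and ranks everything by AIC
and AICc, with the Kolmogorov–Smirnov statistic and its asymptotic
p-value as an absolute-fit check.  Two deliberate choices:

* The GG row's information criteria use the **unpenalized** log-likelihood
  evaluated at the PML estimates; a penalized value would not be
  comparable across families.
* The KS p-value ignores the fact that parameters were estimated, exactly
  as in routine applied practice; this is conservative (p too large), and
  a parametric-bootstrap p-value is available behind the `bootstrap`
  argument of `gg_ks_test()`.

A caution discovered while validating the ranking: the EW family can
reproduce some GG members almost exactly (for GG(0.5, 0.5, 3) the
population Kullback–Leibler gap to the best EW is about $10^{-5}$ nats),
so AIC cannot meaningfully separate the two at realistic $n$ and
"the true family wins" should not be expected replicate by replicate; the
$\Delta_w < 2$ plausibility band is the right reading.

## Mean residual lifetime

`gg_mrl()` answers the applied question — given a patient has already
stayed $t$ days, how much longer do we expect? — via
$r(t) = \Gamma(\phi + 1/\alpha, (\mu t)^\alpha) / (\mu\,\Gamma(\phi, (\mu
t)^\alpha)) - t$ with unregularized upper incomplete gamma functions,
evaluated from log-gamma and log-survival differences so the ratio
survives far into the tail.  At $t = 0$ it reduces to the mean.

## The simulation harness and the synthetic fixtures

`run_sim_study()` reproduces the estimator-comparison protocol: samples
from GG($\theta$), every method started from fresh $U(0,4)$ draws per
coordinate, failures tabulated, bias/MSE computed over the successful
replicates (the success and failure counts are both reported — failed
replicates produce no estimate, so success-conditional summaries are the
only well-defined ones).  Per-replicate seeds derive deterministically
from the master seed, so any single cell can be reproduced in isolation.
Methods share the generated sample within a replicate by default (paired
comparison); `paired = FALSE` draws per method.

Problem sizes are chosen for a desk-scale run: the bundled acceptance
script and tests use $N = 2000$ replicates per cell (at $n \in \{20, 50,
100\}$ this takes a few minutes per cell on one core), and
`run_sim_study()` defaults to a lighter annealing schedule
(`max_iter = 4000`, `m = 50`) than one-off fits (`max_iter = 20000`,
`m = 100`), sized for thousands of replicates; the terminal Newton polish
does the final refinement either way, so the failure conclusions are
unchanged.  For a publication-scale run, pass `n_rep = 20000` and the
full-size schedule.

`make_tbi_sample()` generates stand-ins for the three motivating hospital
data sets (total stay, neurology-department stay, mechanical-ventilation
time for male traumatic-brain-injury patients): GG draws at the published
PML estimates, rounded *up* to whole days, with the published sample sizes
(19, 19, 16).  The ceiling matches data whose minima are 4, 2 and 1 whole
days and guarantees positive integers; it also produces genuine ties,
which exercise the spacings tie-substitution branch.  What the fixtures do
**not** emulate: any censoring (the motivating data are uncensored
discharges only), covariates, or the discreteness bias a one-day grid
induces on sub-day stays.  Tests passing on these fixtures therefore
validate the estimation machinery, not the clinical conclusions — the
published point estimates can only be reproduced from the original
spreadsheet, which `convert_stay_xls()` will convert for users who have
it.

## Numerical choices, in one place

* Quantiles by the exact transform `qgamma(p, phi)^(1/alpha)/mu`; random
  generation by the same gamma-power transform, never cdf inversion.
* Penalty radicand: exact identity
  $(1 + \phi^2\psi'(1+\phi))\psi'(1+\phi) - 1$ below $\phi = 0.5$ (stable
  as $\phi \to 0$), direct formula above, $1/(12\phi^2)$ fallback where
  the direct form cancels below machine precision.
* $\partial F/\partial\phi$ (needed by the least-squares, spacings and
  Anderson–Darling estimating equations) by Richardson-extrapolated
  central differences of `pgamma` in its order; the $\mu$- and
  $\alpha$-derivatives use their closed forms.
* Newton polish: damped (step clipped to 1 in log space), numeric
  Jacobian, keeps the best-residual iterate; tolerance $10^{-11}$ on the
  score residuals for fits, $10^{-8}$ for bootstrap warm starts.
* Tie handling, degenerate samples, and the $n < 4$ floor as described
  above; annealing stopping temperature `k_min` is exposed in
  `sann_control()` because no canonical value exists.

## Known limitations

* No censoring support — the likelihoods are for fully observed
  durations.
* The Wald intervals are supplied for completeness; at the target sample
  sizes ($n \approx 20$) they should not be trusted, and the package says
  so with a warning.
* The asymptotic KS p-value is conservative for fitted models (see
  above).
* ML failure rates at very small $n$ depend on the failure definition:
  this package counts a boundary (nonexistent) MLE as a failure, which is
  stricter than counting only optimizer crashes; roughly a third of
  $n = 20$ samples from GG(0.5, 0.5, 3) have no interior MLE at all.
  The penalized estimator is the recommended default precisely because it
  does not suffer this.
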