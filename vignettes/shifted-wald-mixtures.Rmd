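---
title: "Shifted-Wald models with across-trial drift variability: methods and design"
author: "waldmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shifted-Wald models with across-trial drift variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waldmix)
```

## The model

One-choice reaction-time (RT) tasks — simple detection, go/no-go,
psychomotor vigilance — produce a single latency per trial.  The standard
process account is a Wiener diffusion toward one absorbing boundary:
evidence accumulates at drift rate $\xi$ until it reaches a threshold
$\alpha$, and a nondecision time $\theta$ (encoding and motor execution) is
added.  The decision time is then Wald (inverse Gaussian) distributed, and
the observed RT follows the shifted-Wald (SW) density

$$\mathrm{SW}(t;\alpha,\theta,\xi) =
  \frac{\alpha}{\sqrt{2\pi (t-\theta)^3}}
  \exp\!\left(-\frac{[\alpha-\xi(t-\theta)]^2}{2(t-\theta)}\right),
  \qquad t > \theta,$$

implemented by `dsw()`/`psw()`/`rsw()`.  All times are in seconds
internally; `read_rt_table(unit = "ms")` converts millisecond input at the
I/O boundary.  The prior location for $\theta$ (0.180) and typical
estimates (≈ 0.13) only make sense on the seconds scale, which is why the
unit is fixed internally rather than configurable.

Attention, motivation, and fatigue fluctuate over an experimental session,
so a constant drift rate is psychologically implausible.  The package
models across-trial drift variability by treating the trial-level drift as
a draw from a positive-valued mixing law $h(\xi)$ and marginalizing:

$$f(t;\alpha,\theta,\gamma) = \int_0^\infty
  \mathrm{SW}(t;\alpha,\theta,\xi)\, h(\xi;\gamma)\, d\xi.$$

Two mixing laws are supported:

* **Zero-truncated normal** (`"tn"`), location $\mu_\xi$, scale
  $\sigma_\xi$, truncated to $[0,\infty)$.  The marginal has a closed form
  (with $s = t-\theta$, $v = s\sigma_\xi^2+1$):
  $$f(t) = \frac{\alpha}{\sqrt{2\pi s^3 v}}
    \frac{1}{\Phi(\mu_\xi/\sigma_\xi)}
    \exp\!\left(-\frac{(\mu_\xi s-\alpha)^2}{2sv}\right)
    \Phi\!\left(\frac{\alpha\sigma_\xi^2+\mu_\xi}
                {\sqrt{\sigma_\xi^2 v}}\right),$$
  implemented in log space by `dswtn()`.
* **Gamma** (`"gam"`), shape $\kappa$ and rate $\tau$, reparameterized to
  mean $\mu_\xi = \kappa/\tau$ and variance $\sigma_\xi^2 = \kappa/\tau^2$
  (`gamma_from_moments()`/`gamma_to_moments()`) so that results are
  directly comparable with the truncated-normal fit.  A closed form for
  this marginal exists but involves Laguerre polynomials and is unwieldy;
  `dswgam()` instead evaluates the defining integral by adaptive
  quadrature, which keeps the density deterministic, testable, and
  accurate to ~1e-8 relative.

Both mixtures collapse to the plain SW density as the drift variance goes
to zero.  That limit is numerically treacherous (catastrophic cancellation
between the $\Phi$ factors), so a degeneracy threshold routes evaluation to
the fixed-drift branch below $\sigma_\xi < 10^{-6}$ (TN) or
$\sigma^2_\xi < 10^{-12}$ (gamma); continuity across the threshold is part
of the test suite.

## Numerical choices

**Log-CDF primitives.**  Every $\Phi$ or $\log\Phi$ is computed with
`pnorm(log.p = TRUE)` (an erfc-based log-CDF), never as the log of a
possibly-underflowed CDF.  `dswtn()` therefore remains finite for
$t-\theta$ from $10^{-6}$ to $10^3$ s and for truncated-normal locations
far below zero.

**Three independent routes to the gamma marginal.**  (1) `dswgam()` uses
`stats::integrate()` on the drift scaled by its mean, after factoring out
the maximum of the log integrand (located analytically from the quadratic
stationarity condition), with relative tolerance $10^{-10}$ over an
interval covering both the gamma's $10^{-14}$ quantile range and the
Laplace peak region; non-convergence is an error naming the parameter
point.  (2) The MCMC likelihood (C++) uses a fixed composite 15-point
Gauss–Legendre rule in log-drift space, centred on the same Laplace point
with graded filler panels toward the gamma quantile bounds — deterministic
and an order of magnitude faster, and validated against (1) to $10^{-8}$
in the tests.  (3) The test oracle `sw_mix_quadrature()` takes an
*arbitrary* mixing density, locates the integrand peak by a zoomed grid
scan, and applies a graded 20-point Gauss–Legendre panel rule with a
compactified right tail.  Scheme (3) shares no code or nodes with (1) or
(2), so agreement between them is evidence of correctness rather than of
consistency.  The oracle accepts optional support bounds because no
black-box scan can find a mixing spike narrower than grid resolution (the
near-point-mass checks supply them).

**Exact samplers.**  `rwald()` uses the Michael–Schucany–Haas transform
(one $\chi^2_1$ and one uniform per draw); `rtnorm0()` uses rejection from
the untruncated normal while the kept mass exceeds 5% and otherwise a
tail-safe inverse-CDF in the survival domain.  `simulate_participant()`
draws one drift per trial and then one SW time — the sampling-based
definition of the mixtures — redrawing the measure-zero event $\xi_i = 0$
because the Wald sampler rejects it.  Per-participant seeds are spawned
from a master seed through a minimal-standard Lehmer generator (multiplier
16807, modulus $2^{31}-1$; all arithmetic exact in doubles), so a dataset
is citable by `(master_seed, i)`.

## Bayesian estimation

`swfit()` estimates $(\alpha, \theta, \mu_\xi, \sigma^2_\xi)$ per
participant.  The priors (`default_priors()`) are weakly informative on
the seconds scale of one-choice tasks:
$\alpha \sim N^+(2, \sqrt{5/2})$, $\theta \sim N^+(0.180, 1/2)$,
$\mu_\xi \sim N^+(8, \sqrt{10})$, $\sigma^2_\xi \sim U(0,5)$, with the
second truncated-normal hyperparameter read as a standard deviation.

Sampling is random-walk Metropolis on transformed coordinates
($\log\alpha$, $\log\theta$, $\log\mu_\xi$, and a logit map of
$\sigma^2_\xi$ onto the support of its uniform prior) with Jacobian
corrections.  Three design points deserve justification:

* **Joint, not componentwise, proposals.**  The posterior has strong
  threshold–shift and threshold–drift-mean correlations (a higher boundary
  can be traded against a shorter nondecision time or a faster drift).
  Componentwise updates mix too slowly along these ridges to reach the
  convergence criterion within a sensible draw budget, so the proposal is
  multivariate normal with a Haario-style adapted covariance: during
  burn-in the empirical covariance of the second half of the burn-in
  history is refreshed every 25 iterations and a global scale is tuned by
  Robbins–Monro toward ~30% acceptance (within the 20–50% band that
  random-walk theory recommends).  Adaptation is frozen at the end of
  burn-in, so retained draws come from a fixed, valid kernel.
* **Laplace initialization.**  Before sampling, the posterior mode in
  z-space is located by Nelder–Mead from the best of 25 prior draws and
  the numerical Hessian supplies the initial proposal covariance.  Chains
  start from overdispersed draws around that mode (jitter twice the
  Laplace scale).  Raw prior-draw starts are supported as a fallback, but
  a random walk started several dozen posterior standard deviations from
  the mode cannot traverse that distance within a 1000-draw burn-in, which
  in practice turned prior starts into spurious convergence failures.
  Overdispersed-around-the-mode starts keep the Gelman–Rubin diagnostic
  meaningful while letting the protocol's burn-in suffice.
* **Convergence protocol.**  Convergence is declared when the classical
  (non-split) Gelman–Rubin $\hat R$ of every parameter is below 1.05 —
  deliberately stricter than the 1.1 rule of thumb.  While any $\hat R$ is
  at or above threshold the chains are *extended* by 1000 retained draws
  (a continuation with the frozen kernel, not a restart; "refitting with
  more samples" is ambiguous and continuation wastes nothing), up to a cap
  of 10 extensions, after which `swfit()` raises an error carrying the
  convergence report.  The cap makes non-convergence diagnosable instead
  of looping forever.

Point summaries are posterior *modes* — a Gaussian KDE with Silverman's
bandwidth evaluated on a 512-point grid spanning the pooled draws —
because the marginal posteriors (especially of $\sigma^2_\xi$) are skewed
enough that means would be misleading.  Uncertainty is summarized by the
25th–75th percentile interval under the linear-interpolation (type 7)
quantile convention.  With strong skew the mode can legitimately fall
outside the interquartile range.

The restricted model (`fix_sigma2 = TRUE`) clamps the drift variance to
zero, i.e. fits the vanilla constant-drift SW; its parameter vector omits
`sigma2_xi` entirely and supplying one is an error, not a silent drop.

## Recovery studies

`run_recovery()` wires the loop: simulate participants from a generating
table, fit each with the matched family under the recovery protocol (3
chains, 2000 retained draws after 1000 burn-in, extensions to
$\hat R < 1.05$), and tabulate generating values against posterior modes
and IQRs.  `summarize_recovery()` reports per-parameter correlations, mean
signed errors, and mean IQR widths, plus the free-versus-restricted
drift-mean comparison when both fits of the same dataset are supplied.
Participants that hit the extension cap are excluded with a warning and
flagged in the table — a crash would discard the other 29 fits.

The shipped generating table (`default_recovery_params()`) has 30 rows
spanning $\alpha \in [0.6, 1.8]$, $\theta \in [0.08, 0.20]$ s,
$\mu_\xi \in [5, 15]$, $\sigma^2_\xi \in [0.2, 3]$ — ranges centred on
what large simple-RT samples typically yield (threshold near 1, shift near
0.13 s, drift mean near 10), with the columns scrambled against each other
so no two parameters are collinear across participants.  The table is a
frozen fixture: regenerating it is not part of any analysis.
`representative_params()` implements the companion selection rule for real
data — participants nearest the $k/(n+1)$ quantiles of the mean-RT
distribution, each selectable once, ties to the lowest index.

The package's own validation runs use 10 participants per family at 1200
trials (and the acceptance script scales similarly); at this size a full
free-plus-restricted run of both families completes in a few minutes on
one core.  The qualitative conclusions: the drift variance does not
recover reliably, clamping it to zero biases the drift mean downward for
essentially every participant, and threshold/shift/drift-mean recovery is
good over most of the table — with one instructive exception.  For the
gamma family the three correlations exceed 0.9; for the truncated-normal
family, table rows that combine a low drift mean with a high drift
variance (μ_ξ ≈ 5–7.5 with σ²_ξ ≈ 1.7–2) produce posteriors shaped like a
long ridge trading threshold against drift variance.  The joint posterior
mode stays near the generating values, but the *marginal* modes — the
summary used throughout — are pulled along the ridge by volume and by the
σ²_ξ prior boundary, landing at thresholds 30–70% above the generating
ones and dragging the 10-participant correlations to ≈ 0.83.  This is a
property of the posterior, not of the sampler: a 15-fold longer run and a
fully independent natural-scale Metropolis sampler started at the
generating values reproduce the same marginals.  Studies that pick
generating values as posterior modes of real-data fits sit, by
construction, near fixed points of the mode map and largely avoid this
corner of the parameter space; a uniformly scrambled table does not.
What a passing run does *not* show: real RT data contain contaminant
responses, sequential dependencies, and parameter drift that the
generator deliberately omits; recovery on clean synthetic data is a
necessary, not sufficient, validation.

## Goodness of fit

`gof_report()` compares, per participant, the observed RT quantiles at
levels .1/.3/.5/.7/.9 with quantiles of `n_pred = 120` RTs simulated at
the posterior modes, and correlates observed against predicted across
participants at each level.  A single 120-draw predictive sample carries
deliberate sampling noise — it mirrors the information in one observed
session; `reps > 1` averages replicates for smoother predictions.
`filter_rts()` applies the standard 110–1000 ms exclusion screen with
strict inequalities (boundary values are retained) before fitting real
data; it is idempotent and errors on a participant with no surviving
trials.

## Known limitations

* The gamma-marginal quadrature targets the parameter ranges reachable
  under the default priors; shapes $\kappa < 10^{-2}$ are untested.
* The Lévy case $\xi = 0$ is supported by the densities but not the
  sampler (infinite mean first-passage time).
* No hierarchical pooling across participants, no contaminant-mixture
  likelihood, and no Bayes-factor machinery; fits are per participant.
* The oracle quadrature assumes a light-tailed, unimodal (log-concave)
  mixing density, which both supported families satisfy.

## A worked example

```{r example, eval = FALSE}
p <- simulate_participant(drift_mixture("tn", mu = 10, sigma2 = 1),
                          alpha = 1, theta = 0.13, n_trials = 1200,
                          seed = 42)
fit <- swfit(p$rts, family = "tn", chains = 3, draws = 2000,
             burn_in = 1000, seed = 7)
summary(fit)
gof_report(list(p1 = p$rts), list(fit), seed = 1)
```
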