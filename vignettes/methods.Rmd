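---
title: "Simulation methods for longitudinal FA power analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation methods for longitudinal FA power analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtipower)
```

`dtipower` estimates the statistical power of two-group longitudinal studies
of corticospinal-tract fractional anisotropy (FA) in amyotrophic lateral
sclerosis by Monte Carlo simulation. This vignette is the package's account
of the underlying model, the choices that were genuinely open when it was
built, and what its validation does and does not establish.

## The trajectory and measurement model

A subject's true FA follows a line in time,
$$FA_{t,i} = FA_{0,i} + \beta_i\, t,$$
and every acquired scan measures it with independent Gaussian error,
$$\widehat{FA}_{t,i} = FA_{t,i} + \varepsilon, \qquad
  \varepsilon \sim \mathcal{N}(0, SEM).$$

Across subjects, both the intercept and the slope are Gaussian random
effects:

* true baseline $FA_{0,i} \sim \mathcal{N}(\mu_g, \sigma_g)$ with
  group-specific parameters — defaults 0.326 ± 0.018 for the patient group
  and 0.339 ± 0.023 for controls, tract-averaged corticospinal-tract values
  from sizeable ALS and control cohorts;
* patient slope $\beta_i \sim \mathcal{N}(\mu_\beta, \sigma_\beta)$, with
  $\mu_\beta = -(\text{rate}/100)\cdot 0.326$ FA/year and
  $\sigma_\beta = 0.67\,|\mu_\beta|$ (a 67% between-subject coefficient of
  variation of the decline rate);
* control slope exactly zero — healthy controls are modelled without any
  longitudinal FA change, including zero slope variance.

Three decline regimes are studied: 0.5 (slow), 2.0 (intermediate) and 3.5
(fast) percent of the patient baseline mean per year.

Two modelling points deserve emphasis because the alternatives are equally
defensible:

**Anchoring of the percentage decline.** The annual percentage is converted
to FA units per year against the *group mean* baseline (0.326), not each
subject's own baseline. A single group-level normal law for $\beta_i$ is
only well defined with a group-level anchor; subject-anchoring would make
the slope distribution a scale mixture. The subject-anchored variant is
available (`decrease_model(..., anchor = "subject")`); at the default
parameter scales the two differ by under 6% in slope dispersion and the
power difference is within Monte Carlo noise.

**True versus measured baseline.** The group baseline dispersion
(0.018–0.023) is treated as the spread of *true* baselines, and per-scan
error is added on top. Since the per-scan SEM (≤ 0.00134) is more than an
order of magnitude smaller than the group SD, the distinction between "the
quoted SD describes true values" and "it describes measured values" changes
group variances by under 1% and is immaterial in practice — but the
simulation needs a true-value decomposition, so one reading had to be
chosen.

Other fixed conventions: one year is 365 days; decline is encoded as a
negative slope (the test is two-sided, so the sign convention is
immaterial); simulated FA values are not clipped to $[0,1]$, because at
these parameter scales excursions outside the physical range have
negligible probability and clipping would bias the Gaussian model.

## Measurement uncertainty from test-retest reliability

The SEM parameter is estimated from complete test-retest tables (subjects ×
repeated measurements). `compute_icc()` implements the single-rater,
absolute-agreement intraclass correlation from the two-way mixed-effects
model — ICC(A,1) in the McGraw–Wong taxonomy — computed from the two-way
ANOVA mean squares, with the standard F-approximation confidence interval.
Absolute agreement is the right flavour here: a systematic shift between
scanning sessions is a real measurement problem and should count against
reliability.

The SEM conversion is
$$SEM = \sqrt{\frac{TSS}{k-1}\cdot ICC \cdot (1 - ICC)},$$
with $TSS$ the total within-subject sum of squares and $k$ the number of
measurements. The defining expression can be read with the radical covering
the whole product or only its first factor; the package defaults to the
full-radical reading because it is the one with consistent units (FA, not
FA²), and exposes the no-radical product as `variant = "literal"` for
comparability. Note a structural quirk inherited from the formula: it
vanishes at $ICC = 0$ as well as at $ICC = 1$, although zero reliability is
hardly zero error; the formula should only be trusted in the
moderate-to-excellent reliability range where it is used.

Reliability bands (poor < 0.50 ≤ moderate < 0.75 ≤ good < 0.90 ≤ excellent)
are applied to the point estimate *and* to both CI bounds, and all three
are reported: conventional published ranges overlap at their endpoints, so
the package fixes half-open intervals with boundaries assigned to the
higher band, and leaves it to the user whether to band the estimate or the
interval. Negative ICC estimates are returned unclamped and banded "poor".

The packaged defaults use two SEM levels, 0.00054 ("low", from a
62-gradient-direction protocol with ICC 0.97) and 0.00134 ("high", from a
52-direction protocol with ICC 0.91). These are carried as *inputs*: the raw
14-subject test-retest data behind them is not distributed, so the package
cannot (and does not) re-derive them. `generate_retest_fixture()` provides
synthetic test-retest tables with known variance components; the fixture's
population reliability is $\sigma_b^2/(\sigma_b^2+\sigma_e^2)$, which the
test suite uses for parameter-recovery checks.

## The power algorithm

For a scenario $(n, t, m, SEM, \text{rate})$ each Monte Carlo iteration:

1. draws $n$ patients (baseline + slope) and $n$ controls (baseline, slope
   0);
2. simulates $m$ scans per subject at the baseline session and $m$ scans at
   the follow-up session $t$ days later, each with fresh
   $\mathcal{N}(0, SEM)$ error;
3. forms each subject's change score — follow-up session mean minus
   baseline session mean;
4. compares groups with a two-sided pooled-variance t-test;
5. counts the iteration significant if $p < \alpha$ (strict inequality;
   immaterial for a continuous statistic).

Power is the significant fraction over 2000 iterations (the default; the
binomial standard error near power 0.8 is then ≈ 0.009).

*Why the change score:* with exactly two sessions, a per-subject fitted
slope is an affine rescaling of the change score, so both produce the
identical t-test; the change score is the simpler statistic.

*Why the pooled test:* group sizes are equal by design, for which the
pooled and Welch statistics coincide numerically and only the reference df
differ slightly. The group variances do genuinely differ — patients carry
slope variability, $\sigma_\beta^2 (t/365)^2$, that controls lack — so
Welch's test is available (`welch = TRUE`), but the pooled test is the
conventional default for designed equal-n comparisons.

**Seeding.** Every iteration runs on its own RNG substream whose seed is a
fixed integer recurrence of the scenario's master seed and the iteration
index. Results are therefore bit-reproducible from (parameters, seed) and
invariant to how iterations might be scheduled or parallelised. Helper
functions save and restore the caller's RNG state, so package calls never
perturb a user's own stream.

## The analytic cross-check

The change scores are exactly normal within each group:
patients $\sim \mathcal{N}(\mu_\beta t/365,\;
\sigma_\beta^2 (t/365)^2 + 2\,SEM^2/m)$, controls
$\sim \mathcal{N}(0,\; 2\,SEM^2/m)$. `analytic_power_oracle()` computes the
two-sided pooled-t power from the noncentral t distribution with
noncentrality $\delta/\sqrt{(v_{pat}+v_{ctl})/n}$ and $2n-2$ df. This is an
*independent* closed-form route to the same quantity the simulation
estimates, and the test suite requires agreement across a 24-scenario grid.
The oracle is exact under equal group variances and approximate otherwise;
its residual approximation error (worth roughly ±0.007 on the power scale
at the default parameters, largest in the mid-power range where the
variance imbalance matters most) is combined in quadrature with the
binomial Monte Carlo error when the two routes are compared.

## Sample-size search and the scan trade-off

`min_sample_size()` evaluates power on the full integer grid
$n = n_{min}..n_{max}$ (default 3–100, step 1, covering every sample size of
practical interest) using common random numbers: each iteration draws one
cohort of $n_{max}$ subjects per group and evaluates every smaller design
on its leading subset, via prefix sums of the change scores. Prefix
subsetting gives *exact* common random numbers across $n$ — and, as a
side-effect, makes the whole search cost one simulation pass instead of
one per candidate $n$. Because the per-n estimates still carry binomial
noise (~0.009 SE at 2000 iterations), the raw curve may jitter
non-monotonically near the threshold; it is smoothed by isotonic regression
(`stats::isoreg`) before thresholding. If no candidate reaches the target
the result is an explicit "not reached" sentinel, never a clamp to the
bound.

`sample_size_reduction()` reports
$100\,(n_{min}(m_{from}) - n_{min}(m_{to}))/n_{min}(m_{from})$ percent, the
headline quantity for the repeated-scans-versus-subjects trade-off. With
$SEM = 0$ scans are interchangeable and the reduction is identically zero;
the package verifies this limit exactly, since with no measurement error
the change scores are independent of $m$ draw-for-draw.

## What the synthetic-data generator does and does not emulate

The generator reproduces the stated study conditions: Gaussian baselines
and slopes with the default parameters above, Gaussian iid per-scan error,
a complete two-session design, and no dropout. Real longitudinal DTI data
depart from this in known ways — error variance may be higher in patients
than in the healthy subjects whose scans calibrated the SEM, may grow with
disease severity over the follow-up interval, and trajectories need not be
linear over longer windows; scanner or site effects add shared (not iid)
error components. Passing tests therefore demonstrate that the power
machinery is correct *for the stated model*, not that the model captures
every property of clinical data; the design conclusions inherit the model's
assumptions, and the package deliberately keeps all of them visible as
parameters.

## Numerical and degenerate-input conventions

* ICC: all-identical matrices are rejected as degenerate (zero total
  variance); a matrix with zero *within*-subject variance returns
  ICC exactly 1 with a collapsed CI.
* t-test: both groups constant is rejected as degenerate rather than
  returning NaN.
* A scenario with rate 0 *and* SEM 0 is fully deterministic and propagates
  the degenerate-variance error — there is nothing to test.
* Follow-up intervals outside 30–180 days are allowed but warned about,
  since the defaults were characterised in that range.
* Config validation rejects unknown keys and names the offending key; CLI
  flags override file values, which override packaged defaults.
* CSV outputs are written with 15 significant digits and no timestamps, so
  identical runs produce byte-identical files (manifests, which carry a
  timestamp by design, live in separate files).

## Problem sizes used in validation

The shipped test suite runs the five headline design checks at the full
2000-iteration resolution (including the complete n = 3..100 double search
behind the scan-trade-off figure, which the prefix-sum engine makes cheap),
the oracle-agreement grid at 24 scenarios × 2000 iterations, and the
distributional identities (moment recovery, variance decomposition) at
$3\times10^4$–$10^5$ draws — sizes chosen so the whole suite documents the
method at its native resolution while remaining quick to run routinely.

## Known limitations

Single follow-up session only (no multi-visit schedules or visit-weighting);
no dropout or missing-scan modelling; no within-subject mixed models —
the two-session change-score design makes them equivalent here, but they
would matter for richer schedules; no cost model trading scanner time
against recruitment; reliability analysis is restricted to complete
balanced designs and the single-rater absolute-agreement ICC.
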