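# dtipower

Monte Carlo power analysis and study-design optimisation for two-group
longitudinal studies of a scalar imaging biomarker — built for fractional
anisotropy (FA) of the corticospinal tract in amyotrophic lateral sclerosis
(ALS), and applicable to any biomarker whose trajectories are approximately
linear over the study window.

Longitudinal DTI studies in ALS must balance three design levers: the
per-group sample size *n*, the interval *t* between baseline and follow-up,
and the number of repeated scans *m* acquired at each session. Repeated
scans average down the per-scan measurement error and can substitute for
subjects — a crucial trade-off when the patients are hard to recruit and
scanning is a burden. `dtipower` quantifies that trade-off by simulation.

## Model

Each subject *i* follows a linear FA trajectory,

```
FA(t, i) = FA(0, i) + beta_i * t
```

and every scan measures it with independent Gaussian error:

```
FAhat(t, i) = FA(t, i) + eps,    eps ~ N(0, SEM)
```

Random effects across subjects: the true baseline `FA(0, i)` is
`N(mu_g, sigma_g)` with group-specific parameters (patients 0.326 ± 0.018,
controls 0.339 ± 0.023 by default); the patient slope `beta_i` is
`N(mu_beta, sigma_beta)` with `mu_beta = -(rate/100) * 0.326` FA/year and
`sigma_beta = 0.67 * |mu_beta|` (67% between-subject coefficient of
variation); control slopes are exactly zero. One power estimate simulates
2000 independent studies: each draws *n* patients and *n* controls, observes
*m* scans per session at day 0 and day *t*, compares the per-subject change
in session-mean FA between groups with a two-sided pooled t-test at
alpha = 0.05, and power is the fraction of significant replicates.

The per-scan error SD (the standard error of measurement, SEM) comes from
test-retest reliability analysis: the two-way mixed-effects, single-rater,
absolute-agreement intraclass correlation ICC(A,1), converted via
`SEM = sqrt( TSS/(k-1) * ICC * (1-ICC) )` with TSS the within-subject sum of
squares over *k* repeated measurements. The package ships the two reference
uncertainty levels 0.00054 (low, 62-gradient-direction protocol, ICC 0.97)
and 0.00134 (high, 52-direction protocol, ICC 0.91).

## Worked example

Reliability of a test-retest table (14 subjects scanned twice; the packaged
file is synthetic, generated from known variance components):

```r
library(dtipower)
path <- system.file("extdata", "synthetic_retest_14x2.csv", package = "dtipower")
compute_icc(read_retest_csv(path))
#> Test-retest reliability: ICC(A,1) = 0.9503, 95% CI [0.8523, 0.9838]
#>   14 subjects, 2 measurements each
#>   band (point estimate): excellent; band (CI): good to excellent
#>   SEM (sqrt variant): 0.00328043
```

The ICC point estimate is excellent (> 0.90) but its lower confidence bound
is only good — with 14 subjects, reliability is estimated imprecisely, which
is why the per-scan SEM, not the ICC itself, feeds the simulation.

Power of a short (30-day) follow-up design with two scans per session:

```r
sc <- scenario(rate_percent = 2.0,   # intermediate annual FA decline, %/yr
               sem = 0.00054,        # low measurement uncertainty
               t_days = 30, m = 2, n_per_group = 20, seed = 1)
estimate_power(sc)
#> Monte Carlo power estimate: 0.787 (1575/2000 significant, MC SE 0.0091)
#>   alpha = 0.05, seed = 1
analytic_power_oracle(sc)   # closed-form cross-check
#> [1] 0.7903465
```

Twenty subjects per group sit at the power ≈ 0.8 threshold: the second scan
per session is what makes a 30-day interval workable at this sample size
(with m = 1 the same design needs ~35 subjects per group).

The scan-repetition trade-off under high measurement uncertainty:

```r
red <- sample_size_reduction(scenario(rate_percent = 2.0, sem = 0.00134,
                                      t_days = 60, seed = 1),
                             m_from = 1, m_to = 2)
red
#> Moving from 1 to 2 scan(s)/session: required n 53 -> 30 (43.4% reduction)
```

A second scan per session cuts the required sample size by roughly 40% when
measurements are noisy — scans are cheaper than subjects.

## Command line

The same analyses are scriptable through the installed `exec/dtipower`
Rscript (subcommands `icc`, `simulate-retest`, `power`, `samplesize`,
`grid`; data to stdout or `--output`, logs to stderr):

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "dtipower", package = "dtipower"))')
Rscript "$CLI" power --rate 3.5 --sem 0.00134 --t-days 90 --n 12 --seed 1
Rscript "$CLI" samplesize --rate 2.0 --sem 0.00134 --t-days 60 --m 2 --seed 1
Rscript "$CLI" grid --config grid.yaml --output power_grid.csv --manifest manifest.yaml
```

Every subcommand accepts a YAML config (`--config`) whose keys mirror
`scenario()` arguments; command-line flags override file values, and a run
manifest (seed, resolved parameters, version) can be written next to every
output.

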