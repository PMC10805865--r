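# regrowth

Regression-growth modelling of tumor kinetics in clinical trials.

## What it does and for whom

Serial radiographic tumor measurements taken while a patient is on therapy
mix two processes: regression of the treatment-sensitive fraction of the
tumor and (re)growth of the resistant fraction. `regrowth` is for trial
statisticians and translational researchers who want to turn those
measurements into a per-patient **growth rate constant *g*** — a candidate
biomarker of overall survival — and then run the cohort-level analyses that
follow from it: kinetic classification tables, arm and subgroup comparisons
of the *g* distribution, survival by *g* tertile, doubling-time thresholds,
and "how early would the arms have separated" accrual analyses.

The core model describes the relative tumor quantity *f(t)* (baseline = 1,
*t* in days) with one of four nested exponential models:

| model | equation | parameters |
|---|---|---|
| `gd` | f(t) = e^(−d·t) + e^(g·t) − 1 | g, d |
| `gx` | f(t) = e^(g·t) | g |
| `dx` | f(t) = e^(−d·t) | d |
| `gd_theta` | f(t) = θ·e^(−d·t) + (1−θ)·e^(g·t) | g, d, θ |

where *g* and *d* (day⁻¹) are the growth and decay rate constants and θ is
the treatment-sensitive fraction. Because time enters explicitly, estimates
are indifferent to the assessment schedule, and *g* converts directly to a
doubling time T_d = ln(2)/g.

Per patient, the pipeline screens the series for sufficiency (at least a
baseline plus one scan changed by ≥ 20%, or three scans), normalizes to
baseline, fits all four models by bounded multi-start nonlinear least
squares, drops candidates with any parameter Wald *p* ≥ 0.1 (or on a
bound), and selects the admissible model with the lowest AIC
(= −2·logL + 2·k).

A synthetic-trial generator (`simulate_trial()`) reproduces the structure of
a 2:1 randomized trial — endocrine-sensitivity strata, per-arm kinetic-class
mixtures, ~6-weekly scans, multiplicative lognormal measurement noise, and
overall survival whose hazard rises with *g* — and exports ground truth, so
the whole pipeline is testable without access to any proprietary trial data.

## Worked example

Fit one patient whose tumor shrinks and then regrows:

```r
library(regrowth)
t <- seq(0, 378, by = 42)                      # 6-weekly scans
q <- c(64, 57, 54, 52, 53, 56, 60, 66, 73, 81) # tumor quantity (e.g. mm SLD)
fit <- growth_fit(t, q)
print(fit)
#> Regression-growth kinetic fit
#>   measurements: 10
#>   status:       fitted
#>   model:        gd_theta
#>   estimates:    g = 0.00296641, d = 0.00746345, theta = 0.598202
#>   doubling time: 234 days
#>   AIC:          -76.2328
```

The nadir-then-regrowth shape is best captured by the three-parameter model:
about 60% of the tumor responds (decay rate 0.0075/day) while the resistant
fraction regrows at g = 0.0030/day, a 234-day doubling time. `summary()`,
`coef()`, `predict()`, `plot()`, `residuals()` and `simulate()` work as for
any fitted model object.

Cohort level, on a small synthetic trial:

```r
trial <- simulate_trial(trial_config(n_experimental = 60, n_control = 30), seed = 42)
fits  <- fit_cohort(trial$measurements)
classify_cohort(fits, by = "arm")
#>                        all    control experimental
#> patients                90         30           60
#> sufficient data 75 (83.3%) 21 (70.0%)   54 (90.0%)
#> dx              16 (21.3%)   2 (9.5%)   14 (25.9%)
#> gd_theta          7 (9.3%)   0 (0.0%)    7 (13.0%)
#> gd              27 (36.0%)  7 (33.3%)   20 (37.0%)
#> gx              19 (25.3%)  9 (42.9%)   10 (18.5%)
#> total fit       69 (92.0%) 18 (85.7%)   51 (94.4%)
#> no fit            6 (8.0%)  3 (14.3%)     3 (5.6%)

g <- collect_g(fits)  # dx tumors imputed at g = 1e-4
compare_groups(g$g[g$arm == "experimental"], g$g[g$arm == "control"],
               "experimental", "control")
#> Rank-sum comparison of g: experimental (n=51, median 0.001036) vs control (n=18, median 0.002057)
#>   W = 326, two-sided p = 0.06845 (normal approximation)
```

The experimental arm's median *g* is about half the control arm's — the
kinetic signature of an effective therapy — though at 90 patients the
rank test is only borderline; at the full default trial size (393) the
same comparison is decisive. Doubling-time thresholds translate the *g*
vector into clinically readable fractions:

```r
dt_threshold_fractions(g$g[g$arm == "experimental"])
#>   threshold_g doubling_days n_at_or_below  fraction
#> 1     0.00190      364.8143            35 0.6862745
#> 2     0.00095      729.6286            25 0.4901961
#> 3     0.00063     1100.2336            21 0.4117647
```

i.e. 69% of experimental-arm tumors are doubling more slowly than once a
year. Survival and accrual stages follow the same pattern:
`tertile_analysis()`, `dx_overlay()`, `scan_accrual()`, `patient_accrual()`,
or everything at once via `run_full_pipeline()`.

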