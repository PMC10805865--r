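---
title: "Regression-growth kinetics: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-growth kinetics: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrowth)
```

## The model

On-treatment tumor trajectories commonly show simultaneous regression and
regrowth: a treatment-sensitive fraction of the tumor decays while a
resistant fraction continues to grow. Writing $f(t)$ for the tumor quantity
at day $t$ relative to baseline ($f(0) = 1$), the package fits four nested
exponential descriptions:

$$
\begin{aligned}
\texttt{gd}:\quad & f(t) = e^{-dt} + e^{gt} - 1 \\
\texttt{gx}:\quad & f(t) = e^{gt} \\
\texttt{dx}:\quad & f(t) = e^{-dt} \\
\texttt{gd\_theta}:\quad & f(t) = \theta e^{-dt} + (1-\theta)e^{gt}
\end{aligned}
$$

with growth and decay rate constants $g, d$ (day$^{-1}$) and sensitive
fraction $\theta \in (0,1)$. All four satisfy $f(0)=1$ by construction.
Because $t$ is explicit, estimates do not depend on the assessment
schedule, and $g$ converts to a doubling time $T_d = \ln 2 / g$ (we use
$\ln 2$ at full precision; the conventional rounded 0.693 agrees to 0.1%).
Under `gd` with $d > g$ the curve has its nadir at
$t^\ast = \ln(d/g)/(g+d)$ (`curve_minimum_time()`), a useful diagnostic.

Assumptions worth stating plainly: tumor quantity is treated as an
arbitrary positive scalar (sum of longest diameters, a volume — anything
proportional works, since fits are scale-invariant under baseline
normalization); rate constants are constant over the observation window;
residuals on the normalized scale are homoscedastic Gaussian. The model is
deliberately not Gompertzian or logistic — over typical on-study windows
(months) the exponential description is the parsimonious one.

## Per-patient estimation

1. **Sufficiency screen.** A series with no or one measurement, or exactly
   two whose change from baseline is below 20% in absolute value, carries
   too little signal to identify any rate and is classified
   `insufficient_data` rather than fitted. The threshold is relative to
   baseline, i.e. $|q_1 - q_0| < 0.2\,q_0$, and "exactly 20%" counts as
   sufficient (the rule is a strict inequality).
2. **Normalization.** $f_i = q_i / q_0$; the baseline point $(0, 1)$ is
   retained in the residuals — it is a (noisy) datum, not a constraint.
   Post-baseline zeros are retained too; no model can reach 0 and the
   residual simply penalizes them.
3. **Least squares.** Each model with at most $n - 1$ parameters is fitted
   by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) minimizing
   $\sum_i (f_i - f(t_i))^2$, with $g, d \in [10^{-6}, 0.5]$ day$^{-1}$ and
   $\theta \in [0.01, 0.99]$. The objective is multimodal for sparse
   series, so every fit is multi-started from a log-spaced grid
   ($10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}$ for each rate, crossed, and
   $\theta \in \{0.2, 0.5, 0.8\}$); the start reaching the lowest residual
   sum of squares wins. Convergence tolerance is fixed at $10^{-10}$ on the
   relative RSS change for reproducibility. Analytic Jacobians are
   supplied throughout.
4. **Significance gate.** Standard errors come from the asymptotic
   covariance $\hat\sigma^2 (J^\top J)^{-1}$ with
   $\hat\sigma^2 = \mathrm{RSS}/(n-k)$, and each parameter gets a
   two-sided Wald (normal) p-value. A candidate is admissible only if the
   optimizer converged, no parameter sits on a bound, and every p-value is
   below 0.1. A $\theta$ estimate pinned at its bound therefore invalidates
   the three-parameter fit and forces fallback to the simpler models.
5. **Selection.** Among admissible candidates the minimum
   $\mathrm{AIC} = -2\log L + 2k$ wins, with the Gaussian log-likelihood
   $\log L = -\tfrac n2(\ln(2\pi\,\mathrm{RSS}/n)+1)$ and $k$ the number of
   kinetic parameters (the error variance is not counted, matching the
   stated AIC formula). Ties break to fewer parameters, then to the fixed
   order dx < gx < gd < gd_theta. No admissible candidate at all yields
   status `no_fit`.

Two genuinely open readings had to be resolved. The significance gate
could be parameter-level or whole-model (F-test); we gate **per parameter**,
which is the reading that makes the documented fallback behaviour ("only
$g$ differs significantly from 0, so $d$ is eliminated") operational, and
it is what the nested-degeneracy tests pin down. Whether measurements
should be weighted or log-transformed before fitting is unstated in the
source analyses; we fit untransformed normalized quantities, the most
common convention for this model family.

A numerical subtlety: on noiseless data the RSS reaches machine zero and
the Gaussian log-likelihood is unbounded. Below RSS $= 10^{-12}$ (on the
normalized scale, $n \le$ a few dozen points) a fit is treated as exact
(log-likelihood $+\infty$), which keeps AIC selection well defined and
scale-invariant; competing exact fits resolve by parsimony via the tie
rules. Real measurement noise puts RSS many orders of magnitude above this
floor.

## Cohort analyses

**Classification.** `classify_cohort()` tabulates
{insufficient, dx, gd_theta, gd, gx, no_fit} per group. Denominators follow
the reporting convention of trial kinetic analyses: the sufficiency
fraction is out of all patients; model fractions are out of patients with
sufficient data.

**g collection and imputation.** Tumors best fit by `dx` have no detectable
growth. For distribution comparisons they can be included at a fixed low
$g = 10^{-4}$ day$^{-1}$ (`collect_g(impute_dx = TRUE)`), which can only
lower group medians; for tertile construction they are excluded — tertiles
are defined over patients in whom $g$ was actually determined.

**Comparisons.** "Non-parametric" two-sample comparisons are two-sided
Wilcoxon rank-sum tests: exact enumeration when both samples have at most
20 untied values, normal approximation with tie correction otherwise. The
tests are backed by `stats::wilcox.test`; an independent brute-force
enumeration oracle in the test suite pins the convention on every distinct
3-vs-3 ranking. Subgroup analyses compare **arm vs arm within each
subgroup** (the reading supported by how such figures are captioned),
crossed with the endocrine-sensitivity cohorts; cells under 5 patients per
arm are reported descriptively but not tested; p-values are nominal with
the number of tests flagged rather than corrected, mirroring exploratory
trial reporting.

**Doubling-time thresholds.** `dt_threshold_fractions()` reports the
fraction of patients at or below $g^\ast$ for thresholds defaulting to
0.0019, 0.00095, 0.00063 day$^{-1}$ — doubling times of about 1, 2 and 3
years — the kind of cutoff a "continue therapy while growth is slow"
decision rule would use.

## Survival analyses

Kaplan–Meier estimation and the logrank test are delegated to the
`survival` package behind `km_estimate()` and `dx_overlay()`; hand-worked
product-limit tables serve as the oracle in the tests. The median is the
first time the curve falls to 0.5 or below and is reported as undefined
(never extrapolated) when the curve does not get there. Tertiles of $g$
split at the empirical 1/3 and 2/3 quantiles (type-7 interpolation);
boundary values go to the lower tertile, and if ties collapse the
boundaries the split falls back to a stable rank-based three-way division
— the documented degenerate behaviour when all $g$ are equal. OS time is
measured from the baseline scan, which the synthetic generator defines as
randomization; the dx population is overlaid on the lowest-$g$ tertile
with a logrank statistic quantifying the expected overlap.

## Accrual analyses

`scan_accrual()` truncates every series to its first $k$ scans
($k = 3, \dots$), keeps everyone with at least baseline plus two further
scans (cumulative inclusion — patients with short series stay in at every
later $k$), refits, collects $g$ with dx imputation, and rank-tests the
arms at each $k$. `patient_accrual()` fixes the truncation at three scans
— the earliest point at which $g$ is estimable — and adds patients in
enrollment order, testing after each addition once both arms carry three
evaluable values, and reports the first crossing below $\alpha$. Both
trajectories are sequential looks without multiplicity correction; the
printout says so, and the null-calibration test verifies that a *single*
fixed-$n$ look holds its nominal 5% size. Truncation never invents data:
truncated series are prefixes of the originals.

## The synthetic-trial generator

`trial_config()` defaults encode the structure of a 393-patient 2:1 trial:
arm sizes 261/132; sensitivity split and per-arm × stratum kinetic-class
mixtures taken from the classification table of such a trial; per-arm
lognormal $g$ with medians 0.0009 (experimental) and 0.0023 (control) and
log-sd 1; scans every 42 days up to 10.

Values no published analysis states, chosen once on field-plausibility
grounds and not revisited: decay rates lognormal with median 0.008
day$^{-1}$ (log-sd 0.8 — tumor regression on effective therapy is an
order of magnitude faster than regrowth); $\theta \sim U(0.2, 0.8)$;
baseline quantity lognormal with median 50 and log-sd 0.5; multiplicative
lognormal measurement noise with log-sd 0.10 (a ~10% coefficient of
variation, a sensitivity-tested modelling choice, not a measured value);
per-scan dropout probability $1 - e^{-0.02 f}$ from the third scan on
(progressing patients leave the study; earlier discontinuation is modelled
explicitly by the insufficient-destined class, generated as one or two
scans with a sub-20% change); overall survival exponential with hazard
$h_0 g^{\beta}$ per month, $h_0 = 0.6$, $\beta = 0.5$ — calibrated so the
slowest and fastest $g$ tertiles land near the 48- and 18-month medians
reported for mature readouts of such trials — administratively censored at
73 months (a mature median follow-up); dx patients enter the hazard at the
$10^{-4}$ floor so their survival tracks the best tertile; patients
destined to be insufficient or unfittable draw a latent arm-typical $g$
for the survival link only. Stratifier marginals (visceral 60%,
age < 65 70%) carry no kinetic effect by default. All randomness derives
from one seed through per-patient substreams, so patient $i$'s data are
stable under changes to the total count.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: lesion-level bookkeeping (target/non-target
lesions, new lesions), inter-reader measurement variability, non-exponential
survival, informative censoring, correlated measurement errors within a
patient, and calendar-time enrollment dynamics. Tests against the generator
establish that the estimator and the downstream analyses do what they claim
under the stated error model, not that the error model is true of any
particular trial.

## Problem sizes and runtime choices

The test suite exercises: noiseless parameter recovery on 100 series (25
per model); the selection gate on 100 monotone-growth series; every
distinct 3-vs-3 rank configuration against the enumeration oracle;
100-replicate tertile-ordering runs at the full 393-patient structure
(ground-truth $g$ with generated survival, since the planted property lives
in the survival link, not the fitter); 100-replicate scan-accrual power
runs at 300 patients per trial with three scans; and 100-replicate null
calibration at 60 patients (the single-look type-I rate does not depend on
$n$). These sizes keep the full suite in the minutes range on one CPU
while leaving the replicate counts large enough for the stated
95%/80%-of-replicates properties to be sharp.

## Known limitations

- Homoscedastic Gaussian residuals on the normalized scale; no robust or
  heteroscedastic error models, no measurement weighting.
- No pooling across patients (no mixed-effects or Bayesian shrinkage);
  sparse series simply fall through the gate to `no_fit`.
- Wald p-values are asymptotic and anti-conservative for very short
  series; the gate partially compensates by also rejecting bound-pinned
  parameters.
- Point estimates only for Kaplan–Meier curves (no confidence bands), and
  no proportional-hazards modelling — the tertile analysis is deliberately
  model-free.
- The accrual trajectories are exploratory; no group-sequential boundaries
  are provided or implied.
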