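---
title: "Methods: TKTD survival models for pulsed exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TKTD survival models for pulsed exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tktdsurv)
```

This vignette documents the models implemented in `tktdsurv`, the
assumptions behind them, the numerical strategy, and the design decisions
taken where more than one reasonable choice existed.

## The modelling problem

Survivor counts from toxicity experiments are interval-censored: at each
observation time we know how many of the initial organisms are still
alive, not when each death occurred. When exposure varies over time —
pulses of pesticide separated by recovery periods — the probability of
surviving an interval depends on the whole concentration history, through
the organism's internal dose and its accumulated injury. TKTD models make
that dependence explicit with a small chain of linear ordinary
differential equations, and the GUTS family distinguishes two death
mechanisms that make opposite predictions for repeated identical pulses:

* **Stochastic death (SD)**: all organisms share one effect threshold
  `z`; above it, death is a Poisson-type hazard with rate proportional to
  the exceedance (killing rate `k_k`). A second pulse identical to the
  first kills again.
* **Individual tolerance (IT)**: each organism owns a fixed threshold
  drawn from a log-logistic distribution (median `alpha`, width `beta`);
  it dies the first time the dose metric exceeds it. Once the susceptible
  fraction has died, an identical second pulse — after full damage
  recovery — kills nobody, because survival depends on the exposure
  history only through the *running maximum* of the dose metric.

Both mechanisms can be driven either by scaled damage fed from a
measured-TK submodel ("full" variants, dose metric in nmol/g) or by a
scaled internal concentration driven directly by the water concentration
("reduced" variants, dose metric in nmol/mL). In the reduced variants the
single rate constant `k_d` lumps elimination and damage recovery; the
slower process dominates its value.

### Assumptions inherited from the model family

* Organisms are a single well-mixed compartment and do not change (no
  growth, no molting effects) during the experiment.
* `k_out` is total parent-compound loss; biotransformation is not
  modelled separately.
* The background hazard `h_b` is constant in time and shared by all
  treatments of an experiment; it is estimated from pooled solvent and
  non-solvent controls before the TD calibration and then held fixed.
* Death events are independent across organisms given the survival curve,
  which makes the interval death counts multinomial and justifies both
  the likelihood and the conditional-binomial simulator.

## Parameters and units

Time is in days everywhere; water concentrations in nmol/mL; tissue
concentrations in nmol/g.

| Parameter | Meaning | Units | Typical scale |
|---|---|---|---|
| `k_in` | uptake rate constant | mL g⁻¹ d⁻¹ | ~130 |
| `k_out` | elimination (total loss) rate | d⁻¹ | ~7 |
| `k_d` | damage recovery (full) / dominant rate (reduced) | d⁻¹ | 0.4–15 |
| `k_k` | killing rate | g nmol⁻¹ d⁻¹ (full), mL nmol⁻¹ d⁻¹ (reduced) | 5e-4–0.13 |
| `z` | SD effect threshold | nmol/g (full), nmol/mL (reduced) | 3–320 |
| `alpha` | IT threshold median | dose-metric units | 16–365 |
| `beta` | IT threshold width | – | 2–8 |
| `h_b` | background hazard | d⁻¹ | ~0.01 |

The "typical scale" column is the range spanned by published calibrations
of this model family for propiconazole in *Gammarus pulex*; the package
itself imposes only positivity (and `k_k`, `z`, `h_b` ≥ 0).

## Numerical strategy

### Piecewise-analytic integration

Exposure profiles are step functions (left-closed, right-open segments;
the value *at* a breakpoint belongs to the new segment, which keeps event
handling unambiguous). Within a segment of constant concentration every
state is a linear ODE with constant forcing, so the dose metric has the
closed form `A + P·exp(-k1 s) + Q·exp(-k2 s)` (full variants chain the TK
rate `k_out` into the damage rate `k_d`). The implementation therefore
never discretizes time:

* **Threshold crossings (SD).** Within a segment the metric has at most
  one interior extremum, located in closed form; on each monotone piece a
  crossing of `z` is root-found (`uniroot`, tolerance 1e-12) and the
  hazard integrand is integrated analytically between crossings.
* **Running maximum (IT).** Per-segment maxima come from the same
  closed-form extremum analysis (ties broken toward earlier time by
  taking the first attaining segment), and the running maximum is their
  cumulative maximum.
* **Equal-rate degeneracy.** When `|k_d - k_out| < 1e-9` the double
  exponential degenerates; the solver switches to the
  `t·exp(-kt)` limit form rather than dividing by a vanishing rate gap.

Rates up to ~7 d⁻¹ combined with the kink in `max(M - z, 0)` make naive
fixed-step solvers inaccurate at practical step sizes; the test suite
checks the analytic solver against a brute-force explicit-Euler
integration on 100 randomized scenarios and agrees to better than 1e-4 in
survival probability. (The Euler oracle is run at a step of 2e-5 d: at
1e-4 d the *oracle's* first-order bias, of order rate×dt/2, is itself
larger than the agreement band being certified.)

### Likelihood conventions

The multinomial interval likelihood uses the censoring convention
`S_{n+1} = 0`, `y_{n+1} = 0`: organisms alive at the last observation are
treated as dying in `(t_n, ∞)`, contributing `y_n·ln S_n`. Three
numerical rules keep it well-defined: `0·ln 0 := 0` (a deathless interval
of zero probability is uninformative); a positive death count in an
interval of *exactly* zero probability returns `-Inf` (not an error), so
the optimizer can reject the parameter region; and otherwise interval
probabilities are floored at 1e-12 before the logarithm so that perfect
fits remain finite.

The floor creates a flat likelihood plateau far from the optimum (every
interval pinned to the floor), which can strand a plain golden-section
search; the one-dimensional background-hazard fit therefore brackets the
optimum on a coarse log-spaced grid before refining locally.

### Calibration

Calibration is deliberately two-step, mirroring common practice with
these models: a Levenberg–Marquardt least-squares fit of the survival
curves to observed survivor fractions provides starting values, then
Nelder–Mead maximizes the log-likelihood. Both steps work on
log-parameters, which enforces positivity without hard clipping; invalid
regions are handled by a large penalty, never silently. Because the
likelihood surfaces of these models can be multimodal (the SD variants
calibrated on pulsed data alone are notoriously awkward), step 2 is
multi-start: 5 starts by default, the first from step 1, the rest
jittered around it with a seeded lognormal perturbation (sd 0.5 on the
log scale). `run_model_grid()` additionally seeds every "both"-calibrated
cell with the single-set solutions of the same variant — the total
likelihood of the joint fit must dominate those mathematically, so this
guards the comparison table against local optima.

### Profile-likelihood intervals

95% intervals come from the profile likelihood: the target parameter
walks a multiplicative grid (factor 1.2) away from its estimate, all
other free parameters are re-optimized at each step (warm-started from
the neighbouring solution), and the bound is located by bisection where
the profile drops 1.9207 below the maximum — half the 95% quantile of
χ²(1), the standard cutoff for this method. A profile that never drops
(e.g. the threshold when no treatment mortality occurred) yields a
"not determined" bound, reported as `NA` rather than an error or an
arbitrary large number.

## The synthetic-data generator

`generate_study()` emulates the study design that motivated the package:
treatments A and B (two 1-d pulses at 28 nmol/mL with 2-d and 6-d
recovery gaps, 10 d total), treatment C (constant 4.6 nmol/mL — the
time-weighted average of the pulsed treatments — for 10 d), a
7-concentration acute series spanning 8.2–37.4 nmol/mL over 4 d (equally
spaced between the printed endpoints, the individual test concentrations
not being available), TK exposures of 1 d at 8.7 nmol/mL followed by 5 d
(TK1) or 1 d (TK2) of depuration, ten organisms per beaker, and daily
observations. Replicate beakers are pooled into one dataset per
treatment, which is exactly how the likelihood treats them.

Survivor counts are drawn by conditional binomial thinning,
`y_i ~ Binomial(y_{i-1}, S_i/S_{i-1})` — the population-level law implied
by independent individuals under either death mechanism, and the same
probability model the likelihood assumes, so generator and estimator are
consistent by construction. TK observations get multiplicative lognormal
noise with a default CV of 0.15, chosen once as the order of the
analytical recovery spread reported for such measurements. The acute
datasets are generated without background mortality, matching the
near-complete control survival of short acute tests.

What the generator does *not* emulate: measured (as opposed to nominal)
concentration drift within segments, beaker-level covariates (feeding,
molting), correlated deaths within beakers, and any real-data deviation
from the fitted model family. Passing recovery and coverage tests on
synthetic data therefore demonstrates the estimation machinery is
self-consistent — not that the models describe any particular organism.

## Problem sizes used by the test suite

The parameter-recovery checks calibrate the reduced SD and IT variants on
synthetic studies with 700 organisms per treatment (bias below 10% per
free parameter), and the profile-interval coverage check runs 30
replicates at the study's own scale of 70 organisms per treatment,
pooling the three free parameters (≥90% coverage required). These sizes
were chosen to make the sampling error of the checks small relative to
the tolerances being asserted while keeping the default test run fast.

## Known limitations

* No combined SD+IT mixture model; no time-varying background hazard;
  no sublethal endpoints.
* TK and TD are fitted sequentially (TK first, then fixed), not jointly,
  so TK uncertainty does not propagate into the TD intervals.
* The LC50 module's confidence intervals are asymptotic (from the
  parameter covariance), not profile-based, matching standard
  dose-response software conventions.
* Confidence intervals are frequentist profile intervals; no Bayesian
  posterior sampling is provided.
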