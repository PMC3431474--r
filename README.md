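# tktdsurv

Toxicokinetic–toxicodynamic (TKTD) survival analysis for aquatic organisms
under pulsed and constant contaminant exposure, in the GUTS (general
unified threshold model of survival) family.

Pesticides reach streams in pulses, not at constant concentrations, and
time-weighted-average effect metrics can understate the harm of short, high
peaks. TKTD models resolve this by separating what the organism
accumulates (toxicokinetics, TK) from how accumulated dose translates into
mortality (toxicodynamics, TD). This package implements the complete
analysis for survivor-count experiments of the kind run on *Gammarus
pulex*: pulsed 10-day exposures, a constant treatment at the matching
time-weighted average, a standard 4-day acute series, and
uptake/depuration TK experiments. It is aimed at ecotoxicologists who want
to calibrate, compare and interrogate these models on their own survival
data, or to study the models' behaviour on simulated designs.

## Models

**Toxicokinetics** — one-compartment uptake/elimination with piecewise
constant external concentration C_ext(t):

    dC_int/dt = k_in * C_ext(t) - k_out * C_int(t)

**Dose metric** — either *scaled damage* D\* driven by the simulated
internal concentration ("full" variants; damage-recovery rate k_d),

    dD*/dt = k_d * (C_int(t) - D*(t))

or the *scaled internal concentration* C\*int driven directly by the water
concentration ("reduced" variants; dominant rate constant k_d lumping
elimination and damage recovery):

    dC*int/dt = k_d * (C_ext(t) - C*int(t))

**Death mechanism** — *stochastic death* (SD): hazard proportional to the
exceedance of a shared threshold z,

    dH/dt = k_k * max(M(t) - z, 0) + h_b,      S(t) = exp(-H(t))

or *individual tolerance* (IT): each individual has a fixed log-logistic
threshold (median α, width β) and dies when the running maximum of the
dose metric first crosses it,

    F(t) = 1 / (1 + (max_{τ≤t} M(τ) / α)^(-β)),   S(t) = (1 - F(t)) * exp(-h_b t)

All four variants (full/reduced × SD/IT) are integrated piecewise
analytically — within each constant-concentration segment the dose metric
is a double exponential, threshold crossings are root-found on the closed
form and the hazard is integrated exactly between crossings — so there is
no solver grid to tune.

**Calibration** is the two-step procedure used with interval-censored
survivor counts: least squares (Levenberg–Marquardt) on survivor fractions
to get starting values, then maximization of the multinomial interval
likelihood

    ln l(θ|y) = Σ_{i=1}^{n+1} (y_{i-1} - y_i) ln(S_{i-1}(θ) - S_i(θ))

with S_{n+1} = 0 (animals alive at the last observation die afterwards).
Confidence intervals come from the profile likelihood (bounds at a drop of
1.9207 = χ²₁(0.95)/2, walked on a log grid with re-optimization of the
other parameters). The package also fits log-logistic LC50 dose–response
curves by day, computes organism recovery times (time for the dose metric
to fall to 5% of its post-pulse maximum), and compares model variants by
total likelihood and mean percentage error across calibration data choices
(pulsed / acute / both).

A seeded synthetic-data generator reproduces the full study design
(two-pulse treatments with 2-d and 6-d recovery gaps at 28 nmol/mL, a
constant 4.6 nmol/mL treatment, a 7-concentration acute series, TK
uptake/depuration sampling) with conditional-binomial survivor counts, so
the whole pipeline can be exercised without any external data.

## Worked example

```r
library(tktdsurv)

## toxicokinetics of propiconazole in G. pulex (fitted rate constants)
tk <- tk_params(k_in = 130.9, k_out = 6.9)
baf(tk)                        # 18.97  -> bioaccumulation factor ~19 L/kg
elimination_time(tk, 0.95)     # 0.434 d -> 95% eliminated in ~10 h

## treatment A: two 1-d pulses at 28 nmol/mL separated by a 2-d gap
treatA  <- exposure_profile(c(0, 1, 3, 4), c(28, 0, 28, 0), end_time = 10)
variant <- model_variant("SD", "reduced")
params  <- sd_params(k_d = 1.7, k_k = 0.126, z = 16.4, h_b = 0.0105)
survival_sd(variant, params, treatA, times = 0:10)
```

```
   time dose_metric cumulative_hazard survival
1     0       0.000             0.000    1.000
2     1      22.885             0.234    0.791
3     2       4.181             0.320    0.726
...
11   10       0.001             0.719    0.487
```

The scaled internal concentration crosses the threshold z = 16.4 nmol/mL
during each pulse (peaks ≈ 22.9 and 23.0 nmol/mL), producing the two drops
in survival; between pulses only the small background hazard acts, and 49%
of the population is predicted to survive the 10 days.

```r
recovery_time(variant, params)   # 2.85 d from pulse start to 95% recovery

## calibrate on a synthetic replica of the whole study and profile the CIs
study <- generate_study(variant, params, tk = tk, seed = 1)
h_b   <- fit_background_hazard(study$controls)$h_b
fit   <- profile_cis(calibrate(variant, c(study$pulsed, study$acute),
                               h_b = h_b, seed = 1))
fit
```

```
TKTD fit: reduced-SD
  k_d    =     1.8398  (1.509-2.333)
  k_k    =   0.096701  (0.0667-0.1349)
  z      =     16.393  (14.92-17.27)
  log-likelihood = -341.4323; h_b = 0.0114; converged: TRUE
```

The generating values (k_d = 1.7, k_k = 0.126, z = 16.4) sit inside every
profile-likelihood 95% interval. `run_pipeline()` wraps the whole
workflow — background hazard, TK fit, the 12-cell calibration grid
({SD, IT} × {full, reduced} × {pulsed, acute, both}), model comparison,
recovery times and daily LC50s — from a single seeded YAML/list
configuration and writes a JSON report.

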