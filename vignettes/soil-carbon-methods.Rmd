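---
title: "Methods: tidal wetland soil carbon stock analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tidal wetland soil carbon stock analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalcarbon)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where a choice
was genuinely open.

## From cores to carbon densities

A soil core is a stack of measured depth intervals carrying dry bulk
density (BD, g cm⁻³), organic-matter fraction by loss on ignition (OM),
and sometimes a measured organic-carbon fraction (OC). Carbon density is
BD × OC (gC cm⁻³; × 1000 = kgC m⁻³).

**LOI-to-OC conversion.** OC is predicted from OM by a quadratic,
`OC = a·OM² + b·OM + c`. Two coefficient sets for the linear term are in
circulation, 0.421 and 0.0421. The package defaults to
`(a, b, c) = (0.074, 0.421, −0.0080)` because only that set is internally
consistent with the rest of the analysis: classic linear LOI conversions
for wetland soils have slopes near 0.40–0.45, and the organic
carbon-density ceiling k₁ · OC(1) ≈ 0.098 × 0.487 ≈ 0.048 gC cm⁻³ only
emerges with OC(1) ≈ 0.49 (the alternative set gives OC(1) = 0.108, an
implausibly carbon-poor pure peat). The alternative set remains available
through `oc_coefficients("printed")`. The raw quadratic is negative below
OM ≈ 0.018; outputs are clamped to [0, 1] on physical grounds.

**The conversion is preferred over measured OC.** When a sample has both
LOI and a measured OC, the conversion is used anyway, so that every core
shares one conversion and laboratory differences in OC methodology do not
leak into the response. Measured OC is used only where LOI is absent; a
sample with neither yields a missing carbon density (a data signal, not an
error).

**Aggregation to 10-cm increments.** Profiles are standardized onto
half-open slabs [0,10), …, [90,100) cm by depth-weighted averaging,
mathematically identical to normalizing sampling intervals to 1-cm cells
and summing. The terminal rule: if the deepest sample leaves the last
slab partially covered but more than 5 cm of it is measured, the deepest
sample's values are carried to the slab bottom (last-value
carry-forward, flagged `extrapolated` — a trend-based extrapolation would
require assumptions the data cannot support); at 5 cm or less the slab is
dropped as no-data. Tests verify the aggregation against an independent
1-mm brute-force discretization.

**Distribution of carbon density.** The pooled increment densities are
described by a normal distribution truncated at zero (maximum
likelihood via direct optimization of the truncated likelihood) and
compared by log-likelihood with a log-normal fit, for which exact zeros
are recast to a 0.01 kgC m⁻³ detection floor (= 1e-5 gC cm⁻³). The
truncation acknowledges a hard physical floor at zero without forcing the
right skew a log-normal implies.

## The ideal mixing model

Organic and mineral fractions are assumed to pack additively by volume,
giving

$$BD(OM) = \frac{1}{OM/k_1 + (1-OM)/k_2},$$

with self-packing densities k₁ (pure organic) and k₂ (pure mineral),
and the organic-matter density model OMD(OM) = OM · BD(OM), which rises
monotonically to k₁ at OM = 1. Assumptions worth stating: fractions mix
additively (soils where carbonate dissolution creates volume, as in
karstic embayments, can violate this); compaction during coring is
negligible; and OM is a faithful mass fraction (lab-specific LOI bias is
handled separately, by the submitter random effect).

Numerical choices: nonlinear least squares starts at (k₁, k₂) =
(0.1, 1.5) g cm⁻³ — physically typical values — with a Levenberg–Marquardt
optimizer and positivity bounds at 1e-4; the residual s.d. uses the
population denominator n. Uncertainty comes from a case-resampling
bootstrap (default 1000 iterations, percentile 95% intervals), chosen over
residual resampling because field BD scatter is strongly heteroscedastic
(large at the mineral end, small at the organic end). A bootstrap run
fails if more than 10% of iterations do not converge.

## The organic/mineral threshold

Carbon density responds to OM steeply below the organic plateau and
weakly above it, so a continuous two-segment linear model of carbon
density on OM detects the transition. The breakpoint is chosen by
exhaustive grid search over OM ∈ [0.02, 0.90] in steps of 0.001,
minimizing the residual sum of squares, with ties broken toward the
smaller OM — a fully deterministic search that needs no smoothness
assumptions. A case-resampling bootstrap yields the percentile interval;
single-segment data show up as a diffuse interval rather than a false
kink. The explanatory value of the resulting binary classification is
reported as the one-way ANOVA R² of carbon density on the two-class
factor, at the fitted breakpoint and at the conventional 20% and 35%
definitions. The threshold is estimated on slab-level (increment) data:
increments are the unit of every downstream analysis, and slab averaging
suppresses within-interval measurement noise without hiding the
transition.

Classification is strict: a soil exactly at the threshold is mineral,
since the organic class is defined by exceedance.

## Mixed models, AICc, and effect sizes

Carbon density is modelled as

```
carbon_density ~ fixed terms + (1 | submitter)
```

with categorical fixed effects drawn from climate (4 zones), salinity ×
vegetation (4 classes + unknown), soil class (organic/mineral) and depth
(the 10 increments as a categorical factor — treating depth categorically
matches the increment structure and lets model selection drop it
cleanly). The submitter random intercept absorbs laboratory bias shared
by one submitter's cores. All fits use maximum likelihood, not REML, so
AICc is comparable across fixed structures; AICc = AIC +
2k(k+1)/(n−k−1), whose correction is identically zero for an
intercept-free k = 0.

Model selection enumerates every subset of the candidate terms that
respects marginality (an interaction only enters with all its lower-order
terms), refuses more than 2¹² candidate structures, and ranks by AICc
with Akaike weights. Two dredges differing only in whether soil class is
a candidate give the with-soil and without-soil model pair.

Effect sizes use ω² = (SS − df·MS_err)/(SS_total + MS_err) on Type-III
sums of squares of the fixed-effects design with the random intercept
profiled out (each observation's predicted submitter effect subtracted
before the ANOVA). This is an approximation — documented as such — that
preserves the ranking of terms, which is what the analysis uses. With
interactions present, Type-III main-effect sums of squares are
conservative, so ω² magnitudes are smaller than a main-effects-only
decomposition would give; orderings are unaffected. Pseudo-R² follows the
Nakagawa–Schielzeth variance-components convention (marginal: fixed
variance over total; conditional: fixed plus random over total).
Predictions for validation and application use fixed effects only
(random intercept zero), so they apply identically to seen and unseen
submitters; an unseen *fixed* factor level is an error naming the level.

## Skill metrics

All scores are normalized by the reference standard deviation σ_r:
B* = (μ_m − μ_r)/σ_r, σ* = σ_m/σ_r, the correlation R with 1/n
denominators, and

$$RMSE^{*\prime} = \sqrt{1 + \sigma^{*2} - 2\sigma^* R},
\qquad RMSE^* = \sqrt{RMSE^{*\prime 2} + B^{*2}}.$$

The minus sign in RMSE*' is forced by the perfect-model identity: with
modeled ≡ reference (σ* = R = 1) the unbiased error must be 0, which
+2σ*R would violate (it gives 2); the package's tests assert this
identity, the Pythagorean relation, and scale invariance on random
inputs, plus exact agreement with the direct mean-centred computation.
Standard deviations use the population denominator n, consistent with the
1/n correlation; with n−1 denominators the mean-baseline identity
RMSE* = 1 would only hold asymptotically. Target-diagram coordinates sign
RMSE*' by sign(σ_m − σ_r). A strategy is *accurate* when |B*| < 1 for
every scored increment and *precise* when RMSE*' < 1 for every increment.

## Soil-survey emulation and bias correction

Survey data arrive as map units → components (with percent) → horizons.
Horizons aggregate to 10-cm slabs by overlap-weighted averages under
survey conventions: BD present with OM missing means OM = 0; BD missing
means no-data. Components aggregate to map units by component-percent
weights, renormalized per slab over components with data; zero-percent
components are ignored; only hydric components participate. Carbon uses
the van Bemmelen factor (0.58 gOC/gOM) — deliberately the survey
convention, not the empirical quadratic — and no rock-fragment
correction, which does not apply to tidal wetland soils.

Bias correction fits the mixing model to the survey OM–BD pairs and to
the empirical calibration pairs, standardizes each survey residual by the
survey residual s.d., and rebuilds it on the empirical curve scaled by
the calibration residual s.d.: the survey's anomaly *pattern* is kept
while its mean and variance structure is replaced by the empirical one.
A corrected value below zero is assigned the minimum pre-correction
survey BD. Degenerate case: a zero survey residual s.d. defines all
standardized residuals as 0. One symbol collision is worth noting: the
scale used to rebuild residuals is the *residual* s.d. of the calibration
mixing fit, not the calibration carbon-density s.d. that elsewhere
standardizes the submitter effect.

## The synthetic-data generator

The generator's defaults are the study conditions: 1959 cores in five
salinity × vegetation classes with proportions 1533 : 157 : 46 : 87 : 134
(estuarine emergent dominant), four climate zones, 49 submitters, core
lengths log-normal with mean ≈ 55 cm and median ≈ 24 cm (shallow
monitoring cores dominate), mixing-model BD with (k₁, k₂) =
(0.098, 1.67) g cm⁻³ plus Gaussian noise (s.d. 0.05 g cm⁻³, clamped at a
0.01 g cm⁻³ physical floor), and submitter intercepts of s.d.
0.006 gC cm⁻³ on carbon density. Each core draws a class-dependent mean
OM — mineral from a truncated normal on [0, 0.132], organic on
(0.132, 1] — so a detectable threshold structure exists by construction.

Values not fixed by the study conditions were calibrated once, before
the tests were written, to the emulation targets and then frozen:
mineral OM mean 0.10 (s.d. 0.04), organic OM mean 0.30 (s.d. 0.25),
organic core fraction 0.5, and a 45% proportional OM decline from surface
to 1 m. Under these defaults the generated increment carbon densities
average ≈ 0.027 gC cm⁻³ with s.d. ≈ 0.013 (the distribution targets), the
surface-to-depth OM profile runs ≈ 25% → 14% with BD rising in
compensation, and the climate mix (0.10/0.35/0.30/0.25 across
mediterranean/subtropical/temperate-warm/temperate-cool) reflects the
Gulf- and Atlantic-heavy geography of national coring effort.

The submitter effect is additive on carbon density at the increment
level, mirroring the random-intercept model term. Since the generator
emits BD and OM (carbon density is always derived downstream), the
intercept u_s is carried through bulk density as ΔBD = u_s / max(OC, 0.02);
the OC floor prevents blow-up in nearly carbon-free samples at the cost
of attenuating the effect below OM ≈ 0.07. A side effect is realistic:
BD scatter around the mixing curve is much larger at the mineral end
than the organic end, as in field data.

The map-unit generator draws horizon OM from the same class
distributions, evaluates BD with k₁ multiplied by a configurable bias
(2.7 reproduces survey-style organic packing densities of ≈ 0.26 g cm⁻³
against a true 0.098), and flips a configurable fraction of mapped class
labels against the truth, so classification error and its commission
asymmetry can be injected and audited exactly.

What the generator does **not** emulate: geographic coordinates and any
spatial autocorrelation (classes are assigned directly, and reference
cores are paired to map units by class-matched random assignment rather
than colocation); carbonate chemistry and non-additive karstic soils;
depth-varying self-packing densities; heteroscedastic *measurement* error
beyond what the submitter carrier induces; and true inter-annual or
geomorphic structure. Passing tests therefore demonstrate that the
machinery is correct under the stated statistical structure, not that
real-world mapped products behave this way.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, saves and restores the
caller's RNG state, and is byte-reproducible. The test suite exercises
parameter recovery at sizes chosen to balance statistical power against
run time: bootstrap coverage with 100 replicates of n = 500 pairs at 200
bootstrap iterations; breakpoint recovery on n = 600 at noise s.d. 0.002;
model-selection recovery with 50 replicates of n = 2000 increments; the
full pipeline at 250–1959 cores. The acceptance script runs the complete
pipeline at the full 1959-core scale with 1000 mixing-bootstrap
iterations and 100 threshold-bootstrap iterations — the threshold
bootstrap is the scaled-down count, since each iteration is an 881-point
grid search.

## Known limitations

- ω² on mixed models is an approximation (random intercept profiled out
  via BLUP subtraction); no p-values are reported for mixed-model terms.
- The bootstrap treats increments as exchangeable cases; it does not
  resample at the submitter-cluster level, so intervals for quantities
  dominated by between-submitter variance (notably k₂, identified by the
  sparse near-pure-mineral end) can be optimistic in small datasets.
- Terminal-slab extrapolation is last-value carry-forward; no trend.
- Spatial application is emulated by class-matched assignment of cores to
  map units; real-map colocation error is not modelled.
- Emissions-over-time accounting is out of scope; the package stops at
  stocks.
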