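# tidalcarbon

Tools for tidal-wetland soil carbon accounting: converting soil-core depth
profiles into standardized carbon densities, modelling the physical link
between organic matter and bulk density, and scoring competing strategies
for mapping national-scale carbon stocks.

Tidal wetlands (saltmarshes, tidal freshwater wetlands, mangroves) store
large amounts of organic carbon in anoxic soil. Carbon accounting needs the
carbon density profile — bulk density (BD, g cm⁻³) times fraction organic
carbon (OC) — standardized across heterogeneous coring campaigns, and a way
to decide whether maps of soil, vegetation, salinity or climate classes
actually improve on applying a single empirical mean density. This package
implements that full analysis and ships a synthetic-data generator that
emulates the statistical structure of a national soil-core synthesis, so
every stage is testable and reproducible without any external download.

## The models

**Ideal mixing model.** Organic and mineral soil fractions pack additively
by volume, so bulk density is a function of the organic-matter fraction
(OM) and the two *self-packing densities* k₁ (pure organic) and k₂ (pure
mineral):

    BD(OM) = 1 / (OM/k1 + (1 − OM)/k2)

The derived **organic-matter density model**, OMD(OM) = OM · BD(OM), rises
monotonically to k₁ at OM = 1, putting a physical ceiling on organic-matter
(and hence carbon) density in organic soils: with k₁ = 0.098 g cm⁻³ and the
quadratic LOI-to-OC conversion `OC = 0.074·OM² + 0.421·OM − 0.008`, the
ceiling is ≈ 0.048 gC cm⁻³.

**Organic/mineral threshold.** A continuous two-segment regression of
carbon density on OM, with the breakpoint chosen by exhaustive grid search
and bootstrapped, detects the OM fraction separating mineral-dominated from
organic-dominated behaviour.

**Mixed models and model selection.** Carbon density is modelled with
categorical fixed effects (climate, salinity × vegetation, soil class,
depth increment) and a random intercept per data submitter (laboratory
bias). All marginality-respecting fixed structures are fitted by maximum
likelihood and ranked by AICc, with Akaike weights, ω² effect sizes and
Nakagawa–Schielzeth pseudo-R².

**Skill metrics.** Strategies are scored per 10-cm depth increment by
normalized bias B* = (μ_m − μ_r)/σ_r, unbiased RMSE*' =
√(1 + σ*² − 2σ*R), and total RMSE* = √(RMSE*'² + B*²), all scaled by the
reference standard deviation; RMSE* < 1 beats applying the reference mean.
A strategy is *accurate* if |B*| < 1 on every increment and *precise* if
RMSE*' < 1 on every increment.

**Soil-survey emulation and bias correction.** Map-unit → component →
horizon tables are aggregated by depth- and percent-weighted averages (van
Bemmelen factor 0.58 for carbon), classified organic/mineral, and
bias-corrected by transferring standardized residuals from the survey's
mixing-model fit onto the empirical calibration curve.

## Worked example

```r
library(tidalcarbon)

cfg   <- generator_config(n_cores = 300, seed = 42)
cores <- generate_core_dataset(cfg)
inc   <- aggregate_cores(cores)          # standardized 10-cm increments

fit <- mixing_model(inc$om_fraction, inc$bulk_density)
print(fit)
thr <- fit_segmented_threshold(inc$om_fraction, inc$carbon_density,
                               n_boot = 100, seed = 1)
print(thr)
mean_kg_m3 <- 1000 * mean(inc$carbon_density, na.rm = TRUE)
total_stock(mean_kg_m3, area_ha = 2.67e6)  # Pg C in the top metre
```

Output:

```
Ideal mixing model fit
  k1 (organic): 0.09818 g cm^-3 (s.e. 0.0032)
  k2 (mineral): 1.638 g cm^-3 (s.e. 0.0617)
  residual s.d.: 0.2303 g cm^-3 (n = 1213)
Segmented threshold: OM = 13.5% (95% CI 12.2% to 14.7%)
Classification R^2: 0.48 at breakpoint, 0.45 at 20%, 0.29 at 35%
[1] 0.7076643
```

The mixing fit recovers the generating self-packing densities (k₁ ≈ 0.098,
k₂ ≈ 1.67 g cm⁻³); the detected threshold (13.5% OM) separates organic from
mineral soils; and applying the dataset's mean carbon density
(26.5 kgC m⁻³) over 2.67 million hectares to 1 m depth gives ≈ 0.71 Pg of
soil organic carbon.

`run_pipeline()` chains every stage — generation, aggregation,
calibration/reference split, distribution and mixing fits, threshold
detection, AICc model selection, per-increment skill scoring of all mapping
strategies, map-unit aggregation and bias correction, and the scenario
stock table — and can write a report directory of CSVs, a JSON summary and
a log. A thin command-line wrapper is available:

```sh
Rscript scripts/tidalcarbon.R run --config config.yaml --out report/
```

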