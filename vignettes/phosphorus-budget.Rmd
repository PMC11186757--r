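---
title: "Assembling an ecosystem phosphorus budget and quantifying CO2 effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling an ecosystem phosphorus budget and quantifying CO2 effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbudget)
```

## The accounting model

A whole-ecosystem phosphorus budget is a mass-balance ledger: standing
stocks (pools, g P m⁻²) in every biological and pedological compartment,
and annual transfers (fluxes, g P m⁻² yr⁻¹) between them. `pbudget`
implements the ledger for a two-treatment FACE design with three plots per
CO₂ level, taking plot-level field measurements as input and producing
per-plot budgets, treatment summaries and effect sizes.

The accounting rules, in the order the pipeline applies them:

**Plant pools.** Each vegetation pool is tissue P concentration times
standing biomass (`plant_pool()`). Components: canopy leaves, sapwood,
heartwood, fine roots (< 2 mm, pooled with the 2–3 mm class), coarse roots,
understorey aboveground, forest-floor leaf litter and standing dead wood.
Two conventions inherited from field practice matter here: coarse roots and
all minor woody tissues (bark, twig, branch, reproductive structures) carry
the *sapwood* P concentration, because those tissues are rarely assayed
separately; standing dead wood carries a mixed wood concentration.

**Soil pools.** Depth-resolved concentration × bulk density × layer
thickness (`soil_pool()`), by default over 0–10, 10–30 and 30–60 cm.
Organic P is computed by difference (total − inorganic) at the pool level,
so `organic + inorganic = total` holds exactly per layer. Microbial biomass
P comes from chloroform-fumigation extract pairs via `microbial_p()`:
the fumigation-induced increase in extractable P divided by the extraction
efficiency `k_EP = 0.4`. Negative fumigation differences (possible with
noisy extracts) are clamped to zero and counted — a negative microbial pool
is not physical, and silent negative values would corrupt the organic
residual pool downstream. Hedley sequential-fractionation measurements are
grouped conservatively (`hedley_group()`) into exchangeable inorganic,
exchangeable organic and moderately labile organic P, with everything else
— the occluded residual — defined by difference from aqua-regia total P and
floored at zero with a flag.

**Depth extrapolation.** Several quantities are measured repeatedly only in
the surface layer, with a single deep-profile campaign late in the
experiment. `profile_scale()` carries the surface estimate down the profile
in proportion to a per-layer reference: for microbial and labile P the
reference is the deep-campaign *concentration* profile (the ratio of the
2017-style campaign concentrations); for the net-mineralization flux the
reference is the per-layer *soil-carbon stock* (concentration × bulk
density × thickness), reflecting the assumption that mineralization
activity scales with organic matter, microbial and root mass rather than
with concentration alone. Missing deep layers are only ever filled this
way, never by cross-plot imputation.

**Vegetation fluxes.** Plant P demand is the exact sum of the component
production fluxes: canopy (litterfall-derived production plus the
independently measured insect-frass consumption flux, `canopy_production()`),
understorey, wood, reproduction, coarse root and fine root. Resorption
fluxes apply the green-vs-senesced leaf concentration difference
(`resorption_fraction()`) to canopy and understorey production, the
sapwood-vs-heartwood difference to wood and coarse-root production, and a
fixed 50% coefficient to fine roots (live and dead fine roots cannot be
separated reliably). Uptake is then *defined* as demand − resorption
(`plant_uptake()`), which makes the closure identity
`demand = resorption + uptake` exact by construction — the validation
stage checks it to 10⁻⁹ as a guard against accounting regressions, not as
a scientific test.

**Annualization.** Interval series (monthly litter traps, quarterly
incubations) are summed within year by `annualize()`; incomplete coverage
is scaled by `365 / covered_days`, while full or leap-year coverage is
never scaled down. Multi-year series are annualized first and averaged
across years second, and sub-replicates are averaged to plot level before
anything else — the plot is the experimental unit throughout.

**Indicators.** Mean residence time is the standing vegetation pool over
uptake. The numerator deliberately excludes heartwood and coarse roots
(and litter and standing dead): MRT is meant to track the actively cycling
vegetation P, and including the inert woody stores would roughly double it
while destroying its sensitivity to uptake changes. P-use efficiencies
divide carbon fluxes by P fluxes: overstorey/understorey GPP by the
respective leaf P production flux, and — for growth efficiency — total NPP
by the uptake flux. The growth-efficiency definition is the one that makes
dimensional sense for units of g C g⁻¹ P (NPP/uptake, not demand/NPP); the
ambiguity exists in field usage and we resolve it by the units.

## Effect-size machinery

With `n = 3` plots per arm, hypothesis tests alone are nearly uninformative;
the package therefore reports effect sizes with stacked confidence
intervals. For each budget variable:

$$\Delta = \bar{x}_{ele} - \bar{x}_{amb}, \qquad
SD_{eff} = \sqrt{\tfrac{1}{2}(SD_{amb}^2 + SD_{ele}^2)}, \qquad
CI_{eff} = t_{L,\,n_1+n_2-2} \; SD_{eff} \sqrt{\tfrac{1}{n_1}+\tfrac{1}{n_2}}$$

with two-tailed critical values at 95, 85 and 75% (so a reader can see at
which confidence the interval first excludes zero), the SEM reported as
`SD_eff·√(1/n₁+1/n₂)`, and the relative effect as `100·Δ / x̄_amb`.

`bootstrap_effect()` provides the percentile-bootstrap counterpart:
datapoints are resampled with replacement within each arm, the arm-mean
difference recomputed per draw (1000 by default), and percentile intervals
taken at the same levels. Design choices worth stating:

* **Resampling unit.** The default datapoints are plot-level values,
  preserving the plot as the unit of inference; callers may pass
  plot-year or sub-replicate records for a temporal-fluctuation
  sensitivity analysis instead.
* **Percentile method.** Plain percentile intervals, not BCa or basic —
  transparent, monotone-equivariant, and adequate for a sensitivity check;
  the method is isolated in one function should a different flavour be
  needed.
* **Small-n caveat.** At n = 3 per arm the percentile bootstrap *must*
  undercover (there are only 10 distinct resamples per arm); the
  Monte-Carlo harness therefore verifies nominal coverage of the bootstrap
  at 50-vs-50, and of the exact t interval at 3-vs-3. This is a property of
  the estimator, not of the implementation, and is why the bootstrap is a
  sensitivity test rather than the primary interval.
* **No multiplicity correction** is applied across budget variables,
  matching standard practice for descriptive effect-size tables; the null
  calibration harness quantifies exactly what the per-variable error rate
  means under no true effect.

The linear mixed-effect confirmation (CO₂ × year fixed, plot random) is
out of scope by design; `effects_model_table()` emits the model-ready long
table for external tools.

## The synthetic site

`site_config()` parameterizes a synthetic site whose *noise-free* budget —
`budget_truth()`, computed in closed form — reproduces the ambient-treatment
values of a mature P-limited eucalypt woodland: canopy 0.23, sapwood 0.36,
heartwood 0.30, fine root 0.24, coarse root 0.15, understorey 0.23, litter
0.06, standing dead 0.04 g P m⁻²; soil 31.8 = 25.1 organic + 6.7 inorganic;
microbial 5.97; labile 1.15 g P m⁻²; demand 0.71 = resorption 0.32 + uptake
0.39; net mineralization 0.67 g P m⁻² yr⁻¹. The calibration solves the
budget exactly; with canopy resorption at 55%, the sapwood fraction at 0.5
and fine roots at 0.5, the understorey resorption fraction comes out at
12/35 ≈ 34% — below the canopy value, consistent with overstorey trees
resorbing more efficiently than grasses.

The generator (`generate_measurements()`) emulates the sampling design,
not the process dynamics:

* plot-level values for every primitive quantity are drawn around the
  treatment expectation with the configured between-plot CV, by default
  using a zero-truncated normal (no negative concentrations, masses or
  densities); a mean-unbiased lognormal is available as an alternative;
* records (sub-replicates, repeated dates) are drawn around the plot value
  at half the plot-level CV. The within-plot variance is not identifiable
  from published treatment summaries, so the factor 0.5 is an explicit free
  choice exposed as `subrep_cv_factor`;
* default CVs are back-computed from published between-plot SD/mean ratios
  (e.g. soil P 5.7/31.8 ≈ 18%), split in quadrature between the
  concentration and mass factors of each pool. One exception: the printed
  dead-wood SD equals its mean (CV = 1), which is both outside the
  generator's validity domain (CV < 1) and badly biased under truncation;
  the default caps dead-wood CVs at 0.35;
* dates carry no trend — field analyses of this design found the CO₂
  effect consistent across years, so the generator spends its realism
  budget on the between-plot variance structure instead;
* elevated-treatment expectations are ambient expectations times
  `co2_multipliers`. Multipliers are keyed by primitive (a concentration,
  a mass, a production rate, a soil variable) or by the convenience keys
  `uptake`/`demand`/`production`, which scale every production rate
  uniformly so that demand, resorption and uptake all scale by the same
  factor and the budget identities are preserved exactly;
* one master seed; each table draws in its own deterministic substream, so
  identical `(config, seed)` is bit-reproducible and adding records to one
  table never shifts another's draws.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: temporal autocorrelation and trends, spatial
structure within plots, correlated errors between variables measured on
the same sample, assay-specific biases (the pipeline starts at measured
concentrations), and any mechanistic P-cycle feedback. It is a statistical
emulator of the design, built so that estimator properties (bias,
coverage, calibration, recovery) can be verified against known truth.

## Numerical choices

* Internal canonical units are g P m⁻² and g P m⁻² yr⁻¹; unit conversion
  happens exactly once, inside the elementary operations.
* Closure identities that are exact by construction are validated at
  10⁻⁹; the CV = 0 pipeline-vs-truth equivalence check uses the same
  tolerance (observed agreement is at machine epsilon).
* Truncated-normal draws use the inverse-CDF, consuming exactly one
  uniform per value regardless of CV, which is what makes the substream
  guarantees above hold even when parameters change.
* Degenerate-input policies are explicit: negative fumigation differences
  clamp to 0 (flagged), Hedley residuals floor at 0 (flagged),
  senesced > green clamps the resorption fraction into [0, 1] (flagged),
  and resorption > demand retains the negative uptake with a warning.
* Reported tables round to 3 significant figures; all comparisons in tests
  use tolerances on unrounded values.

## Problem sizes used in verification

The test and acceptance harnesses simulate at the study design (3 plots per
arm) unless the check requires otherwise: generator unbiasedness uses 200
plots per arm at CV = 0.1 (3-SE Monte-Carlo bands); t-interval coverage uses
500 simulated experiments at 3-vs-3; bootstrap coverage uses 500 experiments
at 50-vs-50 with 1000 resamples; null calibration uses 1000 simulated
experiments; and recovery of a configured +8% uptake multiplier averages 50
independent full-pipeline experiments. These sizes put Monte-Carlo error
comfortably below the tolerances being asserted while keeping the default
suite quick to run.

## Known limitations

* Gross mineralization and immobilization are not separated (the in-situ
  incubation measures the net), and no uncertainty is propagated through
  the laboratory chemistry — inputs are taken as measured concentrations.
* Uptake is defined by difference, so any bias in demand or resorption
  propagates into it one-for-one; the budget cannot detect compensating
  errors between the two.
* The depth extrapolation assumes proportionality to the chosen reference
  profile; where deep processes decouple from soil carbon or from the
  campaign-year concentration profile, deep-layer estimates inherit that
  error.
* The bootstrap at n = 3 is a sensitivity device, not a calibrated
  interval (see above).
* The generator reproduces statistical structure only; it is not evidence
  about mechanism.
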