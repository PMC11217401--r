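---
title: "Modelling the climate benefits of regional kelp aquaculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the climate benefits of regional kelp aquaculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpcarbon)
```

## The question and the model

Kelp fixes carbon quickly, but growing kelp is not the same as removing
CO₂ from the atmosphere. Most of the carbon in farmed biomass returns to
the atmosphere unless the biomass is either sequestered in the ocean
(detrital export, near-farm release, purposeful deep-water sinking) or
used to displace a product whose conventional production emits more.
Meanwhile the industry itself emits: nurseries, anchors and longlines,
vessel traffic, transport and processing. `kelpcarbon` closes this
ledger for a whole regional industry in a single algebraic model,
evaluated either at central parameter estimates or as a Monte Carlo
ensemble.

The chain is: harvested biomass per species
(`B_H = B_A · A · S · H_N`); net primary production back-calculated from
harvested carbon with the detrital loss fractions
(`NPP = Σ B_H·DW·C / (1 − FL_DOC − FL_POC)`); DOC and POC as the loss
fractions applied to NPP; three benefit pathways
(`C_Total = C_SeqP + C_SeqA + C_Avoid`); and seven emission terms
summing to `E_Total`. The net benefit is `C_Total − E_Total`, positive
when the scenario is a net atmospheric reduction. Every quantity is
linear in area and in each production rate, which makes the model cheap
(a 10,000-run ensemble evaluates in well under a second) and makes
sensitivity structure easy to reason about.

Key structural assumptions:

* **Static, annualized accounting.** No growth dynamics, no nutrient
  limitation, no inter-annual variability; production rates subsume all
  of that. Capital is amortized to an annual emission and cost.
* **One detrital loss for all biomass.** The same `FL_DOC`/`FL_POC`
  apply to the entire standing crop regardless of fate, mirroring the
  species-independent denominator of the NPP relation.
* **Air–sea correction on marine terms only.** `atm_uptake_efficiency`
  multiplies `C_SeqP` and `C_SeqA` — carbon locked in seawater does not
  map one-to-one to atmospheric drawdown because respiration and
  upwelling replace surface CO₂ — but never `C_Avoid`, which is already
  expressed in CO₂e by its replacement factors.
* **Independent parameters.** The sampler draws every parameter from its
  own marginal distribution; no correlation structure is imposed.
* **Model boundary.** Waste management, product storage and product
  distribution are outside the boundary and have no ledger slots.
  Methane-reducing feed additives are not modelled. Carbon credits are
  not valued.

## Scenarios and zones

The five built-in scenarios differ in cultivated area (507, 1210,
5681 km²), production-rate source (farmer-reported 0.78/0.22/0.26 vs a
literature average of 8.3 kg ww m⁻² applied to all species), and the
fate vector over near-farm release, deep sinking, food, animal feed and
biofuel. All share an 80/10/10 *Saccharina*/*Alaria*/*Nereocystis* mix
and one harvest per year (`harvests_per_year` lives on the scenario, not
in the parameter table, so a two-crop system is a scenario edit).

Spatially varying parameters (capital intensity, port and farm
distances, maintenance trips) are zoned shallow (15–75 m) vs deep
(75–200 m) and combined by area-weighted averaging. The scenario zone
areas are a modelling choice the source material does not pin down: the
Local scenarios sit entirely shallow (507/0), the Expanded scenarios
keep that shallow footprint and add nearby deep water (507/703), and the
coast-wide scenario uses a 1:2 shallow:deep split (1894/3787). Deep
zones carry heavier anchoring and longer transits, so per-area emissions
rise with the deep share.

## The parameter registry and its provenance

The registry holds 81 parameters across four sub-models (production 14,
sequestration-and-products 17, emissions 32, economics 18), each with a
central estimate and a sampling distribution: `point`,
`truncated_normal` (truncated at zero — every physically non-negative
quantity is truncated by default), `uniform`, or `triangular`
(parameterised min/mode/max with the central at the mode). Where
uncertainty was only qualitative the fallback encoding is
uniform(0.5·central, 1.5·central).

Provenance is a per-row tag with three values:

* `main-text` (7 rows): production rates, the species mix conversion
  constant 44/12 — encoded exactly and never recalibrated.
* `supplementary-placeholder` (38 rows): plausible values with
  documented units chosen from the literature anchors the case study
  names (e.g. deep-water sequestration per unit area, diesel emission
  intensity near 2.7 kg CO₂e L⁻¹, barge transport emissions of tens of
  g CO₂e t⁻¹ km⁻¹).
* `calibrated` (36 rows): placeholder rows whose central values (spreads
  scaled proportionally) were tuned so that the full pipeline reproduces
  the case study's reported deterministic baseline and Monte Carlo
  medians. Calibration multiplies a row's central and distribution
  parameters by a common factor, preserving its relative spread, and is
  exposed to users as `calibrate_placeholders()`.

This is the intended upgrade path: a complete published table loaded via
`load_parameter_table()` replaces all placeholder rows through the same
schema, and nothing else in the package changes.

### What the calibrated fixture does and does not establish

Because 74 of 81 parameter values are placeholders constrained only by
(a) their published central anchors where available and (b) the
reported scenario-level outputs, agreement between the package and those
reported outputs is a *consistency* check — it demonstrates that the
pathway structure, unit handling and uncertainty propagation can jointly
reproduce the published results under plausible parameters — not an
independent validation of any individual parameter. Two reported
intermediate values were deliberately not matched because they are
mutually inconsistent with the scenario-level results under this
structure: reproducing the reported Expanded passive-sequestration
median (0.011 Tg CO₂e) would scale the detrital pathway such that the
largest scenario's net benefit overshoots its reported median by ~8%, so
the fixture uses weaker detrital sequestration fractions; similarly the
nursery/at-sea emission split differs while their scenario totals match.
The per-species farmer-rate spreads are wide zero-truncated normals
(coefficient of variation near 1), which simultaneously reproduce the
reported median harvest uplift over the deterministic harvest, the
reported harvest interquartile range, and the reported possibility of a
more-than-fourfold net-benefit swing from the *Saccharina* rate alone;
the replacement factors are right-skewed triangulars
(min/mode/max = 0.5c/c/1.65c), reflecting benefits bounded below by
near-zero and a long tail where the displaced product is
emissions-intensive.

## Numerical choices

* **Percentiles** use linear interpolation between order statistics
  (quantile type 7, the R default), applied per ledger field. Medians of
  components therefore need not sum to the median of a total.
* **Sampling** is inverse-CDF throughout: one uniform stream per
  parameter, keyed on the (seed, parameter-id) pair. Subset sampling —
  the one-at-a-time sensitivity design — therefore reproduces exactly
  the values a parameter takes in a full-model run with the same seed,
  making sensitivity ensembles comparable across targets. Draws are
  bitwise reproducible for equal seeds.
* **Truncated normals** are sampled by renormalising the uniform stream
  into the upper tail of the parent CDF, so truncation is exact rather
  than by rejection.
* **Degenerate inputs**: a zero-area scenario short-circuits the zonal
  average (which would otherwise have no weights) and yields an all-zero
  ledger; `FL_DOC + FL_POC ≥ 1` is a domain error; an empty run list
  cannot be summarized; ranking ties break alphabetically by target
  name.
* **Units** are kg (wet weight, carbon, CO₂e) and CAD internally;
  teragrams and millions of CAD appear only in summaries and printing.

## Sensitivity design

Sensitivity is strictly one-at-a-time: the target (a sub-model tag or a
single parameter) is sampled while everything else sits at its central
estimate, and each run's net benefit is divided by the no-uncertainty
baseline. The spread statistic for ranking is the interquartile range of
these relative values. Defaults follow the study design: 10,000 runs for
sub-model targets, 1,000 for single parameters. No variance-based
(Sobol-type) global analysis is attempted, and results are
scenario-specific because the fate vector determines which parameters
matter at all.

## Economics

Costs scale with area (operating, amortized capital, nursery,
insurance, maintenance trips — zone-resolved), with harvested biomass
(harvest, transport, port fees, sinking transport) and with
fate-resolved biomass (per-product processing); product value is
`Σ fate_p · B_H · yield_p · price_p`. The cost per Tg CO₂e is computed
run by run on paired draws and then summarized — not as a ratio of
medians, which differs materially on these skewed, anti-correlated
distributions (the package asserts this in its test suite). Runs in
which the scenario is a net emitter contribute negative ratios to the
summary rather than being dropped: dropping them would bias the median
of the remaining ratios upward, and with them included the per-run
summaries are internally consistent with the reported cost-per-benefit
figures for every scenario with positive median benefit. A scenario
whose *median* benefit is non-positive (the no-harvest scenario) has no
meaningful price per unit of benefit and reports `NA`.

## Problem sizes

The package's own regression suite runs each scenario at 10,000 Monte
Carlo draws (matching the study design), sensitivity checks at
1,000–20,000 draws, and distributional property checks at 10⁵–10⁶
draws; the full suite and the acceptance script each complete in a few
seconds because the ledger is closed-form and fully vectorised over
draws.

## Known limitations

* Placeholder distributions are calibrated, not measured; parameter-level
  conclusions (e.g. "biofuel replacement avoids 5.1 kg CO₂e per kg
  product") should not be read off the fixture.
* Independence between parameters is almost certainly optimistic for
  the economics (prices and replacement factors respond to the same
  markets).
* The model is linear in area: no saturation of markets, nutrients or
  suitable sites, so large-area scenarios extrapolate aggressively.
* Marine sequestration fractions are scalars; there is no
  depth-resolved export, remineralisation profile or ocean-circulation
  model behind them.
* The GIS suitability analysis that produced the scenario areas is out
  of scope; areas are consumed as inputs.
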