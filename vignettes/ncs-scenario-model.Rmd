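---
title: "Modelling county-level natural climate solutions scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling county-level natural climate solutions scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ncspath)
```

## The model

`ncspath` estimates how much natural climate solutions (NCS) — changed land
management, avoided land conversion, and ecosystem restoration — could reduce
a state's net greenhouse-gas emissions, county by county, over a 31-year
horizon (simulation year 1 = calendar 2020, year 31 = 2050). Eight reporting
pathways are tracked; three decompose further: extended timber harvest
rotations split by forest ownership (private, state, federal, other, plus an
added-sequestration activity on deferred private even-aged stands), cropland
agriculture combines cover crops, no-till and nutrient management, and
avoided forest conversion combines forest-to-urban and forest-to-rural.

Each (county, activity) starts from a **baseline annual rate** `B` of the
activity (hectares restored per year, harvest volume per year, kg N per
year). For activities observed as annual time series (timber harvest
2003–2017; post-wildfire replanting) the **historical coefficient of
variation** `CV = s/mean` (sample, n−1, standard deviation) is computed from
the series; all other activities use a conservative default `CV = 0.10`.
**Historical variation** is `HV = B × CV`, capped at `B` when `CV > 1` so
implementation can never be scaled from more variation than the activity
provides. The cap rule is read as a condition on the dimensionless CV; a
literal comparison of a CV against an activity amount is dimensionally
incoherent.

### Scenarios

Three rule sets — Limited, Moderate, Ambitious — govern how fast new activity
enrolls, always relative to HV (additionality: each year's activity is the
prior year's plus new implementation). The pre-cap enrollment increment in
year `t` is

```
t in 1..10:   min(t × ramp_fraction, 1) × growth_share × HV
t in 11..31:  post_decade_share × growth_share × HV
```

with `ramp_fraction = 0.1` throughout, so growth reaches 100% of the allowed
growth (`growth_share × HV`) at year 10. Cumulative enrollment is truncated
at `cap_fraction × max_resource`, the enrollable share of the implementable
resource stock; capping acts on enrollment and the capping-year increment is
back-adjusted so `enrolled[t] = enrolled[t−1] + increment[t]` holds exactly.
The uncapped Limited-general closed form is `enrolled[31] = 26.5 × HV`
(ramp sum 5.5 plus 21 post-decade years).

Registry defaults (`scenario_defaults()`, all overridable from
`scenario_params.csv`):

| parameter | value | where |
|---|---|---|
| growth_share | 1.0 | Limited and Ambitious, all activities |
| growth_share | 0.30 / 0.15 / 0.75 | Moderate timber: private / state / federal & other |
| growth_share | 0.5 | Moderate, non-timber |
| post_decade_share | 0.5 | Limited timber (stabilizes at half of HV) |
| post_decade_share | 1.0 | elsewhere (hold at the year-10 increment) |
| cap_fraction | 0.40 / 0.32 / 1.0 | Ambitious timber: private / state / others |
| cap_fraction | 1.0 | elsewhere |

Two of these are design choices rather than published facts. The Moderate
non-timber growth share of 0.5 is a configurable midpoint: the authoritative
per-pathway Moderate/Ambitious growth coefficients live in supplementary
material not reproduced here, so the registry encodes only the main-text
rules and treats everything as overridable. A consequence of bounding
`growth_share` at 1 is that Limited and Ambitious coincide for non-timber
activities under the defaults; scenario spread on those pathways comes from
user-supplied overrides. Because Limited timber holds at half of HV while
Moderate timber grows at 15–75% of HV, the Limited scenario can out-reduce
the Moderate one — a genuine property of the rule set, not a bug.

Pathway-specific baseline derivations: tidal-wetland restoration in Puget
Sound counties without mapped activity uses `lost_ha × 0.00215` (the
proportion of the statewide lost wetland area restored annually in Puget
Sound during the baseline period), capped at the county's lost area;
grassland-conversion rates allocate a statewide rate proportionally to
county grassland shares (conserving the statewide total exactly); nutrient
management is capped at 40% of cropland; counties with more than half of
forestland at high/extreme wildfire risk are excluded from the timber
pathway entirely.

### Flux accounting

Enrolled activity converts to CO₂e flux through signed per-unit rates
(MT CO₂e unit⁻¹ yr⁻¹; negative = removal or avoided emission; internal math
never takes absolute values). The timber net rate is the signed sum of five
components per unit of deferred harvest volume — harvest volume, below-ground
biomass, unused mill residues, commercial fuel, short-lived (≤ 20-yr)
products — kept separate for wet (west) and dry (east) forests and supplied
as data, not constants. Three accrual modes:

* **stock** (default): `flux[t] = enrolled[t] × rate` — management and
  restoration benefits persist on everything enrolled;
* **pulse**: `flux[t] = increment[t] × rate` — committed avoided emissions
  counted once, in the enrollment year;
* **cohort**: activities whose rate depends on stand age (post-wildfire
  replanting, added sequestration on deferred stands) convolve enrollment
  increments with a step-function age profile,
  `flux[t] = Σ_s increment[s] × rate(t − s + 1)`, the terminal profile value
  extending to older ages. Profiles are step functions (growth tables are
  published per period); no interpolation.

Avoided-conversion pathways default to stock mode — their published
reductions grow smoothly to 2050, which pulse accounting cannot produce —
but pulse mode is available per activity via `flux_mode`. Fluxes are
computed in MT and converted to MMT (÷ 10⁶) exactly once, at summary time.

### Monte Carlo design

Rate uncertainty (standard deviation per rate) is the only stochastic input;
baselines and trajectories are deterministic and computed once. Each of the
1,000 iterations draws one rate per (activity key, region) from
`Normal(mean, sd)` — untruncated, since truncation would bias the mean;
sign-flipped draws are counted and retained. Draws are held fixed across
years and across counties sharing a rate within an iteration: the
uncertainty is epistemic (what is the rate?), not interannual weather.
Summaries take the median and the 5th/95th percentiles **after** summing
fluxes over the requested grouping within each iteration, so a total's
interval reflects the joint distribution — the median of a total is not the
sum of pathway medians, and totals are never formed by adding summary rows.
Quantiles interpolate linearly between order statistics (`stats::quantile`
type 7). `p05`/`p95` are percentiles of the signed flux; for reductions
(negative values) `p05` is therefore the most negative bound. A master seed
spawns one substream per (scenario, iteration), so runs are bitwise
reproducible and any iteration can be regenerated in isolation.

## The synthetic generator and what passing tests show

No public accession carries the study's input tables, so
`synth_bundle()`/`generate_bundle()` emulate their structure with known
ground truth: 39 counties on the odd-number ID scheme, a west/east split at
the crest, 2003–2017 annual series for timber (per ownership) and
replanting, wildfire-excluded counties, a ~47,000 ha statewide lost
tidal-wetland stock allocated across western counties, and per-unit rates of
realistic sign and magnitude. Annual series are built constructively — a
centred unit-variance template scaled to `mean × CV` — so the sample mean
and CV equal their targets to machine precision and CV recovery is testable
exactly, rather than statistically. Baseline magnitudes are drawn once from
plausible ranges chosen so the statewide Ambitious total lands in the
single-digit-MMT range, keeping MT-vs-MMT magnitude errors visible. The
timber `max_resource` is set to 30 × the baseline annual volume: the
deferrable resource of a 45 → 75-year rotation shift is the standing stock
eligible for deferral, not a single year's cut (with `max_resource` equal to
one year's harvest every scenario saturates its cap almost immediately,
which no published trajectory shows).

The generator reproduces structure, not geography: it does not model spatial
autocorrelation between neighbouring counties, correlated rates across
pathways, trends or autocorrelation within the annual series, or any real
county's values. Green tests therefore demonstrate that the arithmetic
machinery — CV → HV → trajectory → flux → quantile summary — is correct and
reproducible, not that the package reproduces the published state-level
numbers; reproducing those requires transcribing the study's own input
tables into the documented schema (see `inst/extdata/` data dictionary).

The closed-form oracle (`analytic_oracle()`) covers flat-profile, stock-mode
activities: expected final enrollment is
`min((5.5 + 21 × post_decade_share) × growth_share × HV, cap_fraction ×
max_resource)` and expected flux is enrollment × mean rate. Cohort
activities are checked against a brute-force per-cohort sum instead. With
`sd = 0` the full pipeline matches the oracle to ≤ 10⁻⁹ relative error; with
`sd > 0`, pipeline medians fall within 3 Monte Carlo standard errors
(1.2533 σ/√n for a Normal median) of the analytic values in ≥ 95% of
randomized cases.

## Numerical choices and degenerate inputs

* Missing `max_resource` means unlimited (no cap).
* `HV = 0` (constant series) produces an identically zero trajectory and
  zero flux under every scenario.
* A series shorter than 2 years cannot yield a CV and falls back to the 10%
  default, flagged by `provenance = "default_10pct"`.
* Rate resolution falls back county-region → statewide, never interpolating;
  a baseline whose units differ from its resolved rate's units is rejected
  at load (no silent ha × per-volume products).
* County clusters sort by |median| descending with ties broken by county id
  ascending, and take the smallest prefix reaching the coverage fraction;
  the output is invariant to input order.
* Census disaggregation allocates the statewide residual proportionally to
  the missing counties' other-year values, splitting uniformly (with a
  logged message) when those are all zero.
* Display rounding: goal percentages to 1 decimal, pathway shares to whole
  percent, medians to 2 decimals in rendered tables; unrounded values are
  always retained in machine outputs.

## Problem sizes

The analysis scripts and the acceptance script run the full preset — 39
counties, ~500 activity series, 1,000 iterations per scenario (a few seconds
per scenario on one CPU). Unit and property tests use 4–10-county bundles,
which exercise every pathway and both regions; the parameter-recovery check
uses 20 randomized 4-county bundles at 1,000 iterations each.

## Known limitations

* No leakage, price feedback, or economic feasibility modelling; scenario
  rules are purely biophysical-administrative.
* No uncertainty on baseline activity or trajectory parameters — only rates
  carry standard deviations, so intervals understate total uncertainty.
* Rates are drawn independently across activities; correlated errors (e.g.
  shared growth-model biases across timber activities) would widen total
  intervals.
* Whether avoided-conversion benefits are a stock or a pulse is a documented
  default, not an established fact; both modes ship.
* The stock accrual for stand-replacing pathways is a linearization; it does
  not model saturation of per-hectare sequestration as stands mature except
  through explicit age profiles.
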