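# ncspath

County-level scenario modelling of Natural Climate Solutions (NCS):
how much can changed land management, avoided land conversion and ecosystem
restoration reduce a state's net greenhouse-gas emissions by 2050, and in
which counties?

The package is written for land-carbon analysts and state/regional climate
planners. It implements the full chain from raw activity tables to
uncertainty-quantified reduction estimates for eight NCS pathways (extended
timber harvest rotations by ownership, cropland agriculture with cover-crop,
no-till and nutrient-management sub-activities, avoided forest / sagebrush /
grassland conversion, riparian and tidal-wetland restoration, post-wildfire
replanting), reported per county, pathway, scenario and year.

## The model

For each (county, activity), a baseline annual rate *B* and its historical
coefficient of variation (sample CV from 2003–2017 series where available,
0.10 by default) give the **historical variation** *HV = B · CV* (capped at
*B*). Three rule-based scenarios (Limited, Moderate, Ambitious) enroll new
activity each year relative to *HV*:

    increment(t) = min(t/10, 1) · g · HV          t = 1..10
    increment(t) = p · g · HV                     t = 11..31
    enrolled(t)  = min( Σ_{s≤t} increment(s),  c · max_resource )

with growth share *g*, post-decade share *p* and cap fraction *c* per
(scenario, activity) — e.g. Ambitious timber caps enrollment at 40% of the
private and 32% of the state deferrable resource; Limited timber holds at
half of *HV* after year 10. Enrolled activity converts to CO₂e flux through
signed per-unit rates (negative = reduction), either on the whole enrolled
stock, on the year's new enrollment only (pulse), or through per-age rate
profiles for cohort pathways; the timber rate is the signed sum of five
components (harvest volume, below-ground biomass, mill residues, commercial
fuel, short-lived products), separately west and east of the Cascade crest.
Rate uncertainty is propagated by 1,000-iteration Monte Carlo (one
Normal(mean, sd) draw per rate per iteration, held across years), and
summaries report the median and 5th/95th percentiles of per-iteration
grouped sums — totals are aggregated per iteration, never by summing
pathway summaries.

See `vignettes/ncs-scenario-model.Rmd` for assumptions, parameter defaults
and limitations.

## Worked example

Inputs are CSV tables (schemas in `inst/extdata/data_dictionary.csv`); the
built-in generator produces a complete synthetic bundle with known ground
truth:

```r
library(ncspath)

sb   <- synth_bundle(synth_config(), seed = 42)   # 39 synthetic counties
cube <- run_simulation(sb$bundle, "ambitious", n_iter = 1000, seed = 42)
tot  <- summarize_iterations(cube)                # statewide total, MMT CO2e/yr
subset(tot, year == 31)
#>  geography pathway  scenario year    median       p05       p95
#>  statewide   total ambitious   31 -6.125047 -6.344833 -5.901346

percent_of_goal(tot$median[tot$year == 31], goal_context())$display
#> 6.2
```

The final-year statewide total under the Ambitious scenario on this
synthetic bundle is −6.13 MMT CO₂e yr⁻¹ (5th–95th percentile −6.34 to
−5.90), i.e. 6.2% of the 99.57 MMT CO₂e statewide 2018 emissions baseline.
Pathway shares of that total (per-pathway median ÷ total median):

```r
byp <- summarize_iterations(cube, by = "pathway")
pathway_shares(rbind(subset(byp, year == 31)[, c("pathway", "median")],
                     data.frame(pathway = "total",
                                median = tot$median[tot$year == 31])))
#>              pathway    share display
#>               timber 72.95275      73
#>  wildfire_replanting 12.25542      12
#>          agriculture 10.08508      10
#>  ...
```

The numbered scripts under `analysis/` run the same chain as a narrative
workflow — `01_generate_inputs.R` → `06_published_arithmetic.R` — writing
inputs, derived baselines, trajectory summaries, Monte Carlo results and the
tabular reports under `results/`.

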