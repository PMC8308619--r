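#!/usr/bin/env Rscript
# Step 6: derived arithmetic from the published results table.
#
# Independently of any model run, recomputes the headline percentages from
# the published final-year medians: percent of the 99.57 MMT CO2e statewide
# emissions baseline covered by each scenario's total, and each pathway's
# share of the Ambitious total. Writes results/published_arithmetic.csv.

suppressMessages({
  library(ncspath)
  library(dplyr)
})

tab <- published_table2()
ctx <- goal_context()

totals <- tab |> filter(pathway == "total")
pct <- totals |>
  mutate(
    percent_of_goal = sapply(median, function(m) percent_of_goal(m, ctx)$display)
  ) |>
  select(scenario, median, percent_of_goal)
cat("percent of the statewide emissions baseline, by scenario:\n")
print(as.data.frame(pct), row.names = FALSE)

amb <- tab |> filter(scenario == "ambitious", !is.na(median))
shares <- pathway_shares(amb[, c("pathway", "median")])
cat("\npathway shares of the Ambitious total (final year):\n")
print(as.data.frame(shares), row.names = FALSE)

readr::write_csv(
  bind_rows(
    pct |> mutate(kind = "percent_of_goal", pathway = "total") |>
      rename(value = percent_of_goal) |> select(kind, scenario, pathway, value),
    shares |> mutate(kind = "pathway_share", scenario = "ambitious") |>
      rename(value = display) |> select(kind, scenario, pathway, value)
  ),
  "results/published_arithmetic.csv",
  progress = FALSE
)
cat("\nwrote results/published_arithmetic.csv\n")
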