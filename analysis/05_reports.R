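#!/usr/bin/env Rscript
# Step 5: headline reports.
#
# Re-aggregates the saved iteration cubes into the tabular report set
# (pathway x scenario table, county totals with and without timber, pathway
# by county, shares, clusters, per-area intensity) under results/reports/,
# and prints the percent-of-goal arithmetic for the synthetic run.

suppressMessages({
  library(ncspath)
  library(dplyr)
})

ind <- "results/inputs"
counties <- readr::read_csv(file.path(ind, "counties.csv"), show_col_types = FALSE)
cubes <- readRDS("scratch/iteration_cubes.rds")

paths <- render_reports(cubes, counties, outdir = "results/reports")
cat("wrote report files:\n")
for (p in paths) cat(" -", p, "\n")

ctx <- goal_context()
for (scen in names(cubes)) {
  tot <- summarize_iterations(cubes[[scen]])
  t31 <- tot$median[tot$year == 31]
  cat(sprintf(
    "%-9s total %.2f MMT CO2e/yr = %.1f%% of the %.2f MMT statewide baseline\n",
    scen, t31, percent_of_goal(t31, ctx)$display, ctx$statewide_emissions_baseline
  ))
}
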