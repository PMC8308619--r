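#' Closed registry of NCS activities
#'
#' The model tracks eight reporting pathways. Three of them decompose into
#' sub-activities: extended timber harvest rotations splits by forest
#' ownership (private, state, federal, other) plus an added-sequestration
#' activity on deferred private even-aged stands; cropland agriculture
#' combines cover crops, no-till and nutrient management; avoided forest
#' conversion combines forest-to-urban and forest-to-rural. The remaining
#' pathways are single activities. Every baseline, rate and scenario-parameter
#' row must use one of these (pathway, sub_activity, ownership) combinations;
#' anything else is rejected at load.
#'
#' @return A tibble with columns `pathway`, `sub_activity`, `ownership`,
#'   `units` (the activity unit each rate must be expressed per) and
#'   `cohort` (whether the activity accrues flux through an age profile).
#' @export
activity_registry <- function() {
  tibble::tribble(
    ~pathway, ~sub_activity, ~ownership, ~units, ~cohort,
    "timber", "harvest", "private", "volume_per_yr", FALSE,
    "timber", "harvest", "state", "volume_per_yr", FALSE,
    "timber", "harvest", "federal", "volume_per_yr", FALSE,
    "timber", "harvest", "other", "volume_per_yr", FALSE,
    "timber", "added_sequestration", "private", "ha_per_yr", TRUE,
    "agriculture", "cover_crops", "na", "ha_per_yr", FALSE,
    "agriculture", "no_till", "na", "ha_per_yr", FALSE,
    "agriculture", "nutrient_mgmt", "na", "kgN_per_yr", FALSE,
    "avoided_forest_conversion", "forest_to_urban", "na", "ha_per_yr", FALSE,
    "avoided_forest_conversion", "forest_to_rural", "na", "ha_per_yr", FALSE,
    "avoided_sagebrush_conversion", "", "na", "ha_per_yr", FALSE,
    "avoided_grassland_conversion", "", "na", "ha_per_yr", FALSE,
    "riparian_reforestation", "", "na", "ha_per_yr", FALSE,
    "wildfire_replanting", "", "federal", "ha_per_yr", TRUE,
    "tidal_wetland_restoration", "", "na", "ha_per_yr", FALSE
  )
}

#' Pathway names in the registry
#' @return Character vector of the eight reporting pathway labels.
#' @export
ncs_pathways <- function() unique(activity_registry()$pathway)

#' Scenario labels
#' @return `c("limited", "moderate", "ambitious")`.
#' @export
ncs_scenarios <- function() c("limited", "moderate", "ambitious")

#' Simulation horizon in years (year 1 = calendar 2020, year 31 = 2050)
#' @export
ncs_n_years <- function() 31L

# Internal: composite key string used for joins and error messages.
key_id <- function(pathway, sub_activity, ownership) {
  paste(pathway, sub_activity, ownership, sep = "|")
}

# Internal: validate that (pathway, sub_activity, ownership) rows are all in
# the closed registry; abort naming the offenders otherwise.
assert_registered <- function(df, context) {
  reg <- activity_registry()
  ids <- key_id(df$pathway, df$sub_activity, df$ownership)
  known <- key_id(reg$pathway, reg$sub_activity, reg$ownership)
  bad <- unique(ids[!ids %in% known])
  if (length(bad) > 0) {
    stop(
      sprintf(
        "%s: activity keys not in the closed registry: %s",
        context, paste(bad, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(df)
}
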