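# In-code fixtures: a minimal hand-built bundle and a raw iteration cube.

# Two-county bundle with one single-rate pathway (riparian) and one
# annual-series timber activity; valid against the registry and schemas.
make_toy_bundle <- function(riparian_rate = 100, riparian_sd = 0,
                            timber_series = c(900, 1000, 1100),
                            rate_region = "west") {
  counties <- tibble::tibble(
    county_id = c(1L, 3L),
    name = c("toy_a", "toy_b"),
    region = c("west", "east"),
    area_ha = c(5e5, 4e5),
    timber_excluded = c(FALSE, FALSE)
  )
  baselines <- dplyr::bind_rows(
    tibble::tibble(
      county_id = 1L, pathway = "riparian_reforestation", sub_activity = "",
      ownership = "na", year = NA_integer_, amount = riparian_rate,
      units = "ha_per_yr", max_resource = NA_real_
    ),
    tibble::tibble(
      county_id = 1L, pathway = "timber", sub_activity = "harvest",
      ownership = "private", year = seq(2003L, by = 1L, length.out = length(timber_series)),
      amount = timber_series, units = "volume_per_yr",
      max_resource = mean(timber_series)
    )
  )
  rates <- tibble::tibble(
    pathway = c("riparian_reforestation", "timber"),
    sub_activity = c("", "harvest"),
    ownership = c("na", "private"),
    region = c("statewide", rate_region),
    mean_rate = c(-6, -0.7),
    sd_rate = c(riparian_sd, 0),
    units = c("ha_per_yr", "volume_per_yr"),
    age_profile = NA_character_
  )
  list(
    counties = counties, baselines = baselines, rates = rates,
    scenario_params = ncspath::scenario_defaults(),
    age_profiles = tibble::tibble(
      profile_id = character(), age = integer(), multiplier = double()
    )
  )
}

write_bundle_csvs <- function(bundle, dir) {
  paths <- list(
    counties = file.path(dir, "counties.csv"),
    baselines = file.path(dir, "baselines.csv"),
    rates = file.path(dir, "rates.csv"),
    scenario_params = file.path(dir, "scenario_params.csv"),
    age_profiles = file.path(dir, "age_profiles.csv")
  )
  readr::write_csv(bundle$counties, paths$counties, progress = FALSE)
  readr::write_csv(bundle$baselines, paths$baselines, progress = FALSE)
  readr::write_csv(bundle$rates, paths$rates, progress = FALSE)
  readr::write_csv(bundle$scenario_params, paths$scenario_params, progress = FALSE)
  readr::write_csv(bundle$age_profiles, paths$age_profiles, progress = FALSE)
  paths
}

# Hand-built iteration cube: values is an n_iter x n_series x n_years array,
# series a tibble of key columns.
make_cube <- function(values, series, scenario = "ambitious", seed = 1) {
  structure(
    list(
      values = values, series = series, n_iter = dim(values)[1],
      n_years = dim(values)[3], seed = seed, scenario = scenario,
      n_sign_flips = 0L, deterministic = NULL
    ),
    class = "iteration_cube"
  )
}

# Scenario-parameter row as a plain list (annual_increment/build_trajectory).
param_row <- function(ramp_fraction = 0.1, growth_share = 1,
                      post_decade_share = 1, cap_fraction = 1) {
  list(
    ramp_fraction = ramp_fraction, growth_share = growth_share,
    post_decade_share = post_decade_share, cap_fraction = cap_fraction
  )
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  rel <- abs(actual - expected) / pmax(abs(expected), 1e-12)
  expect_lt(max(rel), tol)
}
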