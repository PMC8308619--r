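#' @importFrom rlang .data
NULL

# Required columns per input file. CSV dialect throughout: UTF-8, comma
# delimited, "." decimal, no thousands separators (readr defaults).
input_schemas <- function() {
  list(
    counties = c("county_id", "name", "region", "area_ha", "timber_excluded"),
    baselines = c(
      "county_id", "pathway", "sub_activity", "ownership",
      "year", "amount", "units", "max_resource"
    ),
    rates = c(
      "pathway", "sub_activity", "ownership", "region",
      "mean_rate", "sd_rate", "units", "age_profile"
    ),
    scenario_params = c(
      "scenario", "pathway", "sub_activity", "ownership",
      "ramp_fraction", "growth_share", "post_decade_share",
      "cap_fraction", "flux_mode"
    ),
    age_profiles = c("profile_id", "age", "multiplier")
  )
}

read_csv_checked <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- input_schemas()[[what]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(
      sprintf(
        "schema error in %s: missing column(s) %s",
        what, paste(missing, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  df
}

normalise_key_cols <- function(df) {
  df$sub_activity <- ifelse(is.na(df$sub_activity), "", as.character(df$sub_activity))
  df$ownership <- ifelse(is.na(df$ownership), "na", as.character(df$ownership))
  df
}

#' Read and validate a complete input bundle
#'
#' Loads the four core tables (plus the optional age-profile table), checks
#' each against its documented schema, verifies the closed activity registry,
#' and enforces referential closure: every baseline activity key must resolve
#' to a flux rate (by the county's side of the Cascade crest, falling back to
#' a statewide rate) and to scenario parameters for all three scenarios
#' (CSV rows override the built-in registry defaults).
#'
#' @param counties_path,baselines_path,rates_path,scenarios_path CSV paths.
#' @param age_profiles_path Optional CSV of (profile_id, age, multiplier)
#'   step-function age profiles for cohort activities.
#' @param quiet Suppress the row-count log messages.
#' @return A validated bundle: a list with tibbles `counties`, `baselines`,
#'   `rates`, `scenario_params`, `age_profiles`.
#' @export
read_inputs <- function(counties_path, baselines_path, rates_path,
                        scenarios_path, age_profiles_path = NULL,
                        quiet = FALSE) {
  counties <- read_csv_checked(counties_path, "counties")
  baselines <- normalise_key_cols(read_csv_checked(baselines_path, "baselines"))
  rates <- normalise_key_cols(read_csv_checked(rates_path, "rates"))
  scen <- normalise_key_cols(read_csv_checked(scenarios_path, "scenario_params"))
  profiles <- if (!is.null(age_profiles_path)) {
    read_csv_checked(age_profiles_path, "age_profiles")
  } else {
    tibble::tibble(profile_id = character(), age = integer(), multiplier = double())
  }
  bundle <- list(
    counties = counties, baselines = baselines, rates = rates,
    scenario_params = scen, age_profiles = profiles
  )
  validate_bundle(bundle)
  if (!quiet) {
    message(sprintf(
      "read_inputs: %d counties, %d baseline rows, %d rate rows, %d scenario-parameter rows, %d age-profile rows",
      nrow(counties), nrow(baselines), nrow(rates), nrow(scen), nrow(profiles)
    ))
  }
  bundle
}

#' Validate an in-memory input bundle
#'
#' Applies the same checks as [read_inputs()] to a bundle constructed in
#' code: schema columns, county invariants, registry closure, non-negative
#' activity amounts, strictly increasing series years, rate resolvability
#' with statewide fallback, and scenario-parameter closure.
#'
#' @param bundle List with `counties`, `baselines`, `rates`,
#'   `scenario_params`, `age_profiles` tibbles.
#' @return The bundle, invisibly; aborts with a descriptive error otherwise.
#' @export
validate_bundle <- function(bundle) {
  counties <- bundle$counties
  if (anyDuplicated(counties$county_id)) {
    stop("validation error: duplicate county_id", call. = FALSE)
  }
  if (!all(counties$region %in% c("west", "east"))) {
    stop("validation error: county region must be 'west' or 'east'", call. = FALSE)
  }
  if (any(counties$area_ha <= 0)) {
    stop("validation error: county area_ha must be > 0", call. = FALSE)
  }

  baselines <- bundle$baselines
  assert_registered(baselines, "baselines")
  assert_registered(bundle$rates, "rates")
  assert_registered(bundle$scenario_params, "scenario_params")
  if (any(baselines$amount < 0, na.rm = TRUE)) {
    stop("validation error: negative baseline activity amount", call. = FALSE)
  }
  if (any(baselines$max_resource < 0, na.rm = TRUE)) {
    stop("validation error: negative max_resource", call. = FALSE)
  }
  if (!all(baselines$county_id %in% counties$county_id)) {
    stop("validation error: baseline county_id not in county table", call. = FALSE)
  }
  series_ok <- baselines |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::group_by(.data$county_id, .data$pathway, .data$sub_activity, .data$ownership) |>
    dplyr::summarise(ok = !is.unsorted(.data$year, strictly = TRUE), .groups = "drop")
  if (!all(series_ok$ok)) {
    stop("validation error: baseline series years must be strictly increasing", call. = FALSE)
  }

  rates <- bundle$rates
  if (any(rates$sd_rate < 0)) {
    stop("validation error: sd_rate must be >= 0", call. = FALSE)
  }
  # referential closure: each baseline key resolves to a rate for its
  # county's region, or to a statewide rate
  resolved <- resolve_rates(baselines, counties, rates)
  unresolved <- resolved |>
    dplyr::filter(is.na(.data$mean_rate)) |>
    dplyr::distinct(.data$pathway, .data$sub_activity, .data$ownership, .data$region)
  if (nrow(unresolved) > 0) {
    stop(
      sprintf(
        "unresolved-key error: no rate (regional or statewide) for: %s",
        paste(key_id(unresolved$pathway, unresolved$sub_activity, unresolved$ownership),
          unresolved$region,
          sep = "@", collapse = ", "
        )
      ),
      call. = FALSE
    )
  }
  # units of a baseline must match the units of the rate it resolves to
  mism <- resolved |>
    dplyr::filter(.data$units != .data$rate_units)
  if (nrow(mism) > 0) {
    stop(
      sprintf(
        "unit mismatch between baseline and rate for: %s",
        paste(unique(key_id(mism$pathway, mism$sub_activity, mism$ownership)), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  # cohort activities need their referenced age profile
  need_prof <- rates$age_profile[!is.na(rates$age_profile)]
  missing_prof <- setdiff(need_prof, bundle$age_profiles$profile_id)
  if (length(missing_prof) > 0) {
    stop(
      sprintf("missing age profile(s): %s", paste(missing_prof, collapse = ", ")),
      call. = FALSE
    )
  }
  if (nrow(bundle$age_profiles) > 0) {
    prof_ok <- bundle$age_profiles |>
      dplyr::group_by(.data$profile_id) |>
      dplyr::summarise(
        ok = .data$age[1] == 1 && !is.unsorted(.data$age, strictly = TRUE),
        .groups = "drop"
      )
    if (!all(prof_ok$ok)) {
      stop("validation error: age profile ages must start at 1 and increase strictly", call. = FALSE)
    }
  }
  # scenario parameters: overrides must be registered and well-formed; the
  # built-in registry guarantees closure for all three scenarios
  sp <- bundle$scenario_params
  if (nrow(sp) > 0) {
    if (!all(sp$scenario %in% ncs_scenarios())) {
      stop("validation error: unknown scenario label in scenario_params", call. = FALSE)
    }
    with(sp, {
      if (any(ramp_fraction <= 0 | ramp_fraction > 1) ||
        any(growth_share < 0 | growth_share > 1) ||
        any(post_decade_share < 0 | post_decade_share > 1) ||
        any(cap_fraction < 0 | cap_fraction > 1)) {
        stop("validation error: scenario parameter out of [0, 1] bounds", call. = FALSE)
      }
      if (!all(flux_mode %in% c("stock", "pulse"))) {
        stop("validation error: flux_mode must be 'stock' or 'pulse'", call. = FALSE)
      }
    })
  }
  invisible(bundle)
}

# Join each baseline key to its rate using region fallback:
# county region first, else statewide. No interpolation.
resolve_rates <- function(baselines, counties, rates) {
  keys <- baselines |>
    dplyr::distinct(.data$county_id, .data$pathway, .data$sub_activity, .data$ownership, .data$units) |>
    dplyr::left_join(counties |> dplyr::select("county_id", "region"), by = "county_id")
  regional <- keys |>
    dplyr::left_join(
      rates |>
        dplyr::select("pathway", "sub_activity", "ownership", "region",
          "mean_rate", "sd_rate", rate_units = "units", "age_profile"
        ),
      by = c("pathway", "sub_activity", "ownership", "region")
    )
  statewide <- rates |>
    dplyr::filter(.data$region == "statewide") |>
    dplyr::select("pathway", "sub_activity", "ownership",
      sw_mean = "mean_rate", sw_sd = "sd_rate",
      sw_units = "units", sw_profile = "age_profile"
    )
  out <- regional |>
    dplyr::left_join(statewide, by = c("pathway", "sub_activity", "ownership")) |>
    dplyr::mutate(
      rate_region = dplyr::if_else(is.na(.data$mean_rate) & !is.na(.data$sw_mean),
        "statewide", .data$region
      ),
      age_profile = dplyr::if_else(is.na(.data$mean_rate), .data$sw_profile, .data$age_profile),
      rate_units = dplyr::if_else(is.na(.data$mean_rate), .data$sw_units, .data$rate_units),
      sd_rate = dplyr::if_else(is.na(.data$mean_rate), .data$sw_sd, .data$sd_rate),
      mean_rate = dplyr::if_else(is.na(.data$mean_rate), .data$sw_mean, .data$mean_rate)
    ) |>
    dplyr::select(-"sw_mean", -"sw_sd", -"sw_units", -"sw_profile")
  out
}

result_columns <- function() {
  c(
    "geography", "pathway", "sub_activity", "scenario", "year",
    "median", "p05", "p95", "cumulative_median"
  )
}

#' Write result records to CSV
#'
#' One row per (geography, pathway, sub_activity, scenario, year), in that
#' canonical sort order. Values are MMT CO2e per year, signed (negative =
#' emissions reduction); `p05` is the least-negative interval bound and
#' `p95` the most negative one, i.e. the 5th and 95th percentiles of the
#' reduction magnitude.
#'
#' @param records Tibble with the [result_columns()] layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  cols <- result_columns()
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop(
      sprintf("write_results: missing column(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  out <- records |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(
      .data$geography, .data$pathway, .data$sub_activity,
      .data$scenario, .data$year
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read result records written by [write_results()]
#' @param path CSV path.
#' @return Tibble in the canonical result layout.
#' @export
read_results <- function(path) {
  df <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      geography = readr::col_character(),
      pathway = readr::col_character(),
      sub_activity = readr::col_character(),
      scenario = readr::col_character(),
      year = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  df$sub_activity[is.na(df$sub_activity)] <- ""
  missing <- setdiff(result_columns(), names(df))
  if (length(missing) > 0) {
    stop(
      sprintf("read_results: missing column(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  df
}
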