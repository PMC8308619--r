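#' Configuration for the synthetic input-bundle generator
#'
#' The generator emulates the structure of the real study inputs: 39
#' counties split by the Cascade crest, county IDs on the odd-number scheme
#' (2i - 1 for the i-th county), timber harvest and post-wildfire replanting
#' as 2003-2017 annual series with county-specific CVs, single annual rates
#' elsewhere, a statewide lost-tidal-wetland stock near 47,000 ha, and
#' per-unit flux rates of plausible magnitude so statewide Ambitious totals
#' land in the single-digit-MMT range (magnitude bugs stay visible). It does
#' not attempt to reproduce any real county's values.
#'
#' @param n_counties Number of counties (default 39).
#' @param n_west Counties west of the crest (default 19).
#' @param n_timber_excluded High/extreme wildfire-risk counties excluded from
#'   the timber pathway (taken from the east side).
#' @param sd_frac Rate standard deviation as a fraction of |mean rate|.
#' @param cv_range Range the per-series target CVs are drawn from.
#' @param series_years Calendar years of the annual activity series.
#' @param lost_tidal_total_ha Statewide lost tidal wetland area.
#' @param grassland_statewide_rate Statewide grassland-conversion rate, ha/yr.
#' @param scale Multiplier on all baseline activity magnitudes (for small
#'   test fixtures).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_counties = 39, n_west = 19, n_timber_excluded = 4,
                         sd_frac = 0.05, cv_range = c(0.1, 0.5),
                         series_years = 2003:2017,
                         lost_tidal_total_ha = 47000,
                         grassland_statewide_rate = 1270,
                         scale = 1) {
  if (n_counties < 2 || n_west < 1 || n_west >= n_counties) {
    stop("invalid config: need >= 2 counties with at least one on each side", call. = FALSE)
  }
  if (sd_frac < 0 || any(cv_range < 0) || scale <= 0) {
    stop("invalid config: negative noise or scale", call. = FALSE)
  }
  structure(
    list(
      n_counties = n_counties, n_west = n_west,
      n_timber_excluded = min(n_timber_excluded, n_counties - n_west),
      sd_frac = sd_frac, cv_range = cv_range, series_years = series_years,
      lost_tidal_total_ha = lost_tidal_total_ha,
      grassland_statewide_rate = grassland_statewide_rate,
      scale = scale
    ),
    class = "synth_config"
  )
}

#' Construct an annual series with exact sample mean and CV
#'
#' Deterministic construction (no sampling noise): a centered, unit-sample-sd
#' template ramp is scaled to `mean * target_cv` and added to the mean, then
#' shuffled with the seeded RNG (sample mean and sd are order-invariant).
#' Guarantees `mean(x) == mean` and `sd(x)/mean(x) == target_cv` to machine
#' precision, with all values >= 0.
#'
#' @param mean Target sample mean, > 0.
#' @param target_cv Target sample CV, >= 0.
#' @param n_years Series length, >= 2.
#' @param seed Integer seed (order shuffling only).
#' @return Numeric vector of length `n_years`.
#' @export
generate_series <- function(mean, target_cv, n_years, seed = 1) {
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (target_cv < 0) stop("target_cv must be >= 0", call. = FALSE)
  if (n_years < 2) stop("need n_years >= 2", call. = FALSE)
  template <- seq_len(n_years) - (n_years + 1) / 2
  z <- template / stats::sd(template)
  if (target_cv * max(abs(z)) > 1) {
    stop(
      sprintf(
        "target_cv %.3f too large for nonnegativity at n = %d (max %.3f)",
        target_cv, n_years, 1 / max(abs(z))
      ),
      call. = FALSE
    )
  }
  x <- mean * (1 + target_cv * z)
  set.seed(seed)
  sample(x)
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

#' Generate a schema-valid synthetic input bundle with known ground truth
#'
#' @param config A [synth_config()].
#' @param seed Master generator seed (recorded in the truth table).
#' @return List with `bundle` (tibbles as returned by [read_inputs()]) and
#'   `truth`: one row per (county, activity) holding the generating
#'   parameters (`baseline_rate`, `cv`, `hv`, `mean_rate`, `sd_rate`,
#'   `max_resource`, `flux_mode`, `age_profile`, `oracle_scope`).
#' @export
synth_bundle <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_counties
  sc <- config$scale
  region <- c(rep("west", config$n_west), rep("east", n - config$n_west))
  county_id <- 2L * seq_len(n) - 1L
  east_ids <- county_id[region == "east"]
  excluded_ids <- utils::tail(east_ids, config$n_timber_excluded)
  counties <- tibble::tibble(
    county_id = county_id,
    name = sprintf("synthcounty_%02d", seq_len(n)),
    region = region,
    area_ha = round(stats::runif(n, 150000, 600000)),
    timber_excluded = county_id %in% excluded_ids
  )

  rows <- list()
  truth <- list()
  n_yrs_series <- length(config$series_years)
  cvr <- config$cv_range
  add_truth <- function(cid, pathway, sub, own, units, baseline_rate, cv,
                        max_resource, age_profile = NA_character_,
                        oracle_scope = TRUE) {
    hv <- if (is.na(cv)) 0.10 * baseline_rate else min(cv, 1) * baseline_rate
    tibble::tibble(
      county_id = cid, pathway = pathway, sub_activity = sub, ownership = own,
      units = units, baseline_rate = baseline_rate,
      cv = ifelse(is.na(cv), 0.10, cv), hv = hv,
      max_resource = max_resource, age_profile = age_profile,
      oracle_scope = oracle_scope
    )
  }
  series_row <- function(cid, pathway, sub, own, units, series, max_resource) {
    tibble::tibble(
      county_id = cid, pathway = pathway, sub_activity = sub, ownership = own,
      year = config$series_years, amount = series, units = units,
      max_resource = max_resource
    )
  }
  rate_row <- function(cid, pathway, sub, own, units, amount, max_resource) {
    tibble::tibble(
      county_id = cid, pathway = pathway, sub_activity = sub, ownership = own,
      year = NA_integer_, amount = amount, units = units,
      max_resource = max_resource
    )
  }

  ownership_scale <- c(private = 1, state = 0.25, federal = 0.12, other = 0.05)
  grass_area <- ifelse(region == "east", stats::runif(n, 1e4, 1e5), 0)
  grass_share <- grass_area / sum(grass_area)
  grass_rates <- grassland_county_baseline(
    config$grassland_statewide_rate * sc, grass_share
  )
  lost_raw <- ifelse(region == "west", stats::runif(n, 100, 8000), 0)
  lost_ha <- lost_raw / sum(lost_raw) * config$lost_tidal_total_ha * sc
  puget <- region == "west" & seq_len(n) <= ceiling(config$n_west * 0.6)

  for (i in seq_len(n)) {
    cid <- county_id[i]
    west <- region[i] == "west"
    reg_scale <- if (west) 1 else 0.3

    # timber harvest volumes: 2003-2017 series per ownership
    for (own in names(ownership_scale)) {
      m <- runif1(1e4, 4e4) * ownership_scale[[own]] * reg_scale * sc
      cv <- runif1(cvr[1], cvr[2])
      s <- generate_series(m, cv, n_yrs_series, seed = seed + 37 * i + match(own, names(ownership_scale)))
      # deferrable resource: the standing volume a 45 -> 75 year rotation
      # shift can defer, ~30 years of baseline cut, not one year's harvest
      rows[[length(rows) + 1]] <- series_row(cid, "timber", "harvest", own, "volume_per_yr", s, 30 * m)
      truth[[length(truth) + 1]] <- add_truth(cid, "timber", "harvest", own, "volume_per_yr", m, cv, 30 * m)
    }
    # added sequestration on deferred private stands (cohort, age profile)
    m_clear <- runif1(1000, 4000) * reg_scale * sc
    rows[[length(rows) + 1]] <- rate_row(
      cid, "timber", "added_sequestration", "private", "ha_per_yr", m_clear, 30 * m_clear
    )
    truth[[length(truth) + 1]] <- add_truth(
      cid, "timber", "added_sequestration", "private", "ha_per_yr", m_clear, NA,
      30 * m_clear,
      age_profile = "added_seq_delta", oracle_scope = FALSE
    )

    # cropland agriculture
    cropland <- (if (west) runif1(5e3, 3e4) else runif1(5e4, 2.5e5)) * sc
    cc_rate <- runif1(0.01, 0.03) * cropland
    cc_max <- runif1(0.5, 0.8) * cropland
    nt_rate <- runif1(0.02, 0.05) * cropland
    nt_max <- runif1(0.3, 0.6) * cropland
    nm_rate <- cropland * runif1(1, 3)
    nm_max <- nutrient_max_area(cropland) * 50
    for (sub in c("cover_crops", "no_till", "nutrient_mgmt")) {
      r <- switch(sub, cover_crops = cc_rate, no_till = nt_rate, nutrient_mgmt = nm_rate)
      mx <- switch(sub, cover_crops = cc_max, no_till = nt_max, nutrient_mgmt = nm_max)
      un <- if (sub == "nutrient_mgmt") "kgN_per_yr" else "ha_per_yr"
      rows[[length(rows) + 1]] <- rate_row(cid, "agriculture", sub, "na", un, r, mx)
      truth[[length(truth) + 1]] <- add_truth(cid, "agriculture", sub, "na", un, r, NA, mx)
    }

    # avoided conversion of forest to urban / rural development
    urb <- (if (west) runif1(50, 400) else runif1(5, 40)) * sc
    rur <- 1.5 * (if (west) runif1(50, 400) else runif1(5, 40)) * sc
    for (sub in c("forest_to_urban", "forest_to_rural")) {
      r <- if (sub == "forest_to_urban") urb else rur
      rows[[length(rows) + 1]] <- rate_row(
        cid, "avoided_forest_conversion", sub, "na", "ha_per_yr", r, 100 * r
      )
      truth[[length(truth) + 1]] <- add_truth(
        cid, "avoided_forest_conversion", sub, "na", "ha_per_yr", r, NA, 100 * r
      )
    }

    # sagebrush-steppe (east side only)
    if (!west) {
      sb <- runif1(200, 2000) * sc
      rows[[length(rows) + 1]] <- rate_row(
        cid, "avoided_sagebrush_conversion", "", "na", "ha_per_yr", sb, 50 * sb
      )
      truth[[length(truth) + 1]] <- add_truth(
        cid, "avoided_sagebrush_conversion", "", "na", "ha_per_yr", sb, NA, 50 * sb
      )
    }

    # grassland conversion (statewide rate allocated by grassland share)
    gr <- grass_rates[i]
    rows[[length(rows) + 1]] <- rate_row(
      cid, "avoided_grassland_conversion", "", "na", "ha_per_yr", gr, 40 * max(gr, 1)
    )
    truth[[length(truth) + 1]] <- add_truth(
      cid, "avoided_grassland_conversion", "", "na", "ha_per_yr", gr, NA, 40 * max(gr, 1)
    )

    # riparian reforestation
    rip <- runif1(20, 150) * sc
    rows[[length(rows) + 1]] <- rate_row(
      cid, "riparian_reforestation", "", "na", "ha_per_yr", rip, 60 * rip
    )
    truth[[length(truth) + 1]] <- add_truth(
      cid, "riparian_reforestation", "", "na", "ha_per_yr", rip, NA, 60 * rip
    )

    # post-wildfire replanting on federal land (east side; cohort pathway)
    if (!west) {
      m_rp <- runif1(100, 1500) * sc
      cv_rp <- runif1(0.2, min(cvr[2], 0.55))
      s_rp <- generate_series(m_rp, cv_rp, n_yrs_series, seed = seed + 101 * i)
      rows[[length(rows) + 1]] <- series_row(
        cid, "wildfire_replanting", "", "federal", "ha_per_yr", s_rp, 40 * m_rp
      )
      truth[[length(truth) + 1]] <- add_truth(
        cid, "wildfire_replanting", "", "federal", "ha_per_yr", m_rp, cv_rp,
        40 * m_rp,
        age_profile = "replant_growth", oracle_scope = FALSE
      )
    }

    # tidal wetland restoration (west side; Puget Sound 0.00215 rule)
    if (west) {
      mapped <- if (i <= 2) runif1(5, 30) * sc else NA
      tb <- tidal_baseline(lost_ha[i], mapped, in_puget_sound = puget[i])
      rows[[length(rows) + 1]] <- rate_row(
        cid, "tidal_wetland_restoration", "", "na", "ha_per_yr", tb$rate, tb$max_resource
      )
      truth[[length(truth) + 1]] <- add_truth(
        cid, "tidal_wetland_restoration", "", "na", "ha_per_yr", tb$rate, NA, tb$max_resource
      )
    }
  }
  baselines <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truth)

  # per-unit flux rates: timber nets from the five components per region,
  # remaining pathways as signed per-unit rates with sd = sd_frac * |mean|
  comp_west <- c(
    harvest_volume = -0.90, belowground_biomass = -0.25,
    unused_mill_residue = 0.12, commercial_fuel = 0.08,
    shortlived_products = 0.25
  )
  comp_east <- c(
    harvest_volume = -0.60, belowground_biomass = -0.18,
    unused_mill_residue = 0.09, commercial_fuel = 0.06,
    shortlived_products = 0.18
  )
  timber_rates <- dplyr::bind_rows(lapply(c("west", "east"), function(rg) {
    net <- timber_net_rate(if (rg == "west") comp_west else comp_east)
    tidyr::crossing(
      sub_activity = "harvest",
      ownership = c("private", "state", "federal", "other")
    ) |>
      dplyr::mutate(
        pathway = "timber", region = rg, mean_rate = net,
        sd_rate = config$sd_frac * abs(net),
        units = "volume_per_yr", age_profile = NA_character_
      )
  }))
  other_rates <- tibble::tribble(
    ~pathway, ~sub_activity, ~ownership, ~region, ~mean_rate, ~age_profile,
    "timber", "added_sequestration", "private", "west", -2.5, "added_seq_delta",
    "timber", "added_sequestration", "private", "east", -1.5, "added_seq_delta",
    "agriculture", "cover_crops", "na", "statewide", -1.2, NA,
    "agriculture", "no_till", "na", "statewide", -0.9, NA,
    "agriculture", "nutrient_mgmt", "na", "statewide", -0.006, NA,
    "avoided_forest_conversion", "forest_to_urban", "na", "west", -7.5, NA,
    "avoided_forest_conversion", "forest_to_urban", "na", "east", -5.0, NA,
    "avoided_forest_conversion", "forest_to_rural", "na", "west", -4.5, NA,
    "avoided_forest_conversion", "forest_to_rural", "na", "east", -3.0, NA,
    "avoided_sagebrush_conversion", "", "na", "statewide", -1.0, NA,
    "avoided_grassland_conversion", "", "na", "statewide", -3.0, NA,
    "riparian_reforestation", "", "na", "statewide", -6.0, NA,
    "wildfire_replanting", "", "federal", "statewide", -5.0, "replant_growth",
    "tidal_wetland_restoration", "", "na", "statewide", -8.0, NA
  ) |>
    dplyr::mutate(
      sd_rate = config$sd_frac * abs(.data$mean_rate),
      units = dplyr::case_when(
        sub_activity == "nutrient_mgmt" ~ "kgN_per_yr",
        pathway == "timber" & sub_activity == "harvest" ~ "volume_per_yr",
        TRUE ~ "ha_per_yr"
      )
    )
  rates <- dplyr::bind_rows(timber_rates, other_rates) |>
    dplyr::select(
      "pathway", "sub_activity", "ownership", "region",
      "mean_rate", "sd_rate", "units", "age_profile"
    )

  age_profiles <- dplyr::bind_rows(
    tibble::tibble(
      profile_id = "replant_growth", age = c(1L, 5L, 10L, 20L),
      multiplier = c(0.2, 0.6, 1.0, 1.3)
    ),
    tibble::tibble(
      profile_id = "added_seq_delta", age = c(1L, 10L, 20L, 30L),
      multiplier = c(1.0, 0.9, 0.7, 0.5)
    )
  )

  bundle <- list(
    counties = counties, baselines = baselines, rates = rates,
    scenario_params = scenario_defaults(), age_profiles = age_profiles
  )
  validate_bundle(bundle)

  # attach realized rate parameters and flux mode to the truth table
  resolved <- resolve_rates(baselines, counties, rates)
  truth <- truth |>
    dplyr::left_join(
      resolved |>
        dplyr::select("county_id", "pathway", "sub_activity", "ownership",
          "mean_rate", "sd_rate"
        ),
      by = c("county_id", "pathway", "sub_activity", "ownership")
    ) |>
    dplyr::left_join(
      counties |> dplyr::select("county_id", "region", "timber_excluded"),
      by = "county_id"
    ) |>
    dplyr::mutate(flux_mode = "stock", generator_seed = seed)

  list(bundle = bundle, truth = truth)
}

#' Write a synthetic bundle to CSV files
#'
#' Writes `counties.csv`, `baselines.csv`, `rates.csv`,
#' `scenario_params.csv`, `age_profiles.csv` and `synthetic_truth.csv` under
#' `outdir`; the files round-trip through [read_inputs()] with no warnings.
#' Two calls with the same config and seed produce identical files.
#'
#' @inheritParams synth_bundle
#' @param outdir Output directory (created if needed).
#' @return List with `files` (named paths) and `truth`.
#' @export
generate_bundle <- function(config = synth_config(), seed = 1, outdir = ".") {
  sb <- synth_bundle(config, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    counties = "counties.csv", baselines = "baselines.csv",
    rates = "rates.csv", scenario_params = "scenario_params.csv",
    age_profiles = "age_profiles.csv", truth = "synthetic_truth.csv"
  )
  paths <- stats::setNames(file.path(outdir, files), names(files))
  readr::write_csv(sb$bundle$counties, paths["counties"], progress = FALSE)
  readr::write_csv(sb$bundle$baselines, paths["baselines"], progress = FALSE)
  readr::write_csv(sb$bundle$rates, paths["rates"], progress = FALSE)
  readr::write_csv(sb$bundle$scenario_params, paths["scenario_params"], progress = FALSE)
  readr::write_csv(sb$bundle$age_profiles, paths["age_profiles"], progress = FALSE)
  readr::write_csv(sb$truth, paths["truth"], progress = FALSE)
  list(files = paths, truth = sb$truth)
}

#' Closed-form expected final-year flux per activity
#'
#' Independent oracle for flat-profile, stock-mode activities: expected
#' enrollment after `n_years` is
#' `min((5.5 + (n_years - 10) * post_decade_share) * growth_share * hv,
#' cap_fraction * max_resource)` (5.5 is the sum of the decade-1 ramp
#' factors 0.1, 0.2, ..., 1.0), and the expected deterministic flux is that
#' enrollment times the mean rate. Timber activities in wildfire-excluded
#' counties are zero. Cohort activities (age profiles) are outside oracle
#' scope and are dropped.
#'
#' @param truth Truth table from [synth_bundle()].
#' @param scenario Scenario label.
#' @param params Scenario-parameter table (defaults unless overridden).
#' @param n_years Simulation horizon.
#' @return Tibble of in-scope rows with `expected_flux_mt` (year `n_years`,
#'   MT CO2e per yr) and attribute `statewide_total_mt`.
#' @export
analytic_oracle <- function(truth, scenario, params = scenario_defaults(),
                            n_years = ncs_n_years()) {
  p <- params[params$scenario == scenario, ]
  rows <- truth |>
    dplyr::filter(
      .data$oracle_scope,
      !(.data$pathway == "timber" & .data$timber_excluded)
    ) |>
    dplyr::left_join(
      p |> dplyr::select(-"scenario"),
      by = c("pathway", "sub_activity", "ownership")
    )
  uncapped <- (5.5 + (n_years - 10) * rows$post_decade_share) *
    rows$growth_share * rows$hv
  cap <- ifelse(is.na(rows$max_resource), Inf, rows$cap_fraction * rows$max_resource)
  enrolled <- pmin(uncapped, cap)
  out <- rows |>
    dplyr::mutate(
      expected_enrolled = enrolled,
      expected_flux_mt = enrolled * .data$mean_rate
    )
  attr(out, "statewide_total_mt") <- sum(out$expected_flux_mt)
  out
}
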