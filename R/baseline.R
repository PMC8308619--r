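#' Coefficient of variation of an annual activity series
#'
#' Sample (n-1) standard deviation divided by the mean. Used for pathways
#' whose inputs arrive as annual time series (timber harvest volumes,
#' post-wildfire replanting areas); all other pathways use a conservative
#' 10% default in place of the CV.
#'
#' @param series Numeric vector of annual activity amounts, all >= 0.
#' @return Dimensionless CV >= 0.
#' @export
coefficient_of_variation <- function(series) {
  if (length(series) < 2) {
    stop("insufficient-series error: need >= 2 years to compute a CV", call. = FALSE)
  }
  if (any(series < 0)) {
    stop("validation error: negative activity in series", call. = FALSE)
  }
  m <- mean(series)
  if (m == 0) {
    stop("degenerate-series error: series mean is zero", call. = FALSE)
  }
  stats::sd(series) / m
}

#' Historical variation of a baseline activity rate
#'
#' Historical variation (HV) is the baseline annual rate times the historical
#' CV; it is the yardstick every scenario's implementation increments are
#' scaled by. When the CV exceeds 1 the HV is capped at 100% of the baseline
#' rate so implementation can never be computed from more variation than the
#' activity itself provides. When no CV is available (series too short, or a
#' single-rate pathway) a conservative default of 0.10 is used.
#'
#' @param baseline_rate Activity units per year, >= 0.
#' @param cv Dimensionless CV, or `NULL`/`NA` to use the 10% default.
#' @return List with `baseline_rate`, `cv`, `hv` (activity units per year)
#'   and `provenance` (`"series_cv"` or `"default_10pct"`).
#' @export
historical_variation <- function(baseline_rate, cv = NULL) {
  if (baseline_rate < 0) {
    stop("validation error: negative baseline rate", call. = FALSE)
  }
  if (is.null(cv) || is.na(cv)) {
    cv <- 0.10
    prov <- "default_10pct"
  } else {
    prov <- "series_cv"
  }
  if (cv < 0) stop("validation error: negative CV", call. = FALSE)
  hv <- if (cv > 1) baseline_rate else baseline_rate * cv
  list(baseline_rate = baseline_rate, cv = cv, hv = hv, provenance = prov)
}

#' Baseline tidal-wetland restoration rate for a county
#'
#' Counties with mapped restoration activity use the mapped annual rate.
#' Puget Sound counties with no mapped activity are assumed to restore a
#' fixed proportion of their lost tidal wetland area each year: lost hectares
#' times 0.00215, the proportion of the statewide lost wetland area restored
#' annually in the Puget Sound during the baseline period. Counties outside
#' Puget Sound with no mapped rate get 0. The restorable resource is capped
#' at the county's lost wetland area.
#'
#' @param lost_ha Lost (converted) tidal wetland area, hectares >= 0.
#' @param mapped_rate Mapped annual restoration rate (ha/yr) or `NULL`/`NA`.
#' @param in_puget_sound Logical.
#' @return List with `rate` (ha/yr) and `max_resource` (= `lost_ha`).
#' @export
tidal_baseline <- function(lost_ha, mapped_rate = NULL, in_puget_sound = FALSE) {
  if (is.na(lost_ha) || lost_ha < 0) {
    stop("validation error: lost_ha must be >= 0", call. = FALSE)
  }
  rate <- if (!is.null(mapped_rate) && !is.na(mapped_rate)) {
    mapped_rate
  } else if (in_puget_sound) {
    lost_ha * 0.00215
  } else {
    0
  }
  list(rate = rate, max_resource = lost_ha)
}

#' Allocate a statewide grassland-conversion rate to counties
#'
#' County baseline conversion rates are proportional to each county's share
#' of statewide grassland area; the county rates sum exactly to the
#' statewide rate.
#'
#' @param statewide_rate Statewide conversion rate (activity units/yr) >= 0.
#' @param county_grassland_share Numeric vector of county shares summing to 1.
#' @return Numeric vector of county rates.
#' @export
grassland_county_baseline <- function(statewide_rate, county_grassland_share) {
  if (statewide_rate < 0) {
    stop("validation error: negative statewide rate", call. = FALSE)
  }
  if (abs(sum(county_grassland_share) - 1) > 1e-9) {
    stop("validation error: grassland shares must sum to 1", call. = FALSE)
  }
  statewide_rate * county_grassland_share
}

#' Maximum croppable area for reduced fertilizer application
#'
#' Nutrient management is capped at 40% of a county's cropland area.
#'
#' @param county_cropland_ha Cropland area (ha) >= 0.
#' @return Maximum implementable area, `0.4 * county_cropland_ha`.
#' @export
nutrient_max_area <- function(county_cropland_ha) {
  if (any(county_cropland_ha < 0)) {
    stop("validation error: negative cropland area", call. = FALSE)
  }
  0.4 * county_cropland_ha
}

#' Fill unreported county values from a statewide census total
#'
#' Agricultural census tables suppress some county values. The residual
#' between the statewide total and the sum of reported counties is allocated
#' to the missing counties in proportion to their values in the other census
#' year; if the other year is also all-zero for them, the residual is split
#' uniformly (and a message notes it).
#'
#' @param statewide_total Statewide reported total (>= sum of reported).
#' @param reported Named numeric vector of reported county values.
#' @param other_year Named numeric vector covering the missing counties with
#'   their values in the other census year.
#' @return Named numeric vector covering reported and missing counties,
#'   summing to `statewide_total`.
#' @export
disaggregate_missing_counties <- function(statewide_total, reported, other_year) {
  residual <- statewide_total - sum(reported)
  if (residual < -1e-9) {
    stop("validation error: reported county values exceed the statewide total", call. = FALSE)
  }
  missing <- setdiff(names(other_year), names(reported))
  if (length(missing) == 0 || residual <= 0) {
    return(reported)
  }
  weights <- other_year[missing]
  if (sum(weights) == 0) {
    message("disaggregate_missing_counties: other-year values all zero; splitting residual uniformly")
    weights[] <- 1
  }
  filled <- residual * weights / sum(weights)
  c(reported, filled)
}

#' Derive per-activity baselines, CVs and historical variation for a bundle
#'
#' Collapses each baseline record to a single annual rate (the series mean
#' for time-series records, the value itself for single-rate records),
#' computes the CV where a series of >= 2 years exists and applies the 10%
#' default elsewhere, applies the HV cap, and attaches the resolved flux
#' rate (with region fallback). Timber activities in counties flagged
#' `timber_excluded` (more than half of forestland at high or extreme
#' wildfire risk) are dropped, with a message.
#'
#' @param bundle A validated input bundle from [read_inputs()].
#' @param quiet Suppress log messages.
#' @return Tibble with one row per (county, activity):
#'   `county_id`, `pathway`, `sub_activity`, `ownership`, `units`,
#'   `baseline_rate`, `cv`, `hv`, `provenance`, `max_resource`,
#'   `mean_rate`, `sd_rate`, `rate_region`, `age_profile`.
#' @export
derive_baselines <- function(bundle, quiet = FALSE) {
  counties <- bundle$counties
  excluded <- counties$county_id[counties$timber_excluded]
  baselines <- bundle$baselines
  n_timber_dropped <- sum(
    baselines$pathway == "timber" & baselines$county_id %in% excluded
  )
  baselines <- baselines |>
    dplyr::filter(!(.data$pathway == "timber" & .data$county_id %in% excluded))
  if (!quiet && n_timber_dropped > 0) {
    message(sprintf(
      "derive_baselines: dropped %d timber baseline row(s) in %d wildfire-excluded county(ies)",
      n_timber_dropped, length(unique(excluded))
    ))
  }

  per_key <- baselines |>
    dplyr::group_by(
      .data$county_id, .data$pathway, .data$sub_activity,
      .data$ownership, .data$units
    ) |>
    dplyr::summarise(
      baseline_rate = mean(.data$amount),
      cv = if (dplyr::n() >= 2 && mean(.data$amount) > 0) {
        stats::sd(.data$amount) / mean(.data$amount)
      } else {
        NA_real_
      },
      max_resource = .data$max_resource[1],
      .groups = "drop"
    )

  hv_rows <- lapply(seq_len(nrow(per_key)), function(i) {
    historical_variation(per_key$baseline_rate[i], per_key$cv[i])
  })
  per_key$cv <- vapply(hv_rows, `[[`, numeric(1), "cv")
  per_key$hv <- vapply(hv_rows, `[[`, numeric(1), "hv")
  per_key$provenance <- vapply(hv_rows, `[[`, character(1), "provenance")

  resolved <- resolve_rates(per_key, counties, bundle$rates)
  out <- per_key |>
    dplyr::left_join(
      resolved |>
        dplyr::select("county_id", "pathway", "sub_activity", "ownership",
          "mean_rate", "sd_rate", "rate_region", "age_profile"
        ),
      by = c("county_id", "pathway", "sub_activity", "ownership")
    )
  if (!quiet) {
    n_fallback <- sum(out$rate_region == "statewide")
    if (n_fallback > 0) {
      message(sprintf(
        "derive_baselines: %d activity(ies) resolved to a statewide rate by fallback",
        n_fallback
      ))
    }
  }
  out
}
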