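#' Net per-unit timber flux from its five components
#'
#' Extending harvest rotations changes carbon flux through five linear
#' components per unit of deferred harvest volume: the harvest volume itself,
#' below-ground biomass, unused mill residues, wood burned as commercial
#' fuel, and short-lived (<= 20-year) transformed wood products. The net
#' per-unit rate is their signed sum, developed separately for wet (west)
#' and dry (east) forests.
#'
#' @param components Named numeric vector or one-row data frame with exactly
#'   `harvest_volume`, `belowground_biomass`, `unused_mill_residue`,
#'   `commercial_fuel`, `shortlived_products` (MT CO2e per volume unit,
#'   signed).
#' @return Net rate, MT CO2e per volume unit.
#' @export
timber_net_rate <- function(components) {
  needed <- c(
    "harvest_volume", "belowground_biomass", "unused_mill_residue",
    "commercial_fuel", "shortlived_products"
  )
  components <- unlist(components)
  missing <- setdiff(needed, names(components))
  if (length(missing) > 0) {
    stop(
      sprintf("missing timber rate component(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  sum(components[needed])
}

flux_series <- function(annual_flux) {
  tibble::tibble(
    year = seq_along(annual_flux),
    annual_flux = as.numeric(annual_flux),
    cumulative = cumsum(as.numeric(annual_flux))
  )
}

#' Annual flux accrued on enrolled stock
#'
#' Every unit of enrolled activity sequesters (or avoids emitting) at the
#' per-unit rate each year it remains enrolled:
#' `annual_flux[t] = enrolled[t] * rate`. Signed; negative = reduction.
#'
#' @param trajectory List with an `enrolled` vector (from
#'   [build_trajectory()]) or a bare numeric vector of enrolled stock.
#' @param rate Per-unit rate, MT CO2e per activity unit per year.
#' @return Tibble with `year`, `annual_flux`, `cumulative` (MT CO2e).
#' @export
stock_flux <- function(trajectory, rate) {
  enrolled <- if (is.list(trajectory)) trajectory$enrolled else trajectory
  flux_series(enrolled * rate)
}

#' Age-dependent flux over enrollment cohorts
#'
#' Cohort pathways (post-wildfire replanting; added sequestration on
#' deferred stands) sequester at rates that change with stand age. Each
#' year's flux sums over cohorts: amount enrolled in year `s` contributes
#' `amount * profile_rate(t - s + 1)` in year `t`. The profile is a step
#' function over tabulated ages; ages beyond the last tabulated age use the
#' terminal value.
#'
#' @param ledger Tibble/data frame with `year` (enrollment year) and
#'   `amount` columns, or a bare numeric vector of per-year increments.
#' @param age_profile Tibble/data frame with `age` (1, 2, ...) and `rate`
#'   (MT CO2e per unit per year at that age).
#' @param n_years Simulation horizon.
#' @return Tibble with `year`, `annual_flux`, `cumulative` (MT CO2e).
#' @export
cohort_flux <- function(ledger, age_profile, n_years = NULL) {
  if (is.null(age_profile) || nrow(as.data.frame(age_profile)) == 0) {
    stop("empty age profile", call. = FALSE)
  }
  if (is.numeric(ledger)) {
    ledger <- tibble::tibble(year = seq_along(ledger), amount = ledger)
  }
  if (any(ledger$amount < 0)) {
    stop("validation error: negative cohort amount", call. = FALSE)
  }
  if (is.null(n_years)) n_years <- max(ledger$year)
  rate_at_age <- profile_lookup(age_profile, n_years)
  annual <- numeric(n_years)
  for (i in seq_len(nrow(ledger))) {
    s <- ledger$year[i]
    a <- ledger$amount[i]
    if (a == 0 || s > n_years) next
    t <- s:n_years
    annual[t] <- annual[t] + a * rate_at_age[t - s + 1]
  }
  flux_series(annual)
}

# Expand a step-function age profile into a rate-per-age vector of length
# n_years, extending the terminal value to older ages.
profile_lookup <- function(age_profile, n_years) {
  ap <- as.data.frame(age_profile)
  rate_col <- if ("rate" %in% names(ap)) "rate" else "multiplier"
  ages <- ap$age
  if (ages[1] != 1 || is.unsorted(ages, strictly = TRUE)) {
    stop("validation error: age profile ages must start at 1 and increase strictly", call. = FALSE)
  }
  idx <- findInterval(seq_len(n_years), ages)
  ap[[rate_col]][idx]
}

#' Added sequestration on deferred private even-aged stands
#'
#' Deferred-harvest stands keep growing at rates higher than the
#' business-as-usual regrowth that would follow a clearcut. The difference
#' is credited as a fifth timber activity, computed as a cohort flux over
#' the per-age growth delta (deferred-stand rate minus regrowth rate).
#' Applies only to private even-aged timberland.
#'
#' @param ledger Enrollment cohorts as in [cohort_flux()].
#' @param growth_delta_profile Age profile of per-unit rate differences.
#' @param ownership Ownership of the enrolled stands; must be `"private"`.
#' @param n_years Simulation horizon.
#' @return Tibble with `year`, `annual_flux`, `cumulative` (MT CO2e).
#' @export
delayed_harvest_added_sequestration <- function(ledger, growth_delta_profile,
                                                ownership = "private",
                                                n_years = NULL) {
  if (!identical(ownership, "private")) {
    stop("added sequestration applies to private even-aged stands only", call. = FALSE)
  }
  cohort_flux(ledger, growth_delta_profile, n_years = n_years)
}

#' Effective activity vector for flux accounting
#'
#' Reduces a trajectory to the per-year quantity the (possibly sampled)
#' per-unit rate multiplies:
#' * `stock` mode, no profile: cumulative enrolled activity;
#' * `pulse` mode: the year's new enrollment only (committed avoided
#'   emissions counted once);
#' * with an age profile: the cohort convolution of increments with the
#'   profile's per-age multipliers, so `flux = rate * effective`.
#'
#' @param increments,enrolled Numeric vectors from [build_trajectory()].
#' @param flux_mode `"stock"` or `"pulse"`.
#' @param age_multipliers Optional tibble with `age` and `multiplier`
#'   (dimensionless, relative to the activity's mean rate).
#' @return Numeric vector, activity units (age-weighted where applicable).
#' @export
effective_activity <- function(increments, enrolled, flux_mode = "stock",
                               age_multipliers = NULL) {
  n_years <- length(increments)
  if (!is.null(age_multipliers) && nrow(as.data.frame(age_multipliers)) > 0) {
    cohort_flux(increments, age_multipliers, n_years = n_years)$annual_flux
  } else if (flux_mode == "pulse") {
    increments
  } else {
    enrolled
  }
}

#' Deterministic flux for a trajectory table
#'
#' Applies [effective_activity()] per activity and multiplies by the mean
#' rate; used for the sd = 0 deterministic pipeline and as the per-iteration
#' kernel of the Monte Carlo engine (which swaps in sampled rates).
#'
#' @param trajectories Output of [build_trajectories()].
#' @param age_profiles Age-profile table (`profile_id`, `age`, `multiplier`).
#' @return `trajectories` with list-columns `effective` (activity units) and
#'   `annual_flux` (MT CO2e per yr, at the mean rate).
#' @export
deterministic_flux <- function(trajectories, age_profiles = NULL) {
  eff <- lapply(seq_len(nrow(trajectories)), function(i) {
    prof <- NULL
    pid <- trajectories$age_profile[i]
    if (!is.na(pid) && !is.null(age_profiles)) {
      prof <- age_profiles[age_profiles$profile_id == pid, ]
    }
    effective_activity(
      trajectories$increments[[i]], trajectories$enrolled[[i]],
      flux_mode = trajectories$flux_mode[i],
      age_multipliers = prof
    )
  })
  trajectories |>
    dplyr::mutate(
      effective = eff,
      annual_flux = Map(function(e, r) e * r, eff, trajectories$mean_rate)
    )
}
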