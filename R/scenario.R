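#' Built-in scenario parameter registry
#'
#' Default ramp/plateau/cap rules for every (scenario, activity) pair. The
#' general shape shared by all scenarios: new enrollment each year of the
#' first decade equals `min(t * ramp_fraction, 1) * growth_share * hv`,
#' reaching 100% of the allowed growth (`growth_share * hv`) at year 10;
#' from year 11 on the annual increment is `post_decade_share` times that
#' year-10 increment ("hold" = 1).
#'
#' Defaults encode: Limited general growth_share 1, post-decade 1; Limited
#' timber post-decade 0.5 (stabilizes at half the historical variation);
#' Moderate timber growth_shares 0.30 (private), 0.15 (state), 0.75
#' (federal/other); Moderate elsewhere growth_share 0.5 (a configurable
#' midpoint); Ambitious growth_share 1 with enrollment caps on timber of
#' 40% (private) and 32% (state) of the implementable resource, 100%
#' elsewhere. Caps on non-timber pathways are 100% of `max_resource` in all
#' scenarios. All entries are overridable via `scenario_params.csv`.
#'
#' @return Tibble with one row per (scenario, pathway, sub_activity,
#'   ownership) and columns `ramp_fraction`, `growth_share`,
#'   `post_decade_share`, `cap_fraction`, `flux_mode`.
#' @export
scenario_defaults <- function() {
  reg <- activity_registry()
  grid <- tidyr::crossing(scenario = ncs_scenarios(), reg)
  grid |>
    dplyr::mutate(
      ramp_fraction = 0.1,
      growth_share = dplyr::case_when(
        scenario == "moderate" & pathway == "timber" & ownership == "private" ~ 0.30,
        scenario == "moderate" & pathway == "timber" & ownership == "state" ~ 0.15,
        scenario == "moderate" & pathway == "timber" ~ 0.75,
        scenario == "moderate" ~ 0.5,
        TRUE ~ 1.0
      ),
      post_decade_share = dplyr::case_when(
        scenario == "limited" & pathway == "timber" ~ 0.5,
        TRUE ~ 1.0
      ),
      cap_fraction = dplyr::case_when(
        scenario == "ambitious" & pathway == "timber" & ownership == "private" ~ 0.40,
        scenario == "ambitious" & pathway == "timber" & ownership == "state" ~ 0.32,
        TRUE ~ 1.0
      ),
      flux_mode = "stock"
    ) |>
    dplyr::select(
      "scenario", "pathway", "sub_activity", "ownership",
      "ramp_fraction", "growth_share", "post_decade_share",
      "cap_fraction", "flux_mode"
    )
}

#' Resolve scenario parameters with CSV overrides
#'
#' @param overrides Tibble in the `scenario_params` schema (possibly empty).
#' @return The full registry with override rows replacing defaults.
#' @export
scenario_params_with_overrides <- function(overrides = NULL) {
  defaults <- scenario_defaults()
  if (is.null(overrides) || nrow(overrides) == 0) {
    return(defaults)
  }
  assert_registered(overrides, "scenario_params overrides")
  keyed <- function(df) key_id(df$pathway, df$sub_activity, df$ownership)
  ids_o <- paste(overrides$scenario, keyed(overrides))
  ids_d <- paste(defaults$scenario, keyed(defaults))
  dplyr::bind_rows(
    overrides[, names(defaults)],
    defaults[!ids_d %in% ids_o, ]
  ) |>
    dplyr::arrange(.data$scenario, .data$pathway, .data$sub_activity, .data$ownership)
}

#' Pre-cap enrollment increment for one simulation year
#'
#' Years 1-10 ramp linearly: `min(t * ramp_fraction, 1) * growth_share * hv`
#' new activity per year. Years 11-31 hold at `post_decade_share` times the
#' full allowed growth `growth_share * hv`.
#'
#' @param params One row of scenario parameters (list or one-row tibble with
#'   `ramp_fraction`, `growth_share`, `post_decade_share`).
#' @param t Simulation year, 1..31.
#' @param hv Historical variation, activity units per year, >= 0.
#' @return New activity enrolled in year `t`, before any resource cap.
#' @export
annual_increment <- function(params, t, hv) {
  if (any(t < 1 | t > ncs_n_years())) {
    stop(sprintf("year out of range 1..%d", ncs_n_years()), call. = FALSE)
  }
  if (hv < 0) stop("validation error: negative historical variation", call. = FALSE)
  allowed <- params$growth_share * hv
  ifelse(
    t <= 10,
    pmin(t * params$ramp_fraction, 1) * allowed,
    params$post_decade_share * allowed
  )
}

#' Build a 31-year enrollment trajectory
#'
#' Cumulative enrolled activity is the running sum of [annual_increment()]
#' values, truncated at `cap_fraction * max_resource` (the enrollable share
#' of the implementable resource). Capping acts on enrollment, with the
#' increment in the capping year back-adjusted so
#' `enrolled[t] = enrolled[t-1] + increments[t]` holds exactly
#' (additionality identity). A missing (`NA`) `max_resource` means
#' unlimited.
#'
#' @param hv Historical variation, activity units per year.
#' @param params Scenario-parameter row (see [annual_increment()], plus
#'   `cap_fraction`).
#' @param max_resource Total implementable resource, activity units (or `NA`).
#' @param n_years Simulation horizon (default 31).
#' @return List with `increments`, `enrolled` (length `n_years`) and
#'   `capped_at` (first year the cap binds, or `NA`).
#' @export
build_trajectory <- function(hv, params, max_resource = NA, n_years = ncs_n_years()) {
  if (!is.na(max_resource) && max_resource < 0) {
    stop("validation error: negative max_resource", call. = FALSE)
  }
  inc <- annual_increment(params, seq_len(n_years), hv)
  cap <- if (is.na(max_resource)) Inf else params$cap_fraction * max_resource
  enrolled <- pmin(cumsum(inc), cap)
  increments <- diff(c(0, enrolled))
  capped_idx <- which(cumsum(inc) > cap)
  list(
    increments = increments,
    enrolled = enrolled,
    capped_at = if (length(capped_idx) > 0) capped_idx[1] else NA_integer_
  )
}

#' Build trajectories for every activity in a derived-baseline table
#'
#' @param derived Output of [derive_baselines()].
#' @param scenario One of `"limited"`, `"moderate"`, `"ambitious"`.
#' @param params Full scenario-parameter table (defaults with overrides).
#' @param n_years Simulation horizon.
#' @return Tibble with one row per activity: key columns, `flux_mode`, and
#'   list-columns `increments` and `enrolled`, plus `capped_at`.
#' @export
build_trajectories <- function(derived, scenario,
                               params = scenario_defaults(),
                               n_years = ncs_n_years()) {
  p <- params |> dplyr::filter(.data$scenario == !!scenario)
  joined <- derived |>
    dplyr::left_join(
      p |> dplyr::select(-"scenario"),
      by = c("pathway", "sub_activity", "ownership")
    )
  if (any(is.na(joined$growth_share))) {
    stop("scenario parameters missing for some activities", call. = FALSE)
  }
  trajs <- lapply(seq_len(nrow(joined)), function(i) {
    build_trajectory(
      hv = joined$hv[i],
      params = joined[i, ],
      max_resource = joined$max_resource[i],
      n_years = n_years
    )
  })
  joined |>
    dplyr::mutate(
      scenario = !!scenario,
      increments = lapply(trajs, `[[`, "increments"),
      enrolled = lapply(trajs, `[[`, "enrolled"),
      capped_at = vapply(trajs, `[[`, integer(1), "capped_at")
    )
}
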