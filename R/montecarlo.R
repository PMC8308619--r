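# Substream seed for one (scenario, iteration); kept below 2^31 - 1 and
# away from double-precision overflow.
iteration_seed <- function(master_seed, scenario, iteration) {
  scen_idx <- match(scenario, ncs_scenarios())
  as.integer((master_seed %% 2147483647) * 69069 +
    scen_idx * 1234567 + iteration * 7919) %% 2147483647L
}

#' Sample one iteration's per-unit rates
#'
#' One draw per unique (activity key, rate region) from
#' `Normal(mean_rate, sd_rate)`, untruncated; the draw is held fixed across
#' years and across counties sharing the rate within an iteration (rate
#' uncertainty is epistemic, not interannual). `sd_rate = 0` returns the
#' mean exactly.
#'
#' @param rate_specs Tibble with `mean_rate` and `sd_rate` columns.
#' @param seed Integer seed for this draw.
#' @return Numeric vector of sampled rates, one per row of `rate_specs`.
#' @export
draw_rates <- function(rate_specs, seed) {
  if (any(rate_specs$sd_rate < 0)) {
    stop("validation error: sd_rate must be >= 0", call. = FALSE)
  }
  set.seed(seed)
  stats::rnorm(nrow(rate_specs), mean = rate_specs$mean_rate, sd = rate_specs$sd_rate)
}

#' Run the Monte Carlo flux simulation for one scenario
#'
#' Trajectories are deterministic (baseline activity and scenario rules carry
#' no sampled uncertainty) and are computed once; each iteration then draws
#' per-unit rates and scales every activity's effective-activity vector by
#' its sampled rate. The result is a complete cube of annual fluxes indexed
#' by (iteration, activity series, year).
#'
#' @param bundle Validated input bundle from [read_inputs()].
#' @param scenario `"limited"`, `"moderate"` or `"ambitious"`.
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param seed Master seed; per-(scenario, iteration) substreams are derived
#'   from it.
#' @param n_years Simulation horizon.
#' @return An `iteration_cube`: list with `values` (array
#'   `n_iter x n_series x n_years`, MT CO2e per yr), `series` (tibble of
#'   county/activity keys per slice), `n_iter`, `seed`, `scenario`,
#'   `n_sign_flips` (count of draws whose sign differs from the mean rate's).
#' @export
run_simulation <- function(bundle, scenario, n_iter = 1000, seed = 1,
                           n_years = ncs_n_years()) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  derived <- derive_baselines(bundle, quiet = TRUE)
  params <- scenario_params_with_overrides(bundle$scenario_params)
  traj <- build_trajectories(derived, scenario, params, n_years = n_years)
  det <- deterministic_flux(traj, bundle$age_profiles)

  specs <- det |>
    dplyr::distinct(
      .data$pathway, .data$sub_activity, .data$ownership,
      .data$rate_region, .data$mean_rate, .data$sd_rate
    )
  spec_ids <- paste(
    key_id(specs$pathway, specs$sub_activity, specs$ownership),
    specs$rate_region
  )
  row_spec <- match(
    paste(key_id(det$pathway, det$sub_activity, det$ownership), det$rate_region),
    spec_ids
  )

  n_series <- nrow(det)
  eff <- matrix(unlist(det$effective), nrow = n_series, byrow = TRUE)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = nrow(specs))
  for (i in seq_len(n_iter)) {
    draws[i, ] <- draw_rates(specs, iteration_seed(seed, scenario, i))
  }
  n_sign_flips <- sum(sweep(sign(draws), 2, sign(specs$mean_rate), `*`) < 0)

  values <- array(0, dim = c(n_iter, n_series, n_years))
  for (r in seq_len(n_series)) {
    values[, r, ] <- draws[, row_spec[r]] %o% eff[r, ]
  }
  structure(
    list(
      values = values,
      series = det |>
        dplyr::select(
          "county_id", "pathway", "sub_activity", "ownership", "scenario"
        ),
      n_iter = n_iter,
      n_years = n_years,
      seed = seed,
      scenario = scenario,
      n_sign_flips = n_sign_flips,
      deterministic = det
    ),
    class = "iteration_cube"
  )
}

#' @export
print.iteration_cube <- function(x, ...) {
  cat(sprintf(
    "<iteration_cube> scenario=%s, %d iterations x %d series x %d years (seed %s)\n",
    x$scenario, x$n_iter, dim(x$values)[2], x$n_years, format(x$seed)
  ))
  invisible(x)
}

#' Quantile summaries of an iteration cube
#'
#' Per-iteration fluxes are summed over the requested grouping FIRST, and
#' quantiles are then taken over iterations, so a total's interval reflects
#' the joint distribution of all its pathways simultaneously - the median of
#' a total is not the sum of pathway medians. Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7);
#' `p05`/`p95` are the 5th and 95th percentiles of the signed flux, so for
#' emission reductions (negative values) `p05` is the most negative bound.
#' Values are converted from MT to MMT CO2e here, exactly once.
#'
#' @param cube An `iteration_cube` from [run_simulation()].
#' @param by Character vector of grouping keys from `county_id`, `pathway`,
#'   `sub_activity`, `ownership`. `character(0)` gives the statewide total;
#'   omit `county_id` for statewide per-pathway rows.
#' @param drop_pathways Optional pathway labels excluded before aggregation
#'   (used e.g. for totals without the timber pathway).
#' @return Tibble with `geography`, `pathway`, `sub_activity`, `scenario`,
#'   `year`, `median`, `p05`, `p95`, `cumulative_median` (MMT CO2e).
#' @export
summarize_iterations <- function(cube, by = character(0), drop_pathways = NULL) {
  stopifnot(inherits(cube, "iteration_cube"))
  if (dim(cube$values)[2] == 0) stop("empty cube", call. = FALSE)
  allowed <- c("county_id", "pathway", "sub_activity", "ownership")
  if (!all(by %in% allowed)) {
    stop(
      sprintf("grouping keys must be among: %s", paste(allowed, collapse = ", ")),
      call. = FALSE
    )
  }
  series <- cube$series
  keep <- rep(TRUE, nrow(series))
  if (!is.null(drop_pathways)) keep <- !(series$pathway %in% drop_pathways)
  if (!any(keep)) stop("no series left after drop_pathways", call. = FALSE)

  if (length(by) == 0) {
    groups <- tibble::tibble(.group = "all")
    gidx <- rep(1L, nrow(series))
  } else {
    key <- do.call(paste, c(series[by], sep = "\r"))
    groups <- series[!duplicated(key) & keep, by, drop = FALSE]
    groups$.group <- do.call(paste, c(groups[by], sep = "\r"))
    groups <- groups[!duplicated(groups$.group), , drop = FALSE]
    gidx <- match(key, groups$.group)
  }

  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- which(keep & (gidx == g | length(by) == 0))
    slab <- cube$values[, sel, , drop = FALSE]
    # iteration x year matrix of grouped sums (MT -> MMT)
    s <- colSums(aperm(slab, c(2, 1, 3))) / 1e6
    if (is.null(dim(s))) s <- matrix(s, nrow = cube$n_iter)
    cum <- t(apply(s, 1, cumsum))
    if (cube$n_years == 1) cum <- matrix(cum, ncol = 1)
    q <- apply(s, 2, stats::quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
    tibble::tibble(
      geography = if ("county_id" %in% by) as.character(groups$county_id[g]) else "statewide",
      pathway = if ("pathway" %in% by) groups$pathway[g] else "total",
      sub_activity = if ("sub_activity" %in% by) groups$sub_activity[g] else "",
      ownership = if ("ownership" %in% by) groups$ownership[g] else "na",
      scenario = cube$scenario,
      year = seq_len(cube$n_years),
      median = q[2, ],
      p05 = q[1, ],
      p95 = q[3, ],
      cumulative_median = apply(cum, 2, stats::median)
    )
  })
  dplyr::bind_rows(rows)
}

#' Run all three scenarios
#'
#' @inheritParams run_simulation
#' @param scenarios Scenario labels to run.
#' @return Named list of `iteration_cube`s.
#' @export
run_all_scenarios <- function(bundle, n_iter = 1000, seed = 1,
                              scenarios = ncs_scenarios(),
                              n_years = ncs_n_years()) {
  stats::setNames(
    lapply(scenarios, function(s) {
      run_simulation(bundle, s, n_iter = n_iter, seed = seed, n_years = n_years)
    }),
    scenarios
  )
}
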