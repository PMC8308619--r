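#' Statewide goal context
#'
#' The percent-of-goal metric divides final-year reductions by the most
#' recent statewide emissions inventory: 99.57 MMT CO2e (2018), with the
#' net zero target year 2050.
#'
#' @param statewide_emissions_baseline MMT CO2e per yr, > 0.
#' @param target_year Calendar target year.
#' @return List with `statewide_emissions_baseline` and `target_year`.
#' @export
goal_context <- function(statewide_emissions_baseline = 99.57, target_year = 2050) {
  if (statewide_emissions_baseline <= 0) {
    stop("validation error: emissions baseline must be > 0", call. = FALSE)
  }
  list(
    statewide_emissions_baseline = statewide_emissions_baseline,
    target_year = target_year
  )
}

#' Percent of the statewide emissions-reduction goal
#'
#' `|total reduction| / statewide baseline x 100`. The display value is
#' rounded to one decimal; the unrounded value is retained alongside.
#'
#' @param total_reduction_mmt Final-year total reduction, MMT CO2e per yr
#'   (signed; negative = reduction).
#' @param context A [goal_context()].
#' @return List with `percent` (unrounded) and `display` (1-decimal).
#' @export
percent_of_goal <- function(total_reduction_mmt, context = goal_context()) {
  pct <- abs(total_reduction_mmt) / context$statewide_emissions_baseline * 100
  list(percent = pct, display = round(pct, 1))
}

#' Pathway shares of the total median reduction
#'
#' Share = pathway median / total median x 100, rounded to whole percent for
#' display. Because the total's median is computed from the joint
#' distribution (not by summing pathway medians), shares need not sum to
#' exactly 100.
#'
#' @param summary_rows Tibble of final-year summary rows containing every
#'   pathway plus a `"total"` row for one scenario (columns `pathway`,
#'   `median`).
#' @return Tibble with `pathway`, `share` (unrounded %), `display` (integer
#'   %), sorted by descending share.
#' @export
pathway_shares <- function(summary_rows) {
  tot <- summary_rows$median[summary_rows$pathway == "total"]
  if (length(tot) != 1) {
    stop("missing (or duplicated) total row", call. = FALSE)
  }
  out <- summary_rows |>
    dplyr::filter(.data$pathway != "total") |>
    dplyr::mutate(
      share = .data$median / tot * 100,
      display = round(.data$share)
    ) |>
    dplyr::arrange(dplyr::desc(.data$share))
  out[, c("pathway", "share", "display")]
}

#' Per-area emissions-reduction intensity by county
#'
#' @param county_totals Named numeric vector of final-year county totals
#'   (MMT CO2e per yr), names = county ids.
#' @param county_areas Named numeric vector of county areas (ha), > 0.
#' @return Tibble with `county_id`, `total_mmt`, `area_ha`,
#'   `intensity` (MMT CO2e per yr per ha), ranked by |intensity| descending.
#' @export
per_area_intensity <- function(county_totals, county_areas) {
  if (any(county_areas <= 0)) {
    stop("validation error: county area must be > 0", call. = FALSE)
  }
  areas <- county_areas[names(county_totals)]
  if (anyNA(areas)) stop("missing county area", call. = FALSE)
  out <- tibble::tibble(
    county_id = names(county_totals),
    total_mmt = as.numeric(county_totals),
    area_ha = as.numeric(areas),
    intensity = as.numeric(county_totals) / as.numeric(areas)
  )
  out[order(-abs(out$intensity), out$county_id), ]
}

#' Smallest set of counties covering a share of a pathway's reductions
#'
#' Counties are sorted by reduction magnitude (ties broken by county id
#' ascending) and the shortest prefix whose summed magnitude reaches
#' `coverage` of the statewide pathway magnitude is returned - the model's
#' notion of a pathway's geographic cluster.
#'
#' @param county_medians Named numeric vector of one pathway's final-year
#'   county medians (signed), names = county ids.
#' @param coverage Fraction of the statewide |median| to cover, in (0, 1].
#' @return Character vector of county ids (possibly empty, with a warning,
#'   when the pathway is all zero).
#' @export
cluster_top_counties <- function(county_medians, coverage = 0.5) {
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  mag <- abs(county_medians)
  total <- sum(mag)
  if (total == 0) {
    warning("all-zero pathway; empty cluster")
    return(character(0))
  }
  ord <- order(-mag, names(county_medians))
  csum <- cumsum(mag[ord])
  n_take <- which(csum >= coverage * total - 1e-12)[1]
  names(county_medians)[ord][seq_len(n_take)]
}

#' Render the tabular report set
#'
#' Writes the final-year analogues of the headline outputs:
#' `table2.csv` (pathway x scenario medians and intervals),
#' `county_totals.csv` (per-county totals with and without the timber
#' pathway, both re-aggregated from the iteration cubes),
#' `pathway_by_county.csv`, `shares.csv`, `clusters.csv`, `intensity.csv`.
#' All content is deterministic given the cubes.
#'
#' @param cubes Named list of `iteration_cube`s (one per scenario).
#' @param counties County table (for areas).
#' @param context A [goal_context()].
#' @param outdir Output directory (created if needed).
#' @param cluster_pathways Pathways to emit clusters for (default: the three
#'   largest by ambitious-scenario magnitude).
#' @return Invisible named character vector of the files written.
#' @export
render_reports <- function(cubes, counties, context = goal_context(),
                           outdir = ".", cluster_pathways = NULL) {
  if (length(cubes) == 0) stop("no cubes supplied", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  final_year <- cubes[[1]]$n_years

  by_pathway <- dplyr::bind_rows(lapply(cubes, summarize_iterations, by = "pathway"))
  totals <- dplyr::bind_rows(lapply(cubes, summarize_iterations))
  table2 <- dplyr::bind_rows(by_pathway, totals) |>
    dplyr::filter(.data$year == final_year) |>
    dplyr::arrange(.data$scenario, .data$median)

  county_tot <- dplyr::bind_rows(lapply(cubes, summarize_iterations, by = "county_id")) |>
    dplyr::filter(.data$year == final_year) |>
    dplyr::rename(total_all = "median") |>
    dplyr::select("geography", "scenario", "total_all")
  county_tot_nt <- dplyr::bind_rows(
    lapply(cubes, summarize_iterations, by = "county_id", drop_pathways = "timber")
  ) |>
    dplyr::filter(.data$year == final_year) |>
    dplyr::rename(total_no_timber = "median") |>
    dplyr::select("geography", "scenario", "total_no_timber")
  county_totals <- dplyr::left_join(county_tot, county_tot_nt,
    by = c("geography", "scenario")
  )

  pbc <- dplyr::bind_rows(
    lapply(cubes, summarize_iterations, by = c("county_id", "pathway"))
  ) |>
    dplyr::filter(.data$year == final_year)

  shares <- dplyr::bind_rows(lapply(names(cubes), function(s) {
    rows <- dplyr::bind_rows(
      by_pathway |> dplyr::filter(.data$scenario == s, .data$year == final_year),
      totals |> dplyr::filter(.data$scenario == s, .data$year == final_year)
    )
    tot <- rows$median[rows$pathway == "total"]
    pathway_shares(rows) |>
      dplyr::mutate(
        scenario = s,
        percent_of_goal = percent_of_goal(tot, context)$display
      )
  }))

  amb <- if ("ambitious" %in% names(cubes)) "ambitious" else names(cubes)[1]
  amb_rows <- pbc |> dplyr::filter(.data$scenario == amb)
  if (is.null(cluster_pathways)) {
    path_mag <- by_pathway |>
      dplyr::filter(.data$scenario == amb, .data$year == final_year) |>
      dplyr::arrange(.data$median)
    cluster_pathways <- utils::head(path_mag$pathway, 3)
  }
  clusters <- dplyr::bind_rows(lapply(cluster_pathways, function(p) {
    rows <- amb_rows |> dplyr::filter(.data$pathway == p)
    med <- stats::setNames(rows$median, rows$geography)
    ids <- suppressWarnings(cluster_top_counties(med, coverage = 0.5))
    if (length(ids) == 0) {
      return(tibble::tibble(
        pathway = character(0), rank = integer(0), county_id = character(0)
      ))
    }
    tibble::tibble(pathway = p, rank = seq_along(ids), county_id = ids)
  }))

  amb_tot <- county_tot |> dplyr::filter(.data$scenario == amb)
  intensity <- per_area_intensity(
    stats::setNames(amb_tot$total_all, amb_tot$geography),
    stats::setNames(counties$area_ha, as.character(counties$county_id))
  )

  files <- c(
    table2 = "table2.csv", county_totals = "county_totals.csv",
    pathway_by_county = "pathway_by_county.csv", shares = "shares.csv",
    clusters = "clusters.csv", intensity = "intensity.csv"
  )
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  readr::write_csv(table2, paths["table2"], progress = FALSE)
  readr::write_csv(county_totals, paths["county_totals"], progress = FALSE)
  readr::write_csv(pbc, paths["pathway_by_county"], progress = FALSE)
  readr::write_csv(shares, paths["shares"], progress = FALSE)
  readr::write_csv(clusters, paths["clusters"], progress = FALSE)
  readr::write_csv(intensity, paths["intensity"], progress = FALSE)
  invisible(paths)
}

#' Published final-year results table
#'
#' The printed pathway x scenario medians and 5th/95th-percentile bounds of
#' the final simulation year (ca. 2050), transcribed from the published
#' results table. `ci_narrow` is the least-negative printed bound and
#' `ci_wide` the most negative. Used by the derived-arithmetic checks
#' (percent of goal, pathway shares), which need no model inputs.
#'
#' @return Tibble with `pathway`, `scenario`, `median`, `ci_narrow`,
#'   `ci_wide` (MMT CO2e per yr).
#' @export
published_table2 <- function() {
  path <- system.file("extdata", "table2_published.csv", package = "ncspath")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
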