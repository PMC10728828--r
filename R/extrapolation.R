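# National and global extrapolation of institute-level emissions.
#
# Pathology case counts are not registered nationally or globally, so the
# number of pathology cases in a region is estimated from its cancer-case
# count by cross multiplication with an institute anchor: the institute's
# ratio of total pathology cases to cancer cases. Per-case emissions
# (institute mean tile workload x scenario energy) then scale to region
# totals through the region's grid intensity.

#' Institute anchor for case-count extrapolation
#'
#' Defaults encode a university-hospital pathology institute with 4 804
#' cancer cases among 40 356 total cases in one year, i.e. about 8.4
#' pathology cases per cancer case. An alternative reading of the source
#' counts (total = 35 552) can be configured but does not reproduce the
#' published German extrapolation.
#'
#' @param cancer_cases Cancer cases at the institute.
#' @param total_cases Total pathology cases at the institute
#'   (>= `cancer_cases`).
#' @param mean_tiles_per_case Named vector of mean tiles per case by input
#'   mode (e.g. `c(wsi = ..., tissue = ..., roi = ...)`), typically computed
#'   from a cohort workload.
#' @return Object of class `institute_anchor`.
#' @export
institute_anchor <- function(cancer_cases = 4804, total_cases = 40356,
                             mean_tiles_per_case = NULL) {
  assert_number(cancer_cases, "cancer_cases", lower = 1)
  assert_number(total_cases, "total_cases", lower = 1)
  if (total_cases < cancer_cases) {
    stop("total_cases must be >= cancer_cases", call. = FALSE)
  }
  structure(list(cancer_cases = cancer_cases, total_cases = total_cases,
                 mean_tiles_per_case = mean_tiles_per_case),
            class = "institute_anchor")
}

#' Mean tiles per case from a cohort, per input mode
#'
#' @param cohort A `cohort`.
#' @param tile_edge_px Tile edge in pixels.
#' @return Named vector with elements `wsi`, `tissue`, `roi`.
#' @export
mean_tiles_per_case <- function(cohort, tile_edge_px = 512L) {
  vapply(c(wsi = "wsi", tissue = "tissue", roi = "roi"), function(m) {
    wl <- cohort_workload(cohort, tiling_spec(tile_edge_px, m))
    mean(wl$per_case$tiles)
  }, numeric(1))
}

#' Extrapolate a region's pathology case count
#'
#' Cross multiplication in the proportion:
#' `region_cancer_cases * total_cases / cancer_cases`, rounded to the
#' nearest integer. Linear in the region's cancer-case count.
#'
#' @param region_cancer_cases Yearly cancer cases in the region.
#' @param anchor An [institute_anchor()].
#' @return Estimated total pathology cases (integer-valued).
#' @export
#' @examples
#' # 552 800 cancer cases with the default anchor: about 4.64 million
#' extrapolate_case_count(552800, institute_anchor())
extrapolate_case_count <- function(region_cancer_cases, anchor = institute_anchor()) {
  if (any(region_cancer_cases <= 0)) {
    stop("region_cancer_cases must be positive", call. = FALSE)
  }
  round(region_cancer_cases * anchor$total_cases / anchor$cancer_cases)
}

#' Read a region table
#'
#' Columns: `region`, `cancer_cases_per_year`, `renewable_share` (optional,
#' blank allowed), `intensity_kg_per_kwh` (optional; takes precedence over
#' the share-derived value), `forest_area_km2`. The packaged fixture
#' (`regions_synthetic.csv`) is synthetic: only its structure, not its
#' figures, should be taken as data.
#'
#' @param path CSV path; defaults to the packaged synthetic fixture.
#' @return Data frame of region statistics.
#' @export
read_region_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "regions_synthetic.csv",
                                package = "carbonpath")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("region", "cancer_cases_per_year", "forest_area_km2"),
                 "region CSV")
  if (anyDuplicated(df$region)) {
    stop("duplicate region names in region table", call. = FALSE)
  }
  df
}

region_intensity <- function(region, constants) {
  direct <- region$intensity_kg_per_kwh
  if (!is.null(direct) && length(direct) == 1L && is.finite(direct) && !is.na(direct)) {
    return(direct)
  }
  share <- region$renewable_share
  if (is.null(share) || is.na(share)) {
    stop(sprintf("region '%s' has neither a direct intensity nor a renewable share",
                 region$region), call. = FALSE)
  }
  intensity_from_mix(share, constants)
}

#' Emissions of one region under a scenario
#'
#' Per-case energy (institute mean tiles for the scenario's input mode times
#' the scenario's summed task energies) multiplied by the extrapolated case
#' count and the region's grid intensity. The bootstrap resamples the
#' institute's per-case tile counts with replacement (the cohort is a
#' sample) and jitters task energies log-normally.
#'
#' @param region One-row data frame (or list) with `region`,
#'   `cancer_cases_per_year`, `forest_area_km2` and either
#'   `intensity_kg_per_kwh` or `renewable_share`.
#' @param anchor [institute_anchor()] carrying `mean_tiles_per_case`.
#' @param scen A [scenario()].
#' @param size_classes Output of [select_size_classes()].
#' @param constants [model_constants()].
#' @param multitask_kwh Multitask energy (see [scenario_emission()]).
#' @param case_tiles Optional vector of institute per-case tile counts in
#'   the scenario's input mode, used to bootstrap the mean workload.
#' @param noise_sd,n_boot,seed Bootstrap controls.
#' @return An `emission_result` with the extrapolated case count attached
#'   as `$n_cases` and forest fractions for the region and the world.
#' @export
region_emission <- function(region, anchor, scen, size_classes,
                            constants = model_constants(), multitask_kwh = NULL,
                            case_tiles = NULL, noise_sd = 0.02, n_boot = 2000,
                            seed = 1L) {
  intensity <- region_intensity(region, constants)
  n_cases <- extrapolate_case_count(region$cancer_cases_per_year, anchor)
  mt <- anchor$mean_tiles_per_case
  if (is.null(mt)) stop("anchor carries no mean_tiles_per_case", call. = FALSE)
  mtc <- if (length(mt) > 1L) mt[[scen$input_mode]] else mt
  e <- resolve_task_energies(scen, size_classes, multitask_kwh)

  kwh_task <- n_cases * mtc * e / constants$reference_tiles
  kg_task <- kwh_task * intensity
  total_kg <- sum(kg_task)
  ci <- c(total_kg, total_kg)
  if (n_boot > 0) {
    set.seed(substream_seed(seed, paste0("region-", region$region)))
    k <- length(e)
    draws <- vapply(seq_len(n_boot), function(b) {
      mtc_b <- if (!is.null(case_tiles)) {
        mean(sample(case_tiles, length(case_tiles), replace = TRUE))
      } else mtc
      jitter <- exp(stats::rnorm(k, 0, noise_sd))
      sum(n_cases * mtc_b * e * jitter / constants$reference_tiles) * intensity
    }, numeric(1))
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  forest_km2 <- region$forest_area_km2
  region_forest <- NULL
  if (!is.null(forest_km2) && is.finite(forest_km2) && forest_km2 > 0) {
    region_forest <- stats::setNames(forest_km2, region$region)
  }
  res <- structure(list(energy_kwh = sum(kwh_task),
                        co2eq_kg = total_kg,
                        ci95_kg = ci,
                        per_task_kg = kg_task,
                        offsets = offset_equivalents(total_kg, constants, region_forest)),
                   class = "emission_result")
  res$n_cases <- n_cases
  res$region <- region$region
  res
}

#' Per-region emission table and world total
#'
#' Runs [region_emission()] for every region, sorts by emission descending
#' and attaches the world total (sum of region totals) with its world-forest
#' equivalents.
#'
#' @param regions Region data frame (see [read_region_table()]).
#' @inheritParams region_emission
#' @return Data frame with columns `region`, `cases`, `co2eq_t`, `ci_low_t`,
#'   `ci_high_t`, `forest_km2`, `world_forest_fraction`, sorted by
#'   `co2eq_t` descending, with attribute `world` = list(`co2eq_t`,
#'   `forest_km2`, `world_forest_fraction`, `cases`).
#' @export
world_table <- function(regions, anchor, scen, size_classes,
                        constants = model_constants(), multitask_kwh = NULL,
                        case_tiles = NULL, noise_sd = 0.02, n_boot = 2000,
                        seed = 1L) {
  if (nrow(regions) == 0L) stop("empty region list", call. = FALSE)
  if (anyDuplicated(regions$region)) {
    stop("duplicate region names in region table", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    res <- region_emission(r, anchor, scen, size_classes, constants,
                           multitask_kwh = multitask_kwh, case_tiles = case_tiles,
                           noise_sd = noise_sd, n_boot = n_boot, seed = seed)
    data.frame(region = r$region,
               cases = res$n_cases,
               co2eq_t = res$co2eq_kg / 1000,
               ci_low_t = res$ci95_kg[1] / 1000,
               ci_high_t = res$ci95_kg[2] / 1000,
               forest_km2 = res$offsets$forest_km2,
               world_forest_fraction = res$offsets$forest_fraction[["world"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$co2eq_t), , drop = FALSE]
  rownames(tab) <- NULL
  world_kg <- sum(tab$co2eq_t) * 1000
  off <- offset_equivalents(world_kg, constants)
  attr(tab, "world") <- list(co2eq_t = world_kg / 1000,
                             forest_km2 = off$forest_km2,
                             world_forest_fraction = off$forest_fraction[["world"]],
                             cases = sum(tab$cases))
  tab
}

#' Survey-based underestimation factor
#'
#' Ratio of a survey-based national case count to the extrapolated count;
#' quantifies how far the cancer-anchored extrapolation understates true
#' pathology volume (for Germany, about 3.8).
#'
#' @param survey_cases Survey-based national case count.
#' @param extrapolated_cases Model-extrapolated national case count.
#' @return The ratio (survey / extrapolated).
#' @export
underestimation_factor <- function(survey_cases, extrapolated_cases) {
  if (extrapolated_cases <= 0) stop("extrapolated_cases must be > 0", call. = FALSE)
  survey_cases / extrapolated_cases
}
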