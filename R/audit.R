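# End-to-end audit driver and published-arithmetic checks.
#
# run_audit() ties the modules together: cohort -> workloads -> calibration
# -> scenario emissions -> national/global extrapolation -> 2023-2052
# projection, writing machine-readable reports plus a provenance block.
# Outputs are pure functions of (config, input tables, seed).

#' Default audit configuration
#'
#' Returns the packaged demo configuration (see
#' `system.file("extdata", "demo_config.yaml", package = "carbonpath")`)
#' with any named overrides applied.
#'
#' @param ... Named overrides of top-level config fields.
#' @return Config list.
#' @export
audit_config <- function(...) {
  cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                     package = "carbonpath"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

build_cohort <- function(cfg) {
  if (!is.null(cfg$cohort_csv)) return(read_cohort_csv(cfg$cohort_csv))
  cc <- cfg$cohort %||% list()
  generate_cohort(cohort_config(
    n_cases = c(prostate = cc$n_prostate_cases %||% 5,
                breast = cc$n_breast_cases %||% 8),
    filesize_model = list(coef_a = 30, exponent_b = 0.8,
                          target_correlation = cc$target_correlation %||% 0.58),
    seed = cfg$seed %||% 1L))
}

num_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a full emission audit
#'
#' Executes the whole pipeline on the configured (or packaged demo) tables
#' and writes, under `out_dir`: `emission_report.csv`/`.json` (one row per
#' scenario x input mode x size class), `world_report.csv`, a projection
#' report, a scanner line if a scanner block is configured, the
#' published-arithmetic check table, a Markdown summary, and
#' `provenance.json` recording package version, seed and the constants
#' actually used.
#'
#' @param config Config list (see [audit_config()]) or a YAML path.
#' @param out_dir Output directory (created if absent); overrides the
#'   config's `out_dir`; defaults to a fresh temporary directory.
#' @param seed Optional seed override.
#' @return Invisibly, a list with every computed component and the report
#'   paths.
#' @export
run_audit <- function(config = audit_config(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("carbonpath_audit_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  constants <- do.call(model_constants, cfg$constants %||% list())
  cohort <- build_cohort(cfg)
  issues <- validate_cohort(cohort)
  if (nrow(issues)) {
    stop(sprintf("cohort validation failed (%d issue(s)); first: %s %s",
                 nrow(issues), issues$id[1], issues$problem[1]), call. = FALSE)
  }
  calibration <- read_model_calibration(cfg$calibration_csv)
  sizes <- select_size_classes(calibration, cfg$device_name)
  fit <- fit_param_energy(calibration, cfg$device_name,
                          n_boot = cfg$n_boot %||% 2000, seed = cfg$seed)
  multitask <- estimate_multitask_energy(fit)

  edge <- cfg$tile_edge_px %||% 512L
  workloads <- lapply(c(wsi = "wsi", tissue = "tissue", roi = "roi"),
                      function(m) cohort_workload(cohort, tiling_spec(edge, m)))
  intensity_de <- 0.40  # direct grid intensity used for the institute runs
  regions <- read_region_table(cfg$region_csv)
  de_row <- regions[regions$region == "Germany", ]
  if (nrow(de_row) == 1L && is.finite(de_row$intensity_kg_per_kwh)) {
    intensity_de <- de_row$intensity_kg_per_kwh
  }

  grid <- expand.grid(scenario = cfg$scenarios %||% "one_task",
                      input_mode = cfg$input_modes %||% "wsi",
                      size_class = cfg$size_classes %||% "large",
                      stringsAsFactors = FALSE)
  # the multitask scenario has no size class: collapse it to one row per mode
  grid$size_class[grid$scenario == "multitask"] <- "large"
  grid <- unique(grid)
  emission_rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    scen <- scenario(g$scenario, g$input_mode, g$size_class)
    res <- scenario_emission(workloads[[g$input_mode]], scen, sizes, intensity_de,
                             constants, multitask_kwh = multitask,
                             noise_sd = cfg$noise_sd %||% 0.02,
                             n_boot = cfg$n_boot %||% 2000, seed = cfg$seed)
    data.frame(scenario = g$scenario, input_mode = g$input_mode,
               size_class = g$size_class,
               energy_kwh = res$energy_kwh, co2eq_kg = res$co2eq_kg,
               ci_low_kg = res$ci95_kg[1], ci_high_kg = res$ci95_kg[2],
               trees = res$offsets$trees, forest_km2 = res$offsets$forest_km2,
               world_forest_fraction = res$offsets$forest_fraction[["world"]],
               stringsAsFactors = FALSE)
  })
  emission_report <- do.call(rbind, emission_rows)

  anchor <- institute_anchor(mean_tiles_per_case = mean_tiles_per_case(cohort, edge))
  ex_mode <- cfg$extrapolation_mode %||% "tissue"
  ex_scen <- scenario(cfg$extrapolation_scenario %||% "multitask", ex_mode)
  case_tiles <- workloads[[ex_mode]]$per_case$tiles
  world <- world_table(regions, anchor, ex_scen, sizes, constants,
                       multitask_kwh = multitask, case_tiles = case_tiles,
                       noise_sd = cfg$noise_sd %||% 0.02,
                       n_boot = cfg$n_boot %||% 2000, seed = cfg$seed)

  yr <- cfg$projection_years %||% c(2023, 2052)
  years <- seq(yr[[1]], yr[[2]])
  drivers <- fit_all_drivers(read_driver_anchors(cfg$driver_csv), years = years,
                             n_boot = cfg$n_boot %||% 2000, seed = cfg$seed)
  world_kg <- attr(world, "world")$co2eq_t * 1000
  projection <- combine_projection(world_kg, years[1], drivers, constants)
  projection_report <- data.frame(
    year = rep(projection$years, 3),
    path = rep(c("best", "mean", "worst"), each = length(projection$years)),
    co2eq_t = c(projection$best, projection$mean, projection$worst) / 1000,
    forest_fraction = c(projection$forest_fraction$best,
                        projection$forest_fraction$mean,
                        projection$forest_fraction$worst))

  scanner <- NULL
  if (!is.null(cfg$scanner)) {
    s <- cfg$scanner
    scanner <- scanner_emission(s$n_slides, s$power_w, s$minutes_per_slide,
                                s$intensity_kg_per_kwh)
  }
  checks <- run_published_checks(constants)

  paths <- list(
    emission_csv = file.path(out_dir, "emission_report.csv"),
    emission_json = file.path(out_dir, "emission_report.json"),
    world_csv = file.path(out_dir, "world_report.csv"),
    projection_csv = file.path(out_dir, "projection_report.csv"),
    checks_csv = file.path(out_dir, "published_checks.csv"),
    summary_md = file.path(out_dir, "summary.md"),
    provenance = file.path(out_dir, "provenance.json"))
  num_csv(emission_report, paths$emission_csv)
  jsonlite::write_json(emission_report, paths$emission_json,
                       dataframe = "rows", digits = NA)
  num_csv(world, paths$world_csv)
  num_csv(projection_report, paths$projection_csv)
  num_csv(checks, paths$checks_csv)
  provenance <- list(package = "carbonpath",
                     version = as.character(utils::packageVersion("carbonpath")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."),
                     seed = cfg$seed,
                     constants = unclass(constants),
                     n_boot = cfg$n_boot %||% 2000,
                     noise_sd = cfg$noise_sd %||% 0.02)
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE, digits = NA)

  md <- c("# carbonpath audit summary", "",
          sprintf("Seed: %d. Cohort: %d cases, %d slides.", cfg$seed,
                  nrow(cohort$cases), nrow(cohort$slides)),
          sprintf("Grid intensity (institute runs): %.3g kg CO2eq/kWh.", intensity_de),
          "",
          sprintf("Scenario grid rows: %d (see emission_report.csv).",
                  nrow(emission_report)),
          sprintf("World total (%s, %s mode): %.4g t CO2eq across %d regions.",
                  ex_scen$name, ex_mode, attr(world, "world")$co2eq_t, nrow(world)),
          if (!is.null(scanner))
            sprintf("Scanner emissions: %.4g kg CO2eq.", scanner),
          sprintf("Projection worst-path forest exceedance year: %s.",
                  format(forest_exceedance_year(projection, "worst"))))
  writeLines(md[!vapply(md, is.null, logical(1))], paths$summary_md)

  invisible(list(config = cfg, cohort = cohort, calibration = calibration,
                 size_classes = sizes, fit = fit, multitask = multitask,
                 workloads = workloads, emission_report = emission_report,
                 anchor = anchor, world = world, drivers = drivers,
                 projection = projection, scanner_kg = scanner,
                 checks = checks, paths = paths, out_dir = out_dir))
}

#' Recompute the published desk-scale arithmetic
#'
#' Reproduces, from the packaged constants alone, the arithmetic results
#' that do not depend on unpublished per-model energy measurements: scanner
#' emissions (237 179 slides, 580 W, 1 min/slide at 0.4 kg/kWh -> about
#' 917 kg), the German pathology-case extrapolation (552 800 cancer cases
#' with the 4 804 / 40 356 anchor -> about 4.64 million), the survey
#' underestimation factor (17 550 000 survey cases over the extrapolated
#' count -> about 3.8), the single-tree unit (21.8 kg -> 1 tree) and the
#' forest area for a 16 Mt emission. Report-only: never throws.
#'
#' @param constants [model_constants()].
#' @return Data frame with columns `check`, `computed`, `reference`,
#'   `rel_diff`.
#' @export
run_published_checks <- function(constants = model_constants()) {
  anchor <- institute_anchor()
  german_cases <- extrapolate_case_count(552800, anchor)
  rows <- list(
    list(check = "scanner_co2eq_kg",
         computed = scanner_emission(237179, 580, 1, 0.4), reference = 917),
    list(check = "german_total_cases",
         computed = german_cases, reference = 4643837),
    list(check = "survey_underestimation_factor",
         computed = round(underestimation_factor(17550000, german_cases), 1),
         reference = 3.8),
    list(check = "trees_for_one_tree_unit",
         computed = trees_required(constants$tree_uptake_kg_per_year, constants),
         reference = 1),
    list(check = "forest_km2_for_16Mt",
         computed = forest_area_required(16e6, constants)$km2, reference = 86590))
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(check = r$check, computed = r$computed, reference = r$reference,
               rel_diff = abs(r$computed - r$reference) / abs(r$reference),
               stringsAsFactors = FALSE)
  }))
  df
}
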