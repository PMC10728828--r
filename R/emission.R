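# Emission accounting: energy -> CO2-equivalents -> sequestration offsets.
#
# The core identity is linear: for one task,
#   kg CO2eq = tiles * (kWh per 1e7 tiles / 1e7) * grid intensity (kg/kWh),
# and a deployment scenario is a sum of such tasks. Uncertainty enters as
# multiplicative log-normal jitter on per-run energy (the run-to-run
# measurement noise of the power tracker) and, optionally, resampling of
# cases to propagate workload variability.

#' Physical and accounting constants
#'
#' Sequestration constants: a mature tree absorbs about 21.8 kg CO2eq per
#' year; the world's forests sequester about 7.6 Gt CO2eq per year over
#' about 40.6 million km2 (hence about 187.2 t per km2 per year). Grid
#' intensities: defaults of 0.70 kg/kWh for a fossil-dominated grid and
#' 0.03 kg/kWh for a fully renewable one, blended linearly by renewable
#' share when no direct intensity is available.
#'
#' @param tree_uptake_kg_per_year kg CO2eq one mature tree absorbs per year.
#' @param world_forest_capacity_t Yearly world-forest sequestration capacity
#'   in metric tons.
#' @param world_forest_area_km2 World forest area in km2.
#' @param reference_tiles Reference workload used for energy normalisation.
#' @param intensity_fossil_kg_per_kwh,intensity_renewable_kg_per_kwh Grid
#'   intensity endpoints of the linear mix.
#' @return List of class `model_constants`.
#' @export
model_constants <- function(tree_uptake_kg_per_year = 21.8,
                            world_forest_capacity_t = 7.6e9,
                            world_forest_area_km2 = 40.6e6,
                            reference_tiles = 1e7,
                            intensity_fossil_kg_per_kwh = 0.70,
                            intensity_renewable_kg_per_kwh = 0.03) {
  vals <- c(tree_uptake_kg_per_year, world_forest_capacity_t,
            world_forest_area_km2, reference_tiles,
            intensity_fossil_kg_per_kwh, intensity_renewable_kg_per_kwh)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all model constants must be strictly positive", call. = FALSE)
  }
  if (intensity_renewable_kg_per_kwh >= intensity_fossil_kg_per_kwh) {
    stop("renewable intensity must be below fossil intensity", call. = FALSE)
  }
  structure(list(tree_uptake_kg_per_year = tree_uptake_kg_per_year,
                 world_forest_capacity_t = world_forest_capacity_t,
                 world_forest_area_km2 = world_forest_area_km2,
                 reference_tiles = reference_tiles,
                 intensity_fossil_kg_per_kwh = intensity_fossil_kg_per_kwh,
                 intensity_renewable_kg_per_kwh = intensity_renewable_kg_per_kwh),
            class = "model_constants")
}

#' Grid intensity from a renewable share
#'
#' Linear blend `share * renewable + (1 - share) * fossil`; strictly
#' decreasing in the share. Direct measured intensities (e.g. from a grid
#' database) should take precedence over this approximation where available.
#'
#' @param renewable_share Share of renewable generation, in \[0, 1\]
#'   (vectorised).
#' @param constants [model_constants()].
#' @return kg CO2eq per kWh.
#' @export
intensity_from_mix <- function(renewable_share, constants = model_constants()) {
  if (any(!is.finite(renewable_share)) || any(renewable_share < 0) ||
      any(renewable_share > 1)) {
    stop("renewable_share must lie in [0, 1]", call. = FALSE)
  }
  renewable_share * constants$intensity_renewable_kg_per_kwh +
    (1 - renewable_share) * constants$intensity_fossil_kg_per_kwh
}

#' Convert energy to CO2-equivalent mass
#'
#' @param energy_kwh Energy in kWh (>= 0, vectorised).
#' @param intensity_kg_per_kwh Grid intensity in kg CO2eq per kWh (>= 0).
#' @return kg CO2eq.
#' @export
energy_to_co2 <- function(energy_kwh, intensity_kg_per_kwh) {
  if (any(energy_kwh < 0) || any(intensity_kg_per_kwh < 0)) {
    stop("energy and intensity must be non-negative", call. = FALSE)
  }
  energy_kwh * intensity_kg_per_kwh
}

#' Trees needed to sequester an emission
#'
#' `ceiling(kg / uptake)`: a fraction of a tree cannot absorb the remainder,
#' so counts are rounded up; zero only for zero emissions.
#'
#' @param co2eq_kg Emission in kg (>= 0, vectorised).
#' @param constants [model_constants()].
#' @return Integer-valued tree count.
#' @export
trees_required <- function(co2eq_kg, constants = model_constants()) {
  if (any(co2eq_kg < 0)) stop("co2eq_kg must be >= 0", call. = FALSE)
  ceiling(co2eq_kg / constants$tree_uptake_kg_per_year)
}

#' Forest area needed to sequester an emission
#'
#' Divides tonnes by the per-km2 sequestration rate (world capacity over
#' world area, about 187.2 t/km2/yr) and expresses the area as a fraction
#' of a reference forest. Linear in tonnes.
#'
#' @param co2eq_t Emission in metric tons (>= 0, vectorised).
#' @param constants [model_constants()].
#' @param region_forest_area_km2 Forest area the fraction refers to
#'   (default: the world's).
#' @return List with `km2` and `fraction`.
#' @export
forest_area_required <- function(co2eq_t, constants = model_constants(),
                                 region_forest_area_km2 = constants$world_forest_area_km2) {
  if (any(co2eq_t < 0)) stop("co2eq_t must be >= 0", call. = FALSE)
  if (!is.numeric(region_forest_area_km2) || any(region_forest_area_km2 <= 0)) {
    stop("region_forest_area_km2 must be > 0", call. = FALSE)
  }
  rate_t_per_km2 <- constants$world_forest_capacity_t / constants$world_forest_area_km2
  km2 <- co2eq_t / rate_t_per_km2
  list(km2 = km2, fraction = km2 / region_forest_area_km2)
}

#' Slide-scanner emissions
#'
#' Emissions of digitising slides: `n_slides * minutes_per_slide / 60 *
#' power_w / 1000 * intensity`. With a 580 W scanner at one minute per
#' slide, a yearly throughput of 237 179 slides at 0.4 kg/kWh comes to
#' roughly 917 kg CO2eq.
#'
#' @param n_slides Number of slides scanned.
#' @param power_w Scanner power draw in watts.
#' @param minutes_per_slide Mean scan time per slide in minutes.
#' @param intensity_kg_per_kwh Grid intensity.
#' @return kg CO2eq.
#' @export
scanner_emission <- function(n_slides, power_w, minutes_per_slide,
                             intensity_kg_per_kwh) {
  for (v in c(n_slides, power_w, minutes_per_slide, intensity_kg_per_kwh)) {
    if (!is.finite(v) || v <= 0) stop("all scanner inputs must be positive", call. = FALSE)
  }
  n_slides * minutes_per_slide / 60 * power_w / 1000 * intensity_kg_per_kwh
}

#' Deployment scenario
#'
#' Task composition per pathology case. `one_task`: a single classifier
#' (current commercial practice). `two_task`: one classifier plus one
#' segmentation model. `seven_task`: a prospective automated workflow of
#' three segmentation tasks (tissue, ROI and instance annotation) and four
#' classification tasks (grading, molecular-alteration detection,
#' treatment-response prediction, survival analysis). `multitask`: a single
#' very large model handling all tasks in one pass. The composition is a
#' configurable default, not a fact about any particular product.
#'
#' @param name Scenario name.
#' @param input_mode Data-input mode the workload must be computed in.
#' @param size_class Model size class applied to every task (ignored for
#'   `multitask`).
#' @param tasks Optional data frame (`task`, `task_type`, `size_class`)
#'   overriding the default composition.
#' @return Object of class `scenario`.
#' @export
scenario <- function(name = c("one_task", "two_task", "seven_task", "multitask"),
                     input_mode = c("wsi", "tissue", "roi"),
                     size_class = c("large", "medium", "small"),
                     tasks = NULL) {
  name <- match.arg(name)
  input_mode <- match.arg(input_mode)
  size_class <- match.arg(size_class)
  if (is.null(tasks)) {
    tasks <- switch(name,
      one_task = data.frame(task = "diagnosis",
                            task_type = "classification", stringsAsFactors = FALSE),
      two_task = data.frame(task = c("diagnosis", "segmentation"),
                            task_type = c("classification", "segmentation"),
                            stringsAsFactors = FALSE),
      seven_task = data.frame(
        task = c("tissue_annotation", "roi_annotation", "instance_annotation",
                 "grading", "molecular_alteration", "treatment_response",
                 "survival"),
        task_type = c("segmentation", "segmentation", "segmentation",
                      "classification", "classification", "classification",
                      "classification"),
        stringsAsFactors = FALSE),
      multitask = data.frame(task = "multitask",
                             task_type = "multitask", stringsAsFactors = FALSE)
    )
    tasks$size_class <- size_class
  }
  n_expected <- c(one_task = 1L, two_task = 2L, seven_task = 7L, multitask = 1L)
  if (nrow(tasks) != n_expected[[name]]) {
    stop(sprintf("scenario '%s' must have %d task(s), got %d",
                 name, n_expected[[name]], nrow(tasks)), call. = FALSE)
  }
  structure(list(name = name, input_mode = input_mode,
                 size_class = size_class, tasks = tasks),
            class = "scenario")
}

# Map each scenario task to a kWh-per-1e7-tiles energy.
resolve_task_energies <- function(scen, size_classes, multitask_kwh = NULL) {
  tasks <- scen$tasks
  e <- numeric(nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    tt <- tasks$task_type[i]
    if (tt == "multitask") {
      if (is.null(multitask_kwh)) {
        stop("calibration missing: no multitask energy estimate supplied",
             call. = FALSE)
      }
      e[i] <- if (is.list(multitask_kwh)) multitask_kwh$point else multitask_kwh
    } else {
      sc <- tasks$size_class[i]
      prof <- size_classes[[tt]][[sc]]
      if (is.null(prof)) {
        stop(sprintf("calibration missing: no profile for task type '%s', size class '%s'",
                     tt, sc), call. = FALSE)
      }
      e[i] <- prof$kwh_per_1e7_tiles
    }
  }
  names(e) <- tasks$task
  e
}

# Shared emission engine: point estimate, percentile-bootstrap CI, offsets.
emission_engine <- function(task_kwh_per_ref, case_tiles, intensity, constants,
                            noise_sd = 0.02, n_boot = 2000, seed = 1L,
                            resample_cases = FALSE,
                            region_forest_km2 = NULL) {
  total_tiles <- sum(case_tiles)
  kwh_task <- total_tiles * task_kwh_per_ref / constants$reference_tiles
  kg_task <- kwh_task * intensity
  total_kg <- sum(kg_task)
  ci <- c(total_kg, total_kg)
  if (n_boot > 0 && total_tiles > 0) {
    set.seed(substream_seed(seed, "emission-boot"))
    k <- length(task_kwh_per_ref)
    draws <- vapply(seq_len(n_boot), function(b) {
      tiles_b <- if (resample_cases) {
        sum(sample(case_tiles, length(case_tiles), replace = TRUE))
      } else total_tiles
      jitter <- exp(stats::rnorm(k, 0, noise_sd))
      sum(tiles_b * task_kwh_per_ref * jitter / constants$reference_tiles) * intensity
    }, numeric(1))
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  structure(list(energy_kwh = sum(kwh_task),
                 co2eq_kg = total_kg,
                 ci95_kg = ci,
                 per_task_kg = kg_task,
                 offsets = offset_equivalents(total_kg, constants, region_forest_km2)),
            class = "emission_result")
}

offset_equivalents <- function(co2eq_kg, constants, region_forest_km2 = NULL) {
  fa <- forest_area_required(co2eq_kg / 1000, constants)
  fractions <- c(world = fa$fraction)
  if (!is.null(region_forest_km2)) {
    fr <- forest_area_required(co2eq_kg / 1000, constants,
                               region_forest_area_km2 = region_forest_km2)$fraction
    names(fr) <- names(region_forest_km2) %||% "region"
    fractions <- c(fractions, fr)
  }
  list(trees = trees_required(co2eq_kg, constants),
       forest_km2 = fa$km2,
       forest_fraction = fractions)
}

#' Emissions of a deployment scenario over a cohort workload
#'
#' Point estimate: for each task, `tiles_total * (kWh per 1e7 tiles / 1e7) *
#' intensity`, summed over the scenario's tasks. The 95% CI is a seeded
#' percentile bootstrap in which per-run energy is jittered log-normally
#' (`noise_sd`, default 0.02, reflecting run-to-run measurement noise);
#' optionally cases are also resampled with replacement to propagate
#' workload variability (`resample_cases = TRUE`, used by the extrapolation
#' layer where the workload is a sample, not a census).
#'
#' @param workload A [cohort_workload()] whose tiling mode matches
#'   `scen$input_mode`.
#' @param scen A [scenario()].
#' @param size_classes Output of [select_size_classes()].
#' @param intensity_kg_per_kwh Grid intensity.
#' @param constants [model_constants()].
#' @param multitask_kwh Energy for multitask tasks (number, or the list from
#'   [estimate_multitask_energy()]).
#' @param noise_sd Log-normal sd of per-run energy jitter.
#' @param n_boot Bootstrap draws (0 disables the CI).
#' @param seed Integer seed.
#' @param resample_cases Also resample cases with replacement in the
#'   bootstrap.
#' @param region_forest_km2 Optional named vector of regional forest areas
#'   for extra offset fractions.
#' @return Object of class `emission_result`: `energy_kwh`, `co2eq_kg`,
#'   `ci95_kg`, `per_task_kg`, `offsets` (trees, forest km2, forest
#'   fractions).
#' @export
scenario_emission <- function(workload, scen, size_classes, intensity_kg_per_kwh,
                              constants = model_constants(), multitask_kwh = NULL,
                              noise_sd = 0.02, n_boot = 2000, seed = 1L,
                              resample_cases = FALSE, region_forest_km2 = NULL) {
  stopifnot(inherits(workload, "cohort_workload"), inherits(scen, "scenario"))
  if (workload$tiling$mode != scen$input_mode) {
    stop(sprintf("workload mode '%s' does not match scenario input mode '%s'",
                 workload$tiling$mode, scen$input_mode), call. = FALSE)
  }
  e <- resolve_task_energies(scen, size_classes, multitask_kwh)
  emission_engine(e, workload$per_case$tiles, intensity_kg_per_kwh, constants,
                  noise_sd = noise_sd, n_boot = n_boot, seed = seed,
                  resample_cases = resample_cases,
                  region_forest_km2 = region_forest_km2)
}

#' Ratio of baseline to alternative emissions
#'
#' @param baseline,alternative `emission_result` objects or plain kg values.
#' @return `baseline / alternative` (1 when equal).
#' @export
reduction_factor <- function(baseline, alternative) {
  b <- if (inherits(baseline, "emission_result")) baseline$co2eq_kg else baseline
  a <- if (inherits(alternative, "emission_result")) alternative$co2eq_kg else alternative
  if (!is.finite(a) || a <= 0) {
    stop("alternative emission must be > 0 (division guard)", call. = FALSE)
  }
  b / a
}

#' Emissions of a pathomics workflow
#'
#' Pathomics replaces task-specific deep models with two sequential
#' inference passes over tissue tiles - tissue detection and segmentation -
#' followed by large-scale extraction of handcrafted morphological features
#' whose compute cost is modelled as a relative overhead (default 0):
#' `(detection pass + segmentation pass) * (1 + overhead_fraction)`.
#'
#' @param workload_tissue A tissue-mode [cohort_workload()].
#' @param segmentation_kwh_per_ref Segmentation-model energy in kWh per 1e7
#'   tiles (a UNet-2D-class model), or a profile list.
#' @param detection_kwh_per_ref Tissue-detection energy; `NULL` configures a
#'   single segmentation pass only.
#' @param overhead_fraction Relative feature-extraction overhead (>= 0).
#' @inheritParams scenario_emission
#' @return An `emission_result`.
#' @export
pathomics_emission <- function(workload_tissue, segmentation_kwh_per_ref,
                               detection_kwh_per_ref = NULL,
                               overhead_fraction = 0,
                               intensity_kg_per_kwh,
                               constants = model_constants(),
                               noise_sd = 0.02, n_boot = 2000, seed = 1L,
                               region_forest_km2 = NULL) {
  stopifnot(inherits(workload_tissue, "cohort_workload"))
  if (workload_tissue$tiling$mode != "tissue") {
    stop("pathomics requires a tissue-mode workload", call. = FALSE)
  }
  if (is.list(segmentation_kwh_per_ref)) {
    segmentation_kwh_per_ref <- segmentation_kwh_per_ref$kwh_per_1e7_tiles
  }
  if (is.null(segmentation_kwh_per_ref) || !is.finite(segmentation_kwh_per_ref)) {
    stop("calibration missing: no segmentation profile for pathomics", call. = FALSE)
  }
  assert_number(overhead_fraction, "overhead_fraction", lower = 0)
  e <- c(segmentation = segmentation_kwh_per_ref)
  if (!is.null(detection_kwh_per_ref)) {
    if (is.list(detection_kwh_per_ref)) {
      detection_kwh_per_ref <- detection_kwh_per_ref$kwh_per_1e7_tiles
    }
    e <- c(tissue_detection = detection_kwh_per_ref, e)
  }
  emission_engine(e * (1 + overhead_fraction), workload_tissue$per_case$tiles,
                  intensity_kg_per_kwh, constants, noise_sd = noise_sd,
                  n_boot = n_boot, seed = seed,
                  region_forest_km2 = region_forest_km2)
}

#' @export
print.emission_result <- function(x, ...) {
  cat(sprintf("Emission result: %.4g kg CO2eq (95%% CI %.4g-%.4g), %.4g kWh\n",
              x$co2eq_kg, x$ci95_kg[1], x$ci95_kg[2], x$energy_kwh))
  cat(sprintf("  offsets: %d tree(s), %.4g km2 forest (%.3g%% of world forest)\n",
              x$offsets$trees, x$offsets$forest_km2,
              100 * x$offsets$forest_fraction[["world"]]))
  invisible(x)
}
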