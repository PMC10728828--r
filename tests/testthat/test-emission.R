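test_that("grid intensity is a linear mix, decreasing in renewable share", {
  expect_equal(intensity_from_mix(1), 0.03)
  expect_equal(intensity_from_mix(0), 0.70)
  expect_equal(intensity_from_mix(0.462), 0.462 * 0.03 + 0.538 * 0.70)
  expect_equal(round(intensity_from_mix(0.462), 2), 0.39)
  shares <- seq(0, 1, by = 0.1)
  expect_true(all(diff(intensity_from_mix(shares)) < 0))
  expect_error(intensity_from_mix(1.2), "\\[0, 1\\]")
})

test_that("energy-to-CO2 conversion is bilinear", {
  expect_equal(energy_to_co2(0, 0.4), 0)
  expect_equal(energy_to_co2(1, 0.4), 0.4)
  expect_rel_equal(energy_to_co2(2292.73, 0.4), 917, 5e-4)
  expect_equal(energy_to_co2(3 * 2, 0.5), 3 * energy_to_co2(2, 0.5))
  expect_equal(energy_to_co2(2, 2 * 0.5), 2 * energy_to_co2(2, 0.5))
})

test_that("tree counts round up and scale correctly", {
  expect_equal(trees_required(0), 0)
  expect_equal(trees_required(21.8), 1)
  expect_equal(trees_required(7650), 351)  # ceil(7650 / 21.8)
  expect_equal(trees_required(0.001), 1)   # nonzero emission needs a whole tree
})

test_that("forest area follows the world sequestration rate", {
  rate <- 7.6e9 / 40.6e6
  expect_equal(forest_area_required(0)$km2, 0)
  expect_equal(forest_area_required(rate)$km2, 1.0)
  expect_equal(forest_area_required(16e6)$km2, 16e6 / rate)
  fa <- forest_area_required(1000, region_forest_area_km2 = 114190)
  expect_equal(fa$fraction, fa$km2 / 114190)
  expect_error(forest_area_required(1, region_forest_area_km2 = 0), "> 0")
})

test_that("scanner emissions follow the power x time x intensity identity", {
  expect_equal(scanner_emission(60, 1000, 1, 1), 1)
  expect_rel_equal(scanner_emission(237179, 580, 1, 0.4), 917, 5e-4)
  expect_equal(scanner_emission(100, 500, 2, 0.4),
               2 * scanner_emission(100, 500, 1, 0.4))
  expect_error(scanner_emission(0, 580, 1, 0.4), "positive")
})

test_that("scenario task compositions match their definitions", {
  expect_equal(nrow(scenario("one_task")$tasks), 1L)
  s2 <- scenario("two_task")
  expect_setequal(s2$tasks$task_type, c("classification", "segmentation"))
  s7 <- scenario("seven_task")
  expect_equal(nrow(s7$tasks), 7L)
  expect_equal(sum(s7$tasks$task_type == "segmentation"), 3L)
  expect_equal(sum(s7$tasks$task_type == "classification"), 4L)
  expect_equal(scenario("multitask")$tasks$task_type, "multitask")
  expect_error(scenario("two_task", tasks = data.frame(task = "x", task_type = "classification",
                                                       size_class = "large")),
               "must have 2")
})

test_that("scenario emissions equal a brute-force per-slide loop", {
  coh <- generate_cohort(cohort_config(seed = 21))
  sizes <- select_size_classes(toy_calibration())
  wl <- cohort_workload(coh, tiling_spec(512, "wsi"))
  res <- scenario_emission(wl, scenario("one_task", "wsi", "large"), sizes,
                           intensity_kg_per_kwh = 0.4, n_boot = 0)
  # independent summation: per slide, tiles x energy-per-tile x intensity
  oracle <- 0
  for (i in seq_len(nrow(coh$slides))) {
    tiles <- ceiling(coh$slides$n_pixels[i] / 512^2)
    oracle <- oracle + tiles * 9 / 1e7 * 0.4
  }
  expect_rel_equal(res$co2eq_kg, oracle, 1e-9)
  expect_rel_equal(sum(res$per_task_kg), res$co2eq_kg, 1e-9)
})

test_that("emission is linear in tiles, energy and intensity, and additive over tasks", {
  coh <- generate_cohort(cohort_config(seed = 22))
  sizes <- select_size_classes(toy_calibration())
  wl <- cohort_workload(coh, tiling_spec(512, "wsi"))
  base <- scenario_emission(wl, scenario("one_task", "wsi", "large"), sizes, 0.4,
                            n_boot = 0)
  # doubling intensity doubles emission
  x2 <- scenario_emission(wl, scenario("one_task", "wsi", "large"), sizes, 0.8,
                          n_boot = 0)
  expect_equal(x2$co2eq_kg, 2 * base$co2eq_kg, tolerance = 1e-12)
  # doubling energy-per-tile doubles emission
  sizes2 <- sizes
  sizes2$classification$large$kwh_per_1e7_tiles <- 18
  e2 <- scenario_emission(wl, scenario("one_task", "wsi", "large"), sizes2, 0.4,
                          n_boot = 0)
  expect_equal(e2$co2eq_kg, 2 * base$co2eq_kg, tolerance = 1e-12)
  # seven identical tasks = 7 x one task
  same <- list(classification = list(large = list(model_name = "x", n_params = 1,
                                                  kwh_per_1e7_tiles = 5)),
               segmentation = list(large = list(model_name = "y", n_params = 1,
                                                kwh_per_1e7_tiles = 5)))
  one <- scenario_emission(wl, scenario("one_task", "wsi", "large"), same, 0.4,
                           n_boot = 0)
  seven <- scenario_emission(wl, scenario("seven_task", "wsi", "large"), same, 0.4,
                             n_boot = 0)
  expect_rel_equal(seven$co2eq_kg, 7 * one$co2eq_kg, 1e-12)
})

test_that("zero workloads give zero emissions and offsets", {
  s <- tiny_slides()
  s$roi_fraction <- 0
  wl <- cohort_workload(s, tiling_spec(512, "roi"))
  res <- scenario_emission(wl, scenario("one_task", "roi", "large"),
                           select_size_classes(toy_calibration()), 0.4)
  expect_equal(res$co2eq_kg, 0)
  expect_equal(res$offsets$trees, 0)
  expect_equal(res$offsets$forest_km2, 0)
})

test_that("emissions are monotone across scenarios and input modes", {
  coh <- generate_cohort(cohort_config(seed = 23))
  sizes <- select_size_classes(toy_calibration())
  modes <- c("roi", "tissue", "wsi")
  wls <- lapply(modes, function(m) cohort_workload(coh, tiling_spec(512, m)))
  names(wls) <- modes
  for (sc in c("small", "medium", "large")) {
    kg <- vapply(c("one_task", "two_task", "seven_task"), function(nm) {
      scenario_emission(wls$wsi, scenario(nm, "wsi", sc), sizes, 0.4,
                        n_boot = 0)$co2eq_kg
    }, numeric(1))
    expect_true(all(diff(kg) >= 0))
  }
  kg_mode <- vapply(modes, function(m) {
    scenario_emission(wls[[m]], scenario("seven_task", m, "large"), sizes, 0.4,
                      n_boot = 0)$co2eq_kg
  }, numeric(1))
  expect_true(kg_mode[["roi"]] <= kg_mode[["tissue"]])
  expect_true(kg_mode[["tissue"]] <= kg_mode[["wsi"]])
})

test_that("the bootstrap CI brackets the point estimate and shrinks with noise", {
  coh <- generate_cohort(cohort_config(seed = 24))
  sizes <- select_size_classes(toy_calibration())
  wl <- cohort_workload(coh, tiling_spec(512, "tissue"))
  scen <- scenario("two_task", "tissue", "medium")
  widths <- vapply(c(0.05, 0.02, 0.005, 1e-6), function(sd) {
    res <- scenario_emission(wl, scen, sizes, 0.4, noise_sd = sd, n_boot = 400,
                             seed = 8)
    expect_true(res$ci95_kg[1] <= res$co2eq_kg && res$co2eq_kg <= res$ci95_kg[2])
    res$ci95_kg[2] - res$ci95_kg[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[4] / widths[1], 1e-3)
})

test_that("mode mismatches and missing calibrations are explicit errors", {
  coh <- generate_cohort(cohort_config(seed = 25))
  sizes <- select_size_classes(toy_calibration())
  wl <- cohort_workload(coh, tiling_spec(512, "wsi"))
  expect_error(scenario_emission(wl, scenario("one_task", "tissue"), sizes, 0.4),
               "does not match")
  expect_error(scenario_emission(wl, scenario("multitask", "wsi"), sizes, 0.4),
               "calibration missing")
  no_seg <- sizes["classification"]
  expect_error(scenario_emission(wl, scenario("two_task", "wsi"), no_seg, 0.4),
               "calibration missing")
})

test_that("reduction factors divide baseline by alternative", {
  expect_equal(reduction_factor(100, 100), 1)
  expect_equal(reduction_factor(100, 4), 25)
  expect_error(reduction_factor(100, 0), "division guard")
})

test_that("pathomics reduces to a single segmentation pass and scales with overhead", {
  coh <- generate_cohort(cohort_config(seed = 26))
  sizes <- select_size_classes(toy_calibration())
  wl <- cohort_workload(coh, tiling_spec(512, "tissue"))
  seg_only <- pathomics_emission(wl, sizes$segmentation$small, overhead_fraction = 0,
                                 intensity_kg_per_kwh = 0.4, n_boot = 0)
  ref <- scenario_emission(wl, scenario("one_task", "tissue", "small",
                                        tasks = data.frame(task = "seg",
                                                           task_type = "segmentation",
                                                           size_class = "small")),
                           sizes, 0.4, n_boot = 0)
  expect_rel_equal(seg_only$co2eq_kg, ref$co2eq_kg, 1e-12)

  two_pass <- pathomics_emission(wl, sizes$segmentation$small,
                                 detection_kwh_per_ref = 0.5,
                                 intensity_kg_per_kwh = 0.4, n_boot = 0)
  with_oh <- pathomics_emission(wl, sizes$segmentation$small,
                                detection_kwh_per_ref = 0.5,
                                overhead_fraction = 0.10,
                                intensity_kg_per_kwh = 0.4, n_boot = 0)
  expect_rel_equal(with_oh$co2eq_kg, 1.1 * two_pass$co2eq_kg, 1e-12)

  # fixture ratio against a multitask run reproduces hand division
  mt <- scenario_emission(wl, scenario("multitask", "tissue"), sizes, 0.4,
                          multitask_kwh = 500, n_boot = 0)
  expect_equal(reduction_factor(mt, two_pass),
               mt$co2eq_kg / two_pass$co2eq_kg)
  expect_error(pathomics_emission(cohort_workload(coh, tiling_spec(512, "wsi")),
                                  sizes$segmentation$small,
                                  intensity_kg_per_kwh = 0.4),
               "tissue-mode")
})
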