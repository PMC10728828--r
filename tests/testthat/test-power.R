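test_that("trace integration reproduces unit cases", {
  # constant 1000 W for one hour is exactly 1 kWh
  tr <- power_trace(data.frame(t_s = c(0, 3600), gpu_w = c(1000, 1000)))
  expect_equal(integrate_trace(tr), 1.0)
  # all-zero draws integrate to zero
  z <- power_trace(data.frame(t_s = c(0, 100, 200), cpu_w = 0, gpu_w = 0))
  expect_equal(integrate_trace(z), 0)
  # components sum: 600 W split across components for 2 h = 1.2 kWh
  m <- power_trace(data.frame(t_s = c(0, 7200), dram_w = 100, cpu_w = 200,
                              gpu_w = 250, cooling_w = 50))
  expect_equal(integrate_trace(m), 1.2)
})

test_that("trace integration matches the 1-second summation oracle on random traces", {
  for (seed in 1:10) {
    tr <- random_linear_trace(seed)
    expect_rel_equal(integrate_trace(tr), riemann_energy_kwh(tr), 1e-9)
  }
})

test_that("trace integration is additive over concatenation and homogeneous", {
  tr <- random_linear_trace(99)
  s <- tr$samples
  cut <- nrow(s) %/% 2
  # split at a knot: both halves share the boundary sample
  e1 <- integrate_trace(power_trace(s[1:cut, ]))
  e2 <- integrate_trace(power_trace(s[cut:nrow(s), ]))
  expect_equal(e1 + e2, integrate_trace(tr), tolerance = 1e-12)
  doubled <- s
  doubled$gpu_w <- 2 * doubled$gpu_w
  expect_equal(integrate_trace(power_trace(doubled)), 2 * integrate_trace(tr),
               tolerance = 1e-12)
})

test_that("malformed traces are rejected", {
  expect_error(power_trace(data.frame(t_s = c(0, 10, 5), gpu_w = 1)),
               "strictly increasing")
  expect_error(power_trace(data.frame(t_s = c(0, 10), gpu_w = c(-1, 1))),
               "negative")
  expect_error(integrate_trace(power_trace(data.frame(t_s = 0, gpu_w = 5))),
               "at least 2")
})

test_that("JSON-lines traces round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"t_s":0,"gpu_w":500,"cpu_w":100}',
               '{"t_s":3600,"gpu_w":500,"cpu_w":100}'), path)
  tr <- read_power_trace(path, n_tiles_processed = 1e6)
  expect_equal(integrate_trace(tr), 0.6)
  expect_equal(tr$n_tiles_processed, 1e6)
})

test_that("energy normalisation to 1e7 tiles is exact arithmetic", {
  expect_equal(energy_per_reference_tiles(2, 1e7), 2)
  expect_equal(energy_per_reference_tiles(1, 5e6), 2)
  set.seed(1)
  for (i in 1:20) {
    e <- runif(1, 0.1, 100); n <- runif(1, 1e4, 1e9)
    expect_equal(energy_per_reference_tiles(e, n), e / n * 1e7)
  }
  expect_error(energy_per_reference_tiles(1, 0), "division guard")
})

test_that("size classing picks min, lower-median and max per task type", {
  sizes <- select_size_classes(toy_calibration())
  expect_equal(sizes$classification$small$kwh_per_1e7_tiles, 1)
  expect_equal(sizes$classification$medium$kwh_per_1e7_tiles, 2)
  expect_equal(sizes$classification$large$kwh_per_1e7_tiles, 9)
  expect_equal(sizes$segmentation$large$model_name, "s_big")
  # small <= medium <= large for both task types
  for (tt in names(sizes)) {
    e <- vapply(sizes[[tt]], `[[`, numeric(1), "kwh_per_1e7_tiles")
    expect_true(e[["small"]] <= e[["medium"]] && e[["medium"]] <= e[["large"]])
  }
})

test_that("size classing uses the lower median for even counts and lexicographic ties", {
  # 20 models: medium must be the rank-10 model after ascending sort
  set.seed(7)
  prof <- data.frame(model_name = sprintf("m%02d", 1:20),
                     task_type = "classification", n_params = 1:20 * 1e6,
                     n_layers = 5, device_name = "dev",
                     kwh_per_1e7_tiles = sample(seq(0.5, 10, length.out = 20)))
  sizes <- select_size_classes(prof)
  sorted <- sort(prof$kwh_per_1e7_tiles)
  expect_equal(sizes$classification$medium$kwh_per_1e7_tiles, sorted[10])
  # duplicate minimum energies: tie broken by model_name
  tie <- toy_calibration()
  tie$kwh_per_1e7_tiles[tie$model_name %in% c("c_small", "c_mid")] <- 1
  expect_equal(select_size_classes(tie)$classification$small$model_name, "c_mid")
  # fewer than 3 profiles in a task type is an error
  expect_error(select_size_classes(toy_calibration()[1:2, ]),
               "insufficient calibration")
})

test_that("the scaling-law fit is exact on two points and permutation invariant", {
  prof <- data.frame(model_name = c("a", "b"), task_type = "classification",
                     n_params = c(1e6, 1e8), n_layers = 2, device_name = "dev",
                     kwh_per_1e7_tiles = c(1, 100))
  fit <- fit_param_energy(prof, n_boot = 0)
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$intercept, -6.0)

  cal <- read_model_calibration()
  f1 <- fit_param_energy(cal, n_boot = 0)
  f2 <- fit_param_energy(cal[sample(nrow(cal)), ], n_boot = 0)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)

  degen <- prof
  degen$n_params <- 1e7
  expect_error(fit_param_energy(degen), "degenerate design")
})

test_that("multitask prediction matches the plug-in formula and its stored draws", {
  fit <- structure(list(intercept = -6, slope = 1, residual_sd = 0, n_models = 2,
                        bootstrap_draws = matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("intercept", "slope")))),
                   class = "param_energy_fit")
  expect_warning(est <- estimate_multitask_energy(fit, n_params = 5.4e11),
                 "CI unavailable")
  expect_equal(est$point, 5.4e5)

  cal <- read_model_calibration()
  fit <- fit_param_energy(cal, n_boot = 300, seed = 5)
  est <- estimate_multitask_energy(fit)
  # independent recomputation from the stored bootstrap draws
  preds <- 10^(fit$bootstrap_draws[, "intercept"] +
                 fit$bootstrap_draws[, "slope"] * log10(540e9))
  expect_equal(est$ci95, unname(quantile(preds, c(0.025, 0.975))))
  expect_lt(est$ci95[1], est$ci95[2])
  expect_true(est$ci95[1] <= est$point && est$point <= est$ci95[2])
})

test_that("a noiseless power law yields a collapsing bootstrap CI", {
  prof <- data.frame(model_name = sprintf("m%d", 1:10),
                     task_type = "classification",
                     n_params = 10^seq(6, 8, length.out = 10), n_layers = 3,
                     device_name = "dev",
                     kwh_per_1e7_tiles = 10^(-5 + 0.8 * seq(6, 8, length.out = 10)))
  fit <- fit_param_energy(prof, n_boot = 200, seed = 2)
  est <- estimate_multitask_energy(fit)
  expect_rel_equal(est$ci95[2], est$ci95[1], 1e-8)
})

test_that("pruning scales energy by the interpolated curve and never up", {
  expect_equal(pruned_energy(10, 0), 10)
  # default curve: 25% saving at 40% pruning
  expect_equal(pruned_energy(10, 0.40), 7.5)
  # hand interpolation on custom knots
  cv <- pruning_curve(data.frame(p = c(0, 0.5), m = c(1, 0.7)))
  expect_equal(pruned_energy(100, 0.25, cv), 85)
  expect_error(pruned_energy(10, 0.6), "extrapolation refused")
  # non-increasing in prune fraction
  f <- seq(0, 0.4, by = 0.05)
  e <- vapply(f, function(p) pruned_energy(10, p), numeric(1))
  expect_true(all(diff(e) <= 1e-12))
  expect_true(all(e <= 10))
  expect_error(pruning_curve(data.frame(p = c(0, 0.3), m = c(1, 1.2))),
               "non-increasing|in \\(0, 1\\]")
})
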