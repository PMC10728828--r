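# Fixtures built in code: tiny cohorts, calibration tables and power traces
# shared across test files.

tiny_slides <- function() {
  data.frame(
    slide_id = c("a_s1", "a_s2", "b_s1"),
    case_id = c("case_a", "case_a", "case_b"),
    organ = c("breast", "breast", "prostate"),
    specimen_type = "biopsy",
    n_pixels = c(2621440, 1e9, 5e8),
    file_size_bytes = c(1e6, 4e8, 2e8),
    tissue_fraction = c(1.0, 0.37, 0.6),
    roi_fraction = c(0.5, 0.2, 0.1),
    stringsAsFactors = FALSE
  )
}

tiny_cases <- function() {
  data.frame(case_id = c("case_a", "case_b"),
             organ = c("breast", "prostate"),
             specimen_type = "biopsy",
             n_slides = c(2L, 1L),
             stringsAsFactors = FALSE)
}

# Calibration table with known energies per task type.
toy_calibration <- function() {
  data.frame(
    model_name = c("c_small", "c_mid", "c_big", "s_small", "s_mid", "s_big"),
    task_type = rep(c("classification", "segmentation"), each = 3),
    n_params = c(1e6, 1e7, 1e8, 2e6, 2e7, 2e8),
    n_layers = 10,
    device_name = "dev",
    kwh_per_1e7_tiles = c(1, 2, 9, 1.5, 3, 12),
    stringsAsFactors = FALSE
  )
}

# Piecewise-linear single-component trace with knots at integer seconds.
random_linear_trace <- function(seed, n_knots = 8, t_max = 7200) {
  set.seed(seed)
  t <- sort(sample(0:t_max, n_knots))
  w <- runif(n_knots, 0, 1500)
  power_trace(data.frame(t_s = t, gpu_w = w))
}

# Independent energy oracle: 1-second-step summation over the linearly
# interpolated trace (trapezoid per step), W*s -> kWh.
riemann_energy_kwh <- function(trace) {
  s <- trace$samples
  total <- rowSums(s[, trace$components, drop = FALSE])
  grid <- seq(min(s$t_s), max(s$t_s), by = 1)
  f <- stats::approx(s$t_s, total, xout = grid)$y
  sum((f[-length(f)] + f[-1]) / 2) / 3.6e6
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
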