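flat_driver <- function(value, kind = "positive", years = 2023:2052, n_boot = 100) {
  fit_driver(data.frame(year = c(2023, 2052), value = value, rel_sd = 0),
             kind, years = years, n_boot = n_boot)
}

flat_drivers <- function(years = 2023:2052, n_boot = 100, share = 0.2) {
  list(renewables = flat_driver(share, "share", years, n_boot),
       model_complexity = flat_driver(1, "positive", years, n_boot),
       hardware_efficiency = flat_driver(1, "positive", years, n_boot),
       cases = flat_driver(1, "positive", years, n_boot))
}

test_that("constant anchors with zero uncertainty give a flat, bandless trajectory", {
  tr <- flat_driver(3)
  expect_equal(tr$mean, rep(3, 30))
  expect_equal(tr$high - tr$low, rep(0, 30))
})

test_that("positive drivers interpolate geometrically between anchors", {
  tr <- fit_driver(data.frame(year = c(2023, 2033), value = c(1, 2), rel_sd = 0),
                   "positive", years = 2023:2052, n_boot = 0)
  expect_rel_equal(tr$mean[tr$years == 2028], sqrt(2), 1e-12)
  # closed form along the whole anchored span and its extrapolation
  expect_equal(tr$mean, 2^((tr$years - 2023) / 10), tolerance = 1e-12)
})

test_that("share drivers are linear and clamped to [0, 1]", {
  tr <- fit_driver(data.frame(year = c(2023, 2033), value = c(0.5, 0.9), rel_sd = 0),
                   "share", years = 2023:2052, n_boot = 0)
  expect_equal(tr$mean[tr$years == 2028], 0.7)
  expect_true(all(tr$mean <= 1))  # the linear extension would exceed 1 after 2035
  expect_equal(tr$mean[tr$years == 2052], 1)
})

test_that("anchor uncertainty produces bands containing the mean and widening with horizon", {
  tr <- fit_driver(data.frame(year = c(2023, 2052), value = c(1, 10),
                              rel_sd = c(0.05, 0.3)),
                   "positive", years = 2023:2052, n_boot = 500, seed = 4)
  expect_true(all(tr$low <= tr$mean & tr$mean <= tr$high))
  rel_width <- (tr$high - tr$low) / tr$mean
  expect_gt(rel_width[length(rel_width)], rel_width[1])
})

test_that("under-specified drivers error unless a growth rate is given", {
  one <- data.frame(year = 2023, value = 1, rel_sd = 0)
  expect_error(fit_driver(one, "positive"), "under-specified")
  tr <- fit_driver(one, "positive", growth_rate = 1.02, n_boot = 0)
  expect_rel_equal(tr$mean[tr$years == 2033], 1.02^10, 1e-9)
})

test_that("flat drivers leave the emission path at its base value", {
  pr <- combine_projection(1000, 2023, flat_drivers())
  expect_true(all(abs(pr$mean - 1000) < 1e-9))
  expect_true(all(abs(pr$best - 1000) < 1e-9))
  expect_true(all(abs(pr$worst - 1000) < 1e-9))
})

test_that("single-driver limits follow closed forms", {
  years <- 2023:2052
  # 2%/yr case growth alone compounds: x1.02^10 after 10 years
  d <- flat_drivers()
  d$cases <- fit_driver(data.frame(year = 2023, value = 1, rel_sd = 0),
                        "positive", years, growth_rate = 1.02, n_boot = 100)
  pr <- combine_projection(500, 2023, d)
  expect_rel_equal(pr$mean[years == 2033], 500 * 1.02^10, 1e-9)
  # doubling hardware efficiency halves emissions
  d <- flat_drivers()
  d$hardware_efficiency <- fit_driver(
    data.frame(year = c(2023, 2024), value = c(1, 2), rel_sd = 0),
    "positive", years, n_boot = 100)
  pr <- combine_projection(500, 2023, d)
  expect_equal(pr$mean[years == 2024], 250)
  # full renewables from the next year scales by floor / base intensity
  d <- flat_drivers(share = 0.2)
  d$renewables <- fit_driver(
    data.frame(year = c(2023, 2024), value = c(0.2, 1), rel_sd = 0),
    "share", years, n_boot = 100)
  pr <- combine_projection(500, 2023, d)
  expect_rel_equal(pr$mean[years == 2052],
                   500 * intensity_from_mix(1) / intensity_from_mix(0.2), 1e-12)
})

test_that("driver effects are monotone in the expected direction", {
  base <- combine_projection(1000, 2023, flat_drivers())
  grow <- function() fit_driver(data.frame(year = 2023, value = 1, rel_sd = 0),
                                "positive", 2023:2052, growth_rate = 1.2,
                                n_boot = 100)
  d <- flat_drivers()
  d$model_complexity <- grow()
  expect_true(all(combine_projection(1000, 2023, d)$mean[-1] > base$mean[-1]))
  d <- flat_drivers()
  d$hardware_efficiency <- grow()
  expect_true(all(combine_projection(1000, 2023, d)$mean[-1] < base$mean[-1]))
})

test_that("combined projections are seed-reproducible with ordered bands", {
  anchors <- read_driver_anchors()
  d1 <- fit_all_drivers(anchors, n_boot = 200, seed = 17)
  d2 <- fit_all_drivers(anchors, n_boot = 200, seed = 17)
  p1 <- combine_projection(1e6, 2023, d1)
  p2 <- combine_projection(1e6, 2023, d2)
  expect_identical(p1$draws, p2$draws)
  expect_true(all(p1$best <= p1$mean + 1e-9))
  expect_true(all(p1$mean <= p1$worst + 1e-9))
  # forest fractions are the emission paths in world-forest units
  expect_equal(p1$forest_fraction$mean, p1$mean / 1000 / 7.6e9)
})

test_that("grid and draw-count mismatches are alignment errors", {
  d <- flat_drivers()
  d$cases <- flat_driver(1, years = 2024:2052)
  expect_error(combine_projection(1, 2023, d), "mismatch")
  d <- flat_drivers()
  d$cases <- flat_driver(1, n_boot = 50)
  expect_error(combine_projection(1, 2023, d), "draw counts")
  expect_error(combine_projection(1, 2020, flat_drivers()), "not on the driver year grid")
})

test_that("forest exceedance is the first year at or above the whole world forest", {
  pr <- combine_projection(1000, 2023, flat_drivers())
  expect_true(is.na(forest_exceedance_year(pr, "worst")))
  # geometric emission growth with a known analytic crossing year:
  # E(y) = E0 * g^(y - 2023) crosses capacity at 2023 + log(cap/E0)/log(g)
  years <- 2023:2052
  cap_kg <- 7.6e9 * 1000
  E0 <- 1e9 * 1000  # 1 Gt in kg
  g <- 1.5
  d <- flat_drivers()
  d$model_complexity <- fit_driver(data.frame(year = 2023, value = 1, rel_sd = 0),
                                   "positive", years, growth_rate = g, n_boot = 100)
  pr <- combine_projection(E0, 2023, d)
  analytic <- 2023 + ceiling(log(cap_kg / E0) / log(g))
  expect_equal(forest_exceedance_year(pr, "mean"), analytic)
  expect_equal(forest_exceedance_year(pr, "worst"), analytic)
})
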