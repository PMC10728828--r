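# Multi-driver emission projections 2023-2052.
#
# Four drivers move future emissions: the renewable share of the grid
# (lowers intensity), deep-learning model complexity (raises energy per
# tile), hardware efficiency (lowers it) and pathology case counts (raise
# workload). Each driver is a yearly trajectory fitted through anchor
# points with seeded bootstrap bands; the combined emission path scales a
# base-year emission multiplicatively by each driver's ratio to its
# base-year value. Best/worst paths are the 2.5/97.5 percentiles of the
# bootstrapped path ensemble.

PROJECTION_DRIVERS <- c("renewables", "model_complexity", "hardware_efficiency",
                        "cases")

interp_endslope <- function(ax, ay, xout) {
  n <- length(ax)
  if (n == 1L) return(rep(ay, length(xout)))
  y <- stats::approx(ax, ay, xout = xout, rule = 2)$y
  lo <- xout < ax[1]
  hi <- xout > ax[n]
  if (any(lo)) {
    s <- (ay[2] - ay[1]) / (ax[2] - ax[1])
    y[lo] <- ay[1] + s * (xout[lo] - ax[1])
  }
  if (any(hi)) {
    s <- (ay[n] - ay[n - 1]) / (ax[n] - ax[n - 1])
    y[hi] <- ay[n] + s * (xout[hi] - ax[n])
  }
  y
}

# Interpolate/extrapolate anchors over a year grid. Positive drivers are
# log-linear between anchors (geometric growth); shares are linear and
# clamped to [0, 1].
driver_path <- function(years, anchor_years, anchor_values, kind) {
  if (kind == "positive") {
    exp(interp_endslope(anchor_years, log(anchor_values), years))
  } else {
    pmin(1, pmax(0, interp_endslope(anchor_years, anchor_values, years)))
  }
}

#' Fit a driver trajectory through anchor points
#'
#' Deterministic interpolation/extrapolation through the anchor means -
#' log-linear (geometric) for positive drivers, linear for the renewable
#' share, which is clamped to \[0, 1\] - plus seeded bootstrap bands from
#' per-anchor uncertainty: each draw perturbs every anchor independently
#' (log-normal for positive drivers, logit-normal for shares, sd =
#' `rel_sd`) and re-interpolates.
#'
#' @param anchors Data frame with columns `year`, `value` and optionally
#'   `rel_sd` (default 0). A single anchor is allowed only together with
#'   `growth_rate`.
#' @param kind `"positive"` (energy, complexity, efficiency, cases) or
#'   `"share"` (renewable share in \[0, 1\]).
#' @param years Year grid (default 2023:2052).
#' @param growth_rate Optional per-year multiplicative growth rate; with a
#'   single anchor it synthesises a second anchor at the last grid year.
#' @param n_boot Bootstrap path draws (default 2000).
#' @param seed Integer seed.
#' @param driver Label stored in the result.
#' @return Object of class `trajectory`: `years`, `mean`, `low`, `high`
#'   (95% band), `draws` (n_boot x length(years)), `kind`, `n_boot`, `seed`.
#' @export
fit_driver <- function(anchors, kind = c("positive", "share"),
                       years = 2023:2052, growth_rate = NULL,
                       n_boot = 2000, seed = 1L, driver = "driver") {
  kind <- match.arg(kind)
  assert_columns(anchors, c("year", "value"), "driver anchors")
  if (is.null(anchors$rel_sd)) anchors$rel_sd <- 0
  anchors <- anchors[order(anchors$year), , drop = FALSE]
  if (nrow(anchors) < 2L) {
    if (is.null(growth_rate)) {
      stop("under-specified driver: need >= 2 anchors or a growth rate", call. = FALSE)
    }
    horizon <- max(years) - anchors$year[1]
    anchors <- rbind(anchors,
                     data.frame(year = max(years),
                                value = anchors$value[1] * growth_rate^horizon,
                                rel_sd = anchors$rel_sd[1]))
  }
  if (any(anchors$value <= 0) && kind == "positive") {
    stop("positive-driver anchors must have value > 0", call. = FALSE)
  }
  if (kind == "share" && (any(anchors$value < 0) || any(anchors$value > 1))) {
    stop("share anchors must lie in [0, 1]", call. = FALSE)
  }
  mean_path <- driver_path(years, anchors$year, anchors$value, kind)

  draws <- matrix(rep(mean_path, each = max(n_boot, 1L)), nrow = max(n_boot, 1L))
  if (n_boot > 0 && any(anchors$rel_sd > 0)) {
    set.seed(substream_seed(seed, paste0("driver-", driver)))
    na <- nrow(anchors)
    for (b in seq_len(n_boot)) {
      eps <- stats::rnorm(na, 0, anchors$rel_sd)
      v <- if (kind == "positive") {
        anchors$value * exp(eps)
      } else {
        vc <- pmin(1 - 1e-9, pmax(1e-9, anchors$value))
        stats::plogis(stats::qlogis(vc) + eps)
      }
      draws[b, ] <- driver_path(years, anchors$year, v, kind)
    }
  }
  structure(list(driver = driver, kind = kind, years = years,
                 mean = mean_path,
                 low = apply(draws, 2, stats::quantile, 0.025),
                 high = apply(draws, 2, stats::quantile, 0.975),
                 draws = draws, n_boot = nrow(draws), seed = seed),
            class = "trajectory")
}

#' Average two trajectories year by year
#'
#' Used for the "mean" renewable-energy scenario, defined as the arithmetic
#' mean of the planned and below-2-degree paths for every year (draws are
#' averaged pairwise; the band is recomputed from the averaged draws).
#'
#' @param a,b `trajectory` objects on the same year grid with the same
#'   number of draws.
#' @return A `trajectory`.
#' @export
average_trajectories <- function(a, b) {
  stopifnot(inherits(a, "trajectory"), inherits(b, "trajectory"),
            identical(a$years, b$years), nrow(a$draws) == nrow(b$draws))
  draws <- (a$draws + b$draws) / 2
  structure(list(driver = paste0("mean(", a$driver, ",", b$driver, ")"),
                 kind = a$kind, years = a$years,
                 mean = (a$mean + b$mean) / 2,
                 low = apply(draws, 2, stats::quantile, 0.025),
                 high = apply(draws, 2, stats::quantile, 0.975),
                 draws = draws, n_boot = nrow(draws), seed = a$seed),
            class = "trajectory")
}

#' Read a driver anchor table
#'
#' Columns: `driver` (`renewables`, `model_complexity`,
#' `hardware_efficiency`, `cases`), `scenario_label` (`planned`,
#' `below_2C`, `mean`), `year`, `value`, `rel_sd`. The packaged fixture
#' (`driver_anchors_synthetic.csv`) is synthetic.
#'
#' @param path CSV path; defaults to the packaged synthetic fixture.
#' @return Data frame of anchors.
#' @export
read_driver_anchors <- function(path = NULL) {
  path <- path %||% system.file("extdata", "driver_anchors_synthetic.csv",
                                package = "carbonpath")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("driver", "scenario_label", "year", "value", "rel_sd"),
                 "driver anchor CSV")
  df
}

#' Fit all four drivers from an anchor table
#'
#' Fits `model_complexity`, `hardware_efficiency` and `cases` as positive
#' drivers and `renewables` as a share; the renewables trajectory is the
#' year-wise mean of the `planned` and `below_2C` scenarios unless a single
#' scenario label is requested.
#'
#' @param anchors Anchor data frame (see [read_driver_anchors()]).
#' @param years Year grid.
#' @param renewables_scenario `"mean"`, `"planned"` or `"below_2C"`.
#' @param n_boot,seed Bootstrap controls (shared by all drivers; each driver
#'   uses its own derived substream).
#' @return Named list of `trajectory` objects (`renewables`,
#'   `model_complexity`, `hardware_efficiency`, `cases`).
#' @export
fit_all_drivers <- function(anchors, years = 2023:2052,
                            renewables_scenario = c("mean", "planned", "below_2C"),
                            n_boot = 2000, seed = 1L) {
  renewables_scenario <- match.arg(renewables_scenario)
  get_anchors <- function(drv, lbl) {
    a <- anchors[anchors$driver == drv & anchors$scenario_label == lbl,
                 c("year", "value", "rel_sd")]
    if (nrow(a) == 0L) {
      stop(sprintf("no anchors for driver '%s' scenario '%s'", drv, lbl),
           call. = FALSE)
    }
    a
  }
  ren <- if (renewables_scenario == "mean") {
    average_trajectories(
      fit_driver(get_anchors("renewables", "planned"), "share", years,
                 n_boot = n_boot, seed = seed, driver = "renewables_planned"),
      fit_driver(get_anchors("renewables", "below_2C"), "share", years,
                 n_boot = n_boot, seed = seed, driver = "renewables_below_2C"))
  } else {
    fit_driver(get_anchors("renewables", renewables_scenario), "share", years,
               n_boot = n_boot, seed = seed,
               driver = paste0("renewables_", renewables_scenario))
  }
  list(renewables = ren,
       model_complexity = fit_driver(get_anchors("model_complexity", "mean"),
                                     "positive", years, n_boot = n_boot,
                                     seed = seed, driver = "model_complexity"),
       hardware_efficiency = fit_driver(get_anchors("hardware_efficiency", "mean"),
                                        "positive", years, n_boot = n_boot,
                                        seed = seed, driver = "hardware_efficiency"),
       cases = fit_driver(get_anchors("cases", "mean"), "positive", years,
                          n_boot = n_boot, seed = seed, driver = "cases"))
}

#' Combine driver trajectories into an emission projection
#'
#' Multiplicative, separable coupling - the only rule consistent with the
#' linear emission accounting: per year `y` (and per bootstrap draw),
#' \deqn{E(y) = E_0 \cdot \frac{complexity(y)}{complexity(y_0)} \cdot
#'   \frac{cases(y)}{cases(y_0)} \cdot
#'   \frac{I(renewables(y))}{I(renewables(y_0))} \Big/
#'   \frac{efficiency(y)}{efficiency(y_0)}}
#' where `I(.)` is [intensity_from_mix()]. The mean path is computed from
#' the driver means; best/worst paths are the 2.5/97.5 percentiles of the
#' drawn paths.
#'
#' @param E0_kg Base-year emission in kg CO2eq (> 0).
#' @param year0 Base year (must be on the common year grid).
#' @param drivers Named list of `trajectory` objects: `renewables` (share),
#'   `model_complexity`, `hardware_efficiency`, `cases` (positive), all on
#'   the same year grid with the same number of draws.
#' @param constants [model_constants()].
#' @return Object of class `projection_result`: `years`, `mean`, `best`,
#'   `worst` (kg per year), `forest_fraction` (list of per-year fractions of
#'   world forest for each path), `draws`, `E0_kg`, `year0`.
#' @export
combine_projection <- function(E0_kg, year0, drivers,
                               constants = model_constants()) {
  assert_number(E0_kg, "E0_kg", lower = 1e-12)
  missing <- setdiff(PROJECTION_DRIVERS, names(drivers))
  if (length(missing)) {
    stop(sprintf("missing driver trajectory(ies): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  years <- drivers[[1]]$years
  for (d in drivers) {
    if (!identical(d$years, years)) stop("driver year grids mismatch", call. = FALSE)
  }
  i0 <- match(year0, years)
  if (is.na(i0)) stop("year0 is not on the driver year grid", call. = FALSE)
  nb <- unique(vapply(drivers, function(d) nrow(d$draws), numeric(1)))
  if (length(nb) != 1L) stop("driver draw counts mismatch", call. = FALSE)

  path_from <- function(comp, cas, ren, eff) {
    I <- intensity_from_mix(ren, constants)
    E0_kg * (comp / comp[i0]) * (cas / cas[i0]) * (I / I[i0]) / (eff / eff[i0])
  }
  mean_path <- path_from(drivers$model_complexity$mean, drivers$cases$mean,
                         drivers$renewables$mean, drivers$hardware_efficiency$mean)
  draws <- matrix(NA_real_, nrow = nb, ncol = length(years))
  for (b in seq_len(nb)) {
    draws[b, ] <- path_from(drivers$model_complexity$draws[b, ],
                            drivers$cases$draws[b, ],
                            drivers$renewables$draws[b, ],
                            drivers$hardware_efficiency$draws[b, ])
  }
  best <- apply(draws, 2, stats::quantile, 0.025)
  worst <- apply(draws, 2, stats::quantile, 0.975)
  frac <- function(kg) (kg / 1000) / constants$world_forest_capacity_t
  structure(list(years = years, mean = mean_path, best = best, worst = worst,
                 draws = draws,
                 forest_fraction = list(mean = frac(mean_path),
                                        best = frac(best),
                                        worst = frac(worst)),
                 E0_kg = E0_kg, year0 = year0),
            class = "projection_result")
}

#' First year a projection path needs the whole world's forest
#'
#' @param result A `projection_result`.
#' @param path `"worst"`, `"mean"` or `"best"`.
#' @return The first year with forest fraction >= 1, or `NA` if never.
#' @export
forest_exceedance_year <- function(result, path = c("worst", "mean", "best")) {
  path <- match.arg(path)
  frac <- result$forest_fraction[[path]]
  i <- which(frac >= 1)
  if (length(i)) result$years[i[1]] else NA_integer_
}
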