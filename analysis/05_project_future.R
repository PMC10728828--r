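#!/usr/bin/env Rscript
# Step 5: 2023-2052 emission projection under four drivers.
#
# Fits renewable-share, model-complexity, hardware-efficiency and case-count
# trajectories from the packaged (synthetic) anchor table, combines them
# multiplicatively around the global multitask total from step 4, and
# reports best/mean/worst paths with the year (if any) the worst path needs
# the whole world's forest.

suppressPackageStartupMessages(library(carbonpath))
arg <- commandArgs(trailingOnly = TRUE)
seed <- if (length(arg) >= 1) as.integer(arg[1]) else 1L
dir.create("results", showWarnings = FALSE)

world <- read.csv("results/world_emissions.csv")
E0_kg <- sum(world$co2eq_t) * 1000

drivers <- fit_all_drivers(read_driver_anchors(), n_boot = 2000, seed = seed)
projection <- combine_projection(E0_kg, 2023, drivers)
report <- data.frame(
  year = rep(projection$years, 3),
  path = rep(c("best", "mean", "worst"), each = length(projection$years)),
  co2eq_t = c(projection$best, projection$mean, projection$worst) / 1000,
  forest_fraction = c(projection$forest_fraction$best,
                      projection$forest_fraction$mean,
                      projection$forest_fraction$worst))
write.csv(report, "results/projection.csv", row.names = FALSE)

at2052 <- report[report$year == 2052, ]
cat(sprintf("Base year 2023: %.3g Mt CO2eq (global multitask total).\n", E0_kg / 1e9))
cat("2052 paths (Mt CO2eq | fraction of world forest):\n")
for (i in seq_len(nrow(at2052))) {
  cat(sprintf("  %-5s %10.3g | %.3g\n", at2052$path[i], at2052$co2eq_t[i] / 1e6,
              at2052$forest_fraction[i]))
}
for (p in c("worst", "mean", "best")) {
  y <- forest_exceedance_year(projection, p)
  cat(sprintf("Forest exceedance (%s path): %s\n", p,
              if (is.na(y)) "never within 2023-2052" else y))
}
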