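#!/usr/bin/env Rscript
# Step 2: per-model energy calibration and the parameter-energy scaling law.
#
# Loads the packaged synthetic 30-model calibration table (20 classification,
# 10 segmentation), selects the small/medium/large representatives per task
# type, fits log10(kWh per 1e7 tiles) ~ log10(parameters) with a bootstrap,
# and extrapolates to a 540-billion-parameter multitask model.

suppressPackageStartupMessages(library(carbonpath))
arg <- commandArgs(trailingOnly = TRUE)
seed <- if (length(arg) >= 1) as.integer(arg[1]) else 1L
dir.create("results", showWarnings = FALSE)

calibration <- read_model_calibration()
sizes <- select_size_classes(calibration, "quadro_6000")
fit <- fit_param_energy(calibration, "quadro_6000", n_boot = 2000, seed = seed)
mt <- estimate_multitask_energy(fit)

sel <- do.call(rbind, lapply(names(sizes), function(tt) {
  do.call(rbind, lapply(names(sizes[[tt]]), function(sc) {
    p <- sizes[[tt]][[sc]]
    data.frame(task_type = tt, size_class = sc, model = p$model_name,
               n_params = p$n_params, kwh_per_1e7_tiles = p$kwh_per_1e7_tiles)
  }))
}))
write.csv(sel, "results/size_classes.csv", row.names = FALSE)
write.csv(data.frame(quantity = c("slope", "intercept", "residual_sd",
                                  "multitask_kwh_per_1e7", "multitask_ci_low",
                                  "multitask_ci_high"),
                     value = c(fit$slope, fit$intercept, fit$residual_sd,
                               mt$point, mt$ci95)),
          "results/calibration_fit.csv", row.names = FALSE)

cat(sprintf("Scaling law over %d models: slope %.3f, intercept %.3f (log10 kWh).\n",
            fit$n_models, fit$slope, fit$intercept))
cat(sprintf("540B-parameter multitask estimate: %.3g kWh per 1e7 tiles (95%% CI %.3g-%.3g).\n",
            mt$point, mt$ci95[1], mt$ci95[2]))
cat("Selected size classes:\n")
print(sel, row.names = FALSE)
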