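#!/usr/bin/env Rscript
# Step 3 -- fit the three hierarchical Bayesian regressions.
#
#   * log10 SMR/MMR ~ log10 mass (Normal likelihood, informative
#     Normal(0.75, 0.1) prior on the global scaling exponent);
#   * log10 field speed ~ log10 length (robust Student-t likelihood);
#   * log10 max speed ~ log10 length + aspect ratio (Student-t, with
#     family x body-shape groups; longer chains because the aspect-ratio
#     coefficient is informed mostly across groups).
#
# Posterior summaries go to results/; full fit objects to scratch/ for the
# next step.

library(fishamr)

obs <- read.csv("results/mr_observations.csv")
speeds <- read.csv("scratch/sim/speeds.csv")
maxspeeds <- read.csv("scratch/sim/maxspeeds.csv")
config <- read_config("results/config.yml")
seed <- config$seed

mr_fit <- fit_mr_model(obs, fit_settings(iter = 5000), seed = seed)
speed_fit <- fit_speed_model(speeds, fit_settings(), seed = seed + 1)
maxspeed_fit <- fit_maxspeed_model(maxspeeds, fit_settings(iter = 5000),
                                   seed = seed + 2)

dir.create("results", showWarnings = FALSE)
for (fit in list(mr_fit, speed_fit, maxspeed_fit)) {
  write.csv(fit$summary,
            sprintf("results/fit_%s_summary.csv", fit$model),
            row.names = FALSE)
  r2 <- bayes_r2(fit)
  cat(sprintf(
    "%-8s converged: %s | global slope %.3f | Bayes R2 %.2f [%.2f, %.2f]\n",
    fit$model, fit$converged,
    fit$summary$mean[fit$summary$parameter == "b"],
    r2$median, r2$ci[1], r2$ci[2]))
}

co <- group_coefficients(mr_fit)
cat("\nper-species scaling exponents (posterior means):\n")
print(co[, c("group", "slope_mean", "slope_q2.5", "slope_q97.5")],
      digits = 3, row.names = FALSE)

dir.create("scratch", showWarnings = FALSE)
saveRDS(list(mr = mr_fit, speed = speed_fit, maxspeed = maxspeed_fit),
        "scratch/fits.rds")
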