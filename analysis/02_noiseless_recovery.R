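#!/usr/bin/env Rscript
# Noiseless end-to-end validation: simulate the 1-h bicarbonate labeling
# calibration scenario (intact-cell turnover rates for galactose, glycerol
# and 16:0), deconvolve the MIDs, and invert the steady-state model to the
# turnover rates. With the model-based estimator and the true enrichment on
# the grid, recovery is exact to machine precision; the default stripping
# estimator carries only its small shift-truncation bias.

library(midtrace)

dir.create("results", showWarnings = FALSE)

sc <- read_scenario(system.file("extdata", "scenario_bicarbonate_mid.yaml",
                                package = "midtrace"))
fit_based <- run_scenario_pipeline(sc, method = "fit",
                                   p_grid = c(seq(0.05, 0.95, 0.05), 0.99))
strip_based <- run_scenario_pipeline(sc)

fit_based$estimator <- "fit"
strip_based$estimator <- "strip"
out <- rbind(fit_based, strip_based)
write.csv(out, "results/recovery_noiseless.csv", row.names = FALSE)

message("noiseless turnover recovery (1-h labeling, 13C bicarbonate):")
print(out, row.names = FALSE, digits = 6)
message(sprintf("max |k_rec - k_true|: fit %.2e, strip %.2e",
                max(abs(fit_based$k_recovered - fit_based$k_true)),
                max(abs(strip_based$k_recovered - strip_based$k_true))))
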