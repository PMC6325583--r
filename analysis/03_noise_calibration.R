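#!/usr/bin/env Rscript
# Ion-counting noise calibration: how the recovered turnover rate degrades
# with the multinomial ion budget. 50 seeded replicates per ion count on
# the galactose pool (k = 0.092 per h, 1-h labeling, p = 0.99 substrate
# enrichment), default stripping estimator.

library(midtrace)

dir.create("results", showWarnings = FALSE)

frag <- default_fragments()["galactose"]
k_true <- c(galactose = 0.092)
ion_counts <- c(1e3, 1e4, 1e5, 1e6)
n_rep <- 50L

rows <- list()
for (n_ions in ion_counts) {
  rel_err <- vapply(seq_len(n_rep), function(s) {
    sc <- simulation_scenario(frag, k_true, p_label = 0.99,
                              n_ions = n_ions, seed = 10000 + s)
    run_scenario_pipeline(sc)$rel_error
  }, numeric(1))
  rows[[length(rows) + 1L]] <- data.frame(
    n_ions = n_ions, n_replicates = n_rep,
    median_rel_error = median(rel_err),
    median_abs_rel_error = median(abs(rel_err)),
    q90_abs_rel_error = unname(quantile(abs(rel_err), 0.9)))
}
calib <- do.call(rbind, rows)
write.csv(calib, "results/noise_calibration.csv", row.names = FALSE)

message("turnover recovery error vs ion budget (galactose, k = 0.092/h):")
print(calib, row.names = FALSE, digits = 3)
message("median |relative error| shrinks monotonically with the ion count: ",
        all(diff(calib$median_abs_rel_error) < 0))
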