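#!/usr/bin/env Rscript
# Parameter-recovery benchmarks: refit quality (R^2) on noisy synthetic
# serum-to-2i courses, and recovery of the serum maintenance efficiency
# p2 from a steady-state course initialized with simulated hairpin data.
# Writes: results/fit_quality.tsv, results/p2_recovery.tsv,
#         results/p2_surface.tsv
# Usage: Rscript analysis/02_parameter_recovery.R [seed]

library(dyadkin)
dir.create("results", showWarnings = FALSE)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

fq <- benchmark_fit_quality(seed = seed, n_seeds = 10L, noise_sd = 0.01)
write.table(data.frame(replicate = seq_along(fq$r2),
                       r_squared = sprintf("%.6f", fq$r2)),
            "results/fit_quality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Median refit R^2 over %d noisy replicates: %.4f\n",
            length(fq$r2), fq$median_r2))

p2b <- benchmark_p2_recovery(seed = seed, noise_sd = 0.01, n_reads = 1e5)
write_surface_tsv(p2b$fit$surface, "results/p2_surface.tsv")
write.table(data.frame(quantity = c("p2_true_percent", "p2_recovered_percent"),
                       value = sprintf("%.3f", c(p2b$p2_true_percent,
                                                 p2b$p2_percent))),
            "results/p2_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Serum maintenance efficiency: true %.1f%%, recovered %.2f%%\n",
            p2b$p2_true_percent, p2b$p2_percent))
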