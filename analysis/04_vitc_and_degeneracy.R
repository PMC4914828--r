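#!/usr/bin/env Rscript
# Vitamin-C response and identifiability: recover the vitC fold increase
# of oxidation (p3) from paired synthetic courses, then demonstrate the
# two-solution degeneracy of 5mC-only fits on a fast-decay (PGC-like)
# series, where distinct (p2, p3) combinations explain 5mC equally well
# but predict very different 5hmC dynamics.
# Writes: results/vitc_ratio.tsv, results/degeneracy_minima.tsv,
#         results/degeneracy_surface.tsv
# Usage: Rscript analysis/04_vitc_and_degeneracy.R [seed]

library(dyadkin)
dir.create("results", showWarnings = FALSE)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

vc <- benchmark_vitc_p3_ratio(seed = seed, noise_sd = 0.005,
                              multiplier = 4)
write.table(data.frame(quantity = c("p3_2i", "p3_vitc", "ratio",
                                    "ratio_true"),
                       value = sprintf("%.5f", c(vc$p3_2i, vc$p3_vitc,
                                                 vc$ratio, 4))),
            "results/vitc_ratio.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Fitted p3: 2i %.4f, 2i+vitC %.4f -> ratio %.3f (true 4)\n",
            vc$p3_2i, vc$p3_vitc, vc$ratio))

# PGC-like fast decay, 5mC-only objective, p2 and p3 free
init <- steady_state_dyads(serum_params())
truth <- rate_params(0.02, 0.30, 0.05)
times <- seq(0, 96, by = 12)
tr <- simulate_trajectory(init, truth, times)
set.seed(seed)
obs <- observation_series(
  times, pmax(0, tr$levels$five_mC + rnorm(length(times), 0, 0.01)))
fit <- grid_search(obs, init,
                   fit_spec(c("p2", "p3"), base = truth, grid_n = 41L,
                            refine = FALSE))
write_surface_tsv(fit$surface, "results/degeneracy_surface.tsv")

minima <- fit$minima
minima$peak_five_hmC <- vapply(seq_len(nrow(minima)), function(i)
  max(simulate_trajectory(
    init, rate_params(truth$p1, minima$p2[i], minima$p3[i]),
    times)$levels$five_hmC), numeric(1))
write.table(cbind(lapply(minima, function(x) sprintf("%.5g", x))),
            "results/degeneracy_minima.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\n%d local minima on the 5mC-only (p2, p3) surface.\n",
            nrow(minima)))
print(minima, row.names = FALSE)
cat(sprintf("Peak 5hmC forecast spans a %.1f-fold range across minima:\n",
            max(minima$peak_five_hmC) / min(minima$peak_five_hmC)))
cat("5mC alone cannot separate impaired maintenance from high TET\n")
cat("activity; the predicted 5hmC course discriminates the solutions.\n")
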