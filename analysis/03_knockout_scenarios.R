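#!/usr/bin/env Rscript
# Knockout predictions: how deleting parts of the methylation machinery
# reshapes the serum-to-2i demethylation curve, without refitting.
# Writes per-knockout trajectory TSVs and a half-life comparison table
# under results/.

library(dyadkin)
dir.create("results", showWarnings = FALSE)

serum <- serum_params()
two_i <- two_i_params()
init <- steady_state_dyads(serum)
times <- c(0, 4, 8, 16, 24, 32, 48, 72, 96, 168, 240, 336)

kos <- c("none", "dnmt1_or_uhrf1", "dnmt3ab", "tet_any", "aicda_or_tdg")
wt <- predict_scenario(init, serum, two_i, scenario_spec(), times)

rows <- lapply(kos, function(ko) {
  tr <- predict_scenario(init, serum, two_i, scenario_spec(ko), times)
  write_timecourse_tsv(tr, sprintf("results/ko_%s.tsv", ko))
  cmp <- compare_rates(tr, wt)
  half <- cmp$crossings$time_a[cmp$crossings$fraction == 0.5]
  data.frame(knockout = ko,
             five_mC_day14 = sprintf("%.4f", tr$levels$five_mC[12]),
             five_hmC_day14 = sprintf("%.5f", tr$levels$five_hmC[12]),
             half_level_time_h = sprintf("%.1f", half))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/knockout_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

cat("\nMaintenance loss (dnmt1_or_uhrf1) accelerates demethylation;\n")
cat("de novo loss (dnmt3ab) barely changes it; TET loss (tet_any)\n")
cat("abolishes 5hmC by replication dilution; aicda_or_tdg is identical\n")
cat("to wild type by construction.\n")
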