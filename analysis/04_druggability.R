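#!/usr/bin/env Rscript
# Retrospective evaluation of the promising-target rule: outcome labels
# of the 16 previously promising phase-3 targets, and per-phase promising
# rates on synthetic flag cohorts.

suppressMessages(library(dtprofiler))

dir.create("results", showWarnings = FALSE)
ev <- evaluate_cohort(phase3_status_table())
out <- data.frame(label = names(ev$counts), count = ev$counts,
                  pct_printed = ev$pct_printed)
rownames(out) <- NULL
write.table(out, "results/status_evaluation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("development outcomes of the ", ev$n, " promising phase-3 targets:")
print(out, row.names = FALSE)
message("cross-tabulation promising x outcome:")
print(ev$crosstab)

# synthetic flag cohorts: promising fractions engineered at the reported
# per-phase identification rates (50/25/10/4%)
set.seed(20160728L)
mk <- function(phase, n, frac) {
  k <- round(n * frac)
  data.frame(phase = phase,
             A = TRUE, B = c(rep(TRUE, k), rep(FALSE, n - k)),
             C = c(rep(TRUE, k), rep(FALSE, n - k)), D = FALSE)
}
targ <- rbind(mk("phase3", 32, 0.50), mk("phase2", 40, 0.25),
              mk("phase1", 40, 0.10), mk("nonclinical", 200, 0.04))
rates <- prediction_rates(targ)
write.table(rates, "results/prediction_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("per-phase promising fractions on the synthetic flag cohorts:")
print(rates, row.names = FALSE)
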