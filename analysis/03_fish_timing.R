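#!/usr/bin/env Rscript
# Replication-timing statistics from interphase FISH of FACS-sorted
# S-phase fractions: rebuild the percentage/SE tables from the shipped raw
# counts, compare control vs mutant patterns by chi-square, and illustrate
# the detection power of the design on simulated nuclei.

suppressPackageStartupMessages(library(replicomb))
dir.create("results", showWarnings = FALSE)
cnt <- fxn_timing_counts()

sink("results/timing_tables.txt")
for (s in unique(cnt$sample)) {
  for (f in c("S1", "S2", "S3", "S4")) {
    cat(sprintf("== %s, fraction %s ==\n", s, f))
    print(timing_table_for(cnt, s, f))
    cat("\n")
  }
}
sink()
cat("wrote per-fraction timing tables to results/timing_tables.txt\n")

# chi-square comparisons per substage on the first-half fractions
pool <- function(sample, frs) {
  m <- matrix(0L, 4, 3, dimnames = list(c("SS", "SD", "DD", "OTHER"),
                                        c("early", "mid", "late")))
  for (f in frs) m <- m + timing_table_for(cnt, sample, f)$counts
  m
}
for (sub in c("early", "mid")) {
  a <- pool("control", c("S1", "S2"))
  b <- pool("frda", c("S1", "S2"))
  c4 <- compare_patterns(a, b, sub, c("SS", "SD", "DD", "OTHER"))
  c3 <- compare_patterns(a, b, sub, c("SS", "SD", "DD"))
  cat(sprintf(
    "S1+S2 %s-S cells, control vs mutant: chi2 = %.1f, p = %.2g (with OTHER); p = %.2g (without)\n",
    sub, c4$chi2, c4$p, c3$p))
}

# simulated nuclei: a per-allele completion-probability shift of the size
# seen in the counts is comfortably detectable at ~500 nuclei per fraction
subm <- matrix(c(0.10, 0.85, 0.05), 1,
               dimnames = list("S2", c("early", "mid", "late")))
ctrl <- simulate_nuclei(timing_sim_params(c(S2 = 0.55), subm, c(S2 = 500),
                                          detection_failure_prob = 0.06,
                                          seed = 71))
frda <- simulate_nuclei(timing_sim_params(c(S2 = 0.42), subm, c(S2 = 500),
                                          detection_failure_prob = 0.10,
                                          seed = 72))
p <- compare_patterns(build_timing_table(ctrl), build_timing_table(frda),
                      "mid")$p
cat(sprintf("simulated S2 shift (allele completion 0.55 vs 0.42): p = %.2g\n",
            p))
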