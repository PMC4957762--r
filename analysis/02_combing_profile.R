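#!/usr/bin/env Rscript
# Orient and classify the simulated fibers, map origins and pauses, build
# per-allele replication profiles, and compare the fork-rate / IOD /
# unidirectional-length distributions between alleles.

suppressPackageStartupMessages(library(replicomb))
dir.create("results", showWarnings = FALSE)

profiles <- list()
values <- list(rate = list(), iod = list(), unidir = list())
for (allele in c("normal", "expanded")) {
  loc <- fxn_locus(expanded = allele == "expanded")
  mols <- read_track_table(file.path("results",
                                     paste0("tracks_", allele, ".tsv")))
  res <- classify_molecules(mols, loc)
  ev <- res$events
  utils::write.table(ev, file.path("results",
                                   paste0("events_", allele, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_positions_bed(ev, loc,
                      file.path("results", paste0("origins_", allele, ".bed")),
                      what = "origin")
  write_positions_bed(ev, loc,
                      file.path("results", paste0("pauses_", allele, ".bed")),
                      what = "pause")
  pr <- summarize_profile(allele, res$molecules, ev, loc)
  profiles[[allele]] <- pr
  write_profile_json(pr, file.path("results",
                                   paste0("profile_", allele, ".json")))
  print(pr)
  fre <- fork_rate_estimate(ev)
  cat(sprintf("  censored-MLE mean fork rate: %.2f kb/min (%d arms)\n",
              fre$mean_p1_mle, fre$n_p1_total))
  gos <- gene_origin_stats(ev, loc)
  cat(sprintf("  origins inside the gene: %d on %d molecules\n",
              gos$origins_in_gene, gos$molecules_with_gene_origin))
  rto <- repeat_template_orientation(ev, loc)
  cat(sprintf("  forks crossing the repeat: %d lagging-template, %d leading-template\n",
              rto$lagging, rto$leading))
  values$rate[[allele]] <- fork_rate_estimate(ev)$rates_complete
  values$iod[[allele]] <- inter_origin_distances(ev)
  values$unidir[[allele]] <-
    unidirectional_length_stats(ev, loc, "central")$lengths
}

write_profile_report(profiles, "results/profile_report.txt")
for (metric in names(values)) {
  kw <- compare_profiles(values[[metric]])
  cat(sprintf("Kruskal-Wallis (%s): H = %.2f, p = %.3g\n",
              metric, kw$H, kw$p))
}
uN <- unidirectional_length_stats(
  utils::read.delim("results/events_normal.tsv"), fxn_locus(), "central")
uE <- unidirectional_length_stats(
  utils::read.delim("results/events_expanded.tsv"),
  fxn_locus(expanded = TRUE), "central")
cat(sprintf(
  "central unidirectional forks: normal mean %.1f kb (CV %.0f%%), expanded mean %.1f kb (CV %.0f%%)\n",
  uN$mean, uN$cv_pct, uE$mean, uE$cv_pct))
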