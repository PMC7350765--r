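#!/usr/bin/env Rscript

# 06 — Target-consensus statistics.
#
# Pools each condition's insertions, tabulates pentamer abundance on the
# cohort genome, and estimates the abundance-normalized CYSRG fold
# preference (generated: 7-fold WT, 20-fold MuB-less), plus the extended
# (NCYSRGN / CYSRGNN / NNCYSRG) scan, which should stay within a few
# percent of the core fold when only the 5-mer drives target choice.

suppressMessages(library(mutargets))

genome <- load_fasta("scratch/cohort_genome.fa")
tab <- pentamer_table(genome, "CYSRG")
launch <- c("OPL", "OPR", "TPL", "TPR", "TerMu", "OriMu")

set.seed(20260928)
out <- list()
for (cond in c("WT", "dMuB")) {
  ev <- do.call(rbind, lapply(launch, function(lab)
    utils::read.table(sprintf("scratch/events_%s_%s.tsv", cond, lab),
                      header = TRUE, sep = "\t")))
  f <- fold_preference(ev, tab)
  message(sprintf("%s: CYSRG fold preference %.2f over %d insertions",
                  cond, as.numeric(f), nrow(ev)))
  sc <- extended_consensus_scan(ev[sample.int(nrow(ev), 2e4), ], genome)
  sc$condition <- cond
  out[[cond]] <- sc
}
utils::write.table(do.call(rbind, out), "results/consensus_folds.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
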