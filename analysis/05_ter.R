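#!/usr/bin/env Rscript

# 05 — Ter macrodomain analysis on the MuB-less cohort.
#
# Per-donor Ter insertion fractions (the in-Ter donor should retain >40%
# of its insertions inside Ter; the five outside donors <15%), and the
# circular two-changepoint segmentation of the in-vs-out contrast, which
# recovers the planted 911-2200 kb compartment at bin (~23 kb) resolution.

suppressMessages(library(mutargets))

L <- 4641652
launch <- c(OPL = 3339450, OPR = 263131, TPL = 2555144,
            TPR = 792226, TerMu = 1657887, OriMu = 4203381)
tm <- ter_model()

pros <- lapply(names(launch), function(lab)
  prophage_locus(launch[[lab]], launch[[lab]] + 36999L, "dMuB", lab))
evs <- lapply(names(launch), function(lab)
  utils::read.table(sprintf("scratch/events_dMuB_%s.tsv", lab),
                    header = TRUE, sep = "\t"))
names(evs) <- names(launch)

frac <- vapply(evs, region_fraction, 0, left = tm$left, right = tm$right,
               L = L)
utils::write.table(data.frame(donor = names(frac), ter_fraction_pct = frac,
                              in_ter = names(frac) == "TerMu"),
                   "results/ter_fractions.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("Ter fractions (%): ",
        paste(sprintf("%s=%.1f", names(frac), frac), collapse = ", "))
message(sprintf("Ter spans %.1f%% of the genome",
                region_span_fraction(tm$left, tm$right, L)))

bm <- bin_matrix(evs, L, prophages = pros, n_bins = 200)
tc <- detect_ter_boundaries(bm, "TerMu", setdiff(names(launch), "TerMu"))
print(tc)
utils::write.table(data.frame(left_bp = tc$left, right_bp = tc$right,
                              left_bin = tc$left_bin,
                              right_bin = tc$right_bin, score = tc$score),
                   "results/ter_call.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
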