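#!/usr/bin/env Rscript

# 01 — Simulate the study cohort.
#
# Six prophage launch sites spread around a 4,641,652 bp circular genome
# (the positions of the six monitored strains), each sampled in WT and
# MuB-less (dMuB) early-stage modes: WT gets the 7-fold CYSRG preference
# and the 1.5 kb cis-immunity dead zone; dMuB gets the 20-fold preference,
# the 550 bp two-phase immunity profile and Ter-compartment mixing.
# Event tables go to scratch/ (inputs for 02-07); a sequencing library for
# the OPL WT prophage exercises the read-level pipeline.

suppressMessages(library(mutargets))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

L <- 4641652
seed <- 20260928L
genome <- generate_genome(L, gc = 0.5, seed = seed)
write_fasta(genome, "scratch/cohort_genome.fa")

launch <- c(OPL = 3339450, OPR = 263131, TPL = 2555144,
            TPR = 792226, TerMu = 1657887, OriMu = 4203381)
n_per_donor <- 10000L

for (cond in c("WT", "dMuB")) {
  pros <- lapply(names(launch), function(lab)
    prophage_locus(launch[[lab]], launch[[lab]] + 36999L,
                   mub_status = cond, label = lab))
  cfg <- sim_config(
    genome, pros,
    consensus = consensus_model(fold = default_fold(cond)),
    immunity = immunity_model(if (cond == "WT") "WT_EST" else "dMuB_EST"),
    ter = if (cond == "dMuB") ter_model() else NULL)
  for (lab in names(launch)) {
    ev <- sample_insertions(cfg, n_per_donor, donor = lab,
                            seed = seed + match(lab, names(launch)) +
                              100L * (cond == "dMuB"))
    utils::write.table(ev, sprintf("scratch/events_%s_%s.tsv", cond, lab),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message(cond, ": ", n_per_donor, " insertions sampled per donor at ",
          length(launch), " launch sites")
}

# read-level library for one prophage (WT OPL) on a reduced genome so the
# junction caller is exercised end to end at desk scale
g0 <- generate_genome(2e5, gc = 0.5, seed = seed + 7L)
pr <- insert_prophage(g0, at = 1e5, mu_length = 37000L, seed = seed + 8L,
                      label = "OPL")
chem <- library_chemistry(pcr_duplication = 1.5)
cfg_lib <- sim_config(pr$genome, list(pr$prophage),
                      consensus = consensus_model(fold = 7),
                      immunity = immunity_model("WT_EST"), chem = chem)
ev_lib <- sample_insertions(cfg_lib, 5000, seed = seed + 9L)
lib <- make_library(ev_lib, pr$genome, chem,
                    "scratch/opl_wt_R1.fastq", "scratch/opl_wt_R2.fastq",
                    truth_tsv = "scratch/opl_wt_truth.tsv",
                    seed = seed + 10L)
write_fasta(pr$genome, "scratch/opl_genome.fa")
message("library: ", lib$n_pairs, " read pairs from ", nrow(ev_lib),
        " events (", lib$n_dropped, " fragments dropped as too short)")
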