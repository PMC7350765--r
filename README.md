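# mutargets

Genome-wide mapping of bacteriophage Mu transposition targets from
target-enriched sequencing reads, and quantification of target immunity.

Mu replicates by transposing its ~37 kb genome into its host's chromosome,
duplicating a 5-bp target site on insertion. Sequencing Mu–host junctions
from a target-enrichment library (HinP1 digestion, y-link adapter with a
6-nt UMI and a 12-mer signature, 2×150 paired reads) turns every
transposition event into a nucleotide-precision coordinate. `mutargets`
implements the full computational chain over such data:

* **Simulator** — a generative model of transposition (degenerate `CYSRG`
  consensus preference, distance-dependent cis-immunity around resident
  prophages, two-compartment Ter macrodomain mixing, rare self-insertion)
  and of the sequencing library itself (restriction fragments, UMIs,
  adapter structure, PCR duplicates), with truth tags so every downstream
  stage is testable offline.
* **Junction caller** — Mu-end/adapter signature detection, exact
  seed-and-verify read mapping (k = 20), UMI deduplication keyed on
  `(position, strand, UMI)`, self-insertion classification; SAM import for
  externally aligned reads. Run reports satisfy
  `reads_in = rejected + unmapped + ambiguous + counted` exactly.
* **Statistics** — 200-bin normalized insertion matrices; insertion
  frequency per 100 bp vs distance from the prophage ends, with bulk
  baseline and 2-vs-3 phase detection; circular two-changepoint
  segmentation of the Ter compartment; abundance-normalized consensus fold
  preference,
  `fold = (consensus ins / consensus sites) / (other ins / other sites)`;
  gene-, tRNA- and operon-relative insertion profiles with exclusion-zone
  calling.

The repository is an analysis workflow: `analysis/01_simulate.R` …
`analysis/07_feature_profiles.R` are thin drivers over the package,
writing tables to `results/` (large intermediates go to `scratch/`). The
methods vignette (`vignettes/mu-target-mapping.Rmd`) documents the models,
conventions and numerical choices.

## Worked example

Simulate a WT early-stage prophage, sequence it, call insertions and
measure the target preference and immunity phases:

```r
library(mutargets)

g  <- generate_genome(200000, gc = 0.5, seed = 1)
pr <- insert_prophage(g, at = 100000, mu_length = 37000, seed = 2,
                      label = "OPL")
genome <- pr$genome; prophage <- pr$prophage

chem <- library_chemistry(pcr_duplication = 1.5)
cfg  <- sim_config(genome, list(prophage),
                   consensus = consensus_model(fold = 7),
                   immunity = immunity_model("WT_EST"), chem = chem)
events <- sample_insertions(cfg, 10000, seed = 3)
make_library(events, genome, chem, "r1.fq", "r2.fq", seed = 4)

res <- call_insertions(fastq1 = "r1.fq", fastq2 = "r2.fq",
                       genome = genome, chem = chem,
                       prophages = list(prophage))
res
#> <mu_call> fastq mode: 13961 reads in; rejected 0 (mu_end 0, adapter 0,
#>   short 0); unmapped 0; ambiguous 0; counted 13961 -> 9193 unique
#>   insertions (0 self)

fold_preference(res$insertions, pentamer_table(genome, "CYSRG"), genome)
#> CYSRG fold preference: 6.41

detect_phases(distance_profile(res$insertions, prophage, genome$length),
              bulk_baseline(res$insertions, prophage, genome$length))
#> <phase_report> 3 phase(s); first insertion L/R: 2200/2400 bp;
#>   boundary 6500 bp; bulk reach 7400 bp
```

Every read maps back to a simulated event (13,961 reads are PCR copies of
9,193 ligation fragments, collapsed by UMI). The fold estimate of 6.41
recovers the generated 7-fold preference within the sampling error of
~9,000 insertions; the phase report shows the three-phase WT immunity
signature — no insertions within ~2 kb of either prophage end, a sharp
rise near 6 kb, bulk insertion density from ~7 kb.

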