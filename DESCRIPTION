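Package: mutargets
Title: Mapping Bacteriophage Mu Transposition Targets from Target-Enriched Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of bacteriophage Mu transposition target
    selection on a circular bacterial chromosome. Provides a generative
    simulator of Mu insertion events and of the restriction-digest / y-link
    adapter target-enrichment sequencing library (HinP1 digestion, 6-nt UMI,
    12-mer adapter signature, PCR duplication); a junction caller that
    recovers nucleotide-precision Mu-host junctions from paired FASTQ or SAM,
    deduplicates by UMI and classifies self-insertions; and downstream
    statistics: 200-bin genome insertion matrices, distance-resolved
    cis-immunity profiles with phase detection, circular two-changepoint
    segmentation of the Ter macrodomain, degenerate-consensus (CYSRG)
    fold-preference estimation, and gene-, tRNA- and operon-relative
    insertion profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests: testthat (>= 3.0.0), rtracklayer, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
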