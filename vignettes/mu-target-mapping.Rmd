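---
title: "Mapping Mu transposition targets: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Mu transposition targets: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutargets)
```

## The problem

Bacteriophage Mu replicates by transposing its ~37 kb genome into
essentially random positions of its host's chromosome. Deep sequencing of
target-enriched Mu–host junctions turns each transposition event into a
nucleotide-precision coordinate, and the genome-wide pattern of those
coordinates carries several distinct signals at very different length
scales:

* a 5-bp **target consensus** (`CYSRG`, with Y = C/T, S = G/C, R = A/G)
  preferred a few-fold over the other pentamers;
* **cis-immunity** — a MuB-dependent avoidance of the few kb immediately
  flanking a resident prophage's ends;
* **Mu genome immunity** — near-absolute avoidance of insertion into the
  prophage itself (self-insertion, SI);
* chromosome-scale structure: the replication-terminus (**Ter**)
  macrodomain exchanges insertions with the rest of the chromosome less
  freely than any other region, visible as a block in per-prophage binned
  insertion matrices;
* local transcription/translation effects: exclusion zones around the +1
  nt of active genes, avoidance of mature tRNA regions and rRNA-operon
  coding segments.

`mutargets` implements the full computational chain for all of these —
a generative simulator of transposition and of the sequencing library, a
junction caller, and the downstream statistics — so that every stage can
be validated by parameter recovery without access to the original
sequencing data. The package is organised as an analysis workflow: the
numbered scripts under `analysis/` are thin narrative drivers over the
exported functions, writing their tables under `results/`.

## Coordinates

All user-facing positions are 1-based inclusive, on a circular chromosome
by default; the circular distance between positions is the shorter arc.
An insertion's coordinate is the **first base of the 5-bp target-site
duplication in the + strand frame**, regardless of the orientation of the
inserted Mu. A fixed anchor makes deduplication, binning and distance
profiles well-defined; the two strands of one duplication event are kept
as separate rows (whether published pipelines collapse the two strands of
one duplication event is unstated, so the finer-grained convention is
used and documented).

## The generative model

`sample_insertions()` draws insertion positions with probability
proportional to a per-position weight:

```
weight(p) = base(p)                      0 inside resident prophages
          x fold                         if the 5-mer at p (either strand)
                                         matches the consensus pattern
          x immunity(d(p))               d = distance to the nearest
                                         prophage end
          x ter_factor(donor, p)         2-compartment Ter mixing
          x exp(-propensity(p))          optional transcription exclusion
```

With probability `self_insertion_rate` an event is instead placed
uniformly inside its donor prophage and flagged.

**Consensus.** Defaults are the generated conditions: fold 7 for WT and 20
for MuB-deleted prophages. The `CYSRG` expansion has 8 members, is closed
under reverse complement and contains no palindromes (asserted by
enumeration in the tests), so the + strand anchor never changes class
membership.

**Cis-immunity.** The published phase locations constrain the curve only
at a few points (dead zone to 1.5 kb, slow rise from ~2 kb, sharp rise
near 5 kb, bulk by ~7 kb for WT; a single ramp from 500–600 bp for
MuB-less early stage; from 98 bp reaching bulk by ~2 kb late stage).
The functional form between those knots is not published, so the weight is
piecewise linear — the least-committed interpolation — with the WT value
at the 5 kb knot set to 0.15, a low plateau representing the weak
initial phase. These are declared calibrations, not measurements.

**Ter mixing.** A full contact map is not needed for a compartment-level
claim, so Ter insulation is a two-compartment mixture: an event from an
in-Ter donor places probability mass `retention` (default 0.45) inside
the Ter interval (default 911–2200 kb on the 4,641,652 bp chromosome);
events from outside donors place `exclusion` (default 0.12) there. The
defaults sit inside the reported >40% / <15% bounds; the factor is exact
under a spatially uniform base weight and only approximately equal to the
realized fraction once consensus weighting is layered on (the
approximation error is well under a percentage point at default
parameters).

**Multi-hop (late stage).** `sample_insertions_lst()` approximates
copy-number growth by re-running the sampler over a growing donor set
(2 new donors per round, 3 rounds by default, matching the reported 5–10
copies per cell); the new prophages occupy intervals on the *unchanged*
coordinate axis — the reference sequence is not re-spliced between rounds.

**Self-insertion.** The default rate for MuB-less late stage is 1e-6 per
event — an order-of-magnitude calibration from the reported 85 events in
90 million targeted reads, not a measured constant.

## The library model and the junction caller

`make_library()` emulates the y-link target-enrichment chemistry. The
host fragment runs from the junction base outward to the nearest
restriction cut; HinP1 cuts `G^CGC`, so the top-strand fragment retains
the leading G of the site (a site planted `d` bp downstream of a junction
yields a `d + 1` bp fragment) and the bottom-strand fragment retains
through the third site base. Read 1 is Mu-end signature + host fragment
(+ reverse-complemented adapter and UMI when the fragment is short);
read 2 is UMI (6 nt) + 12-mer adapter signature + reverse-complemented
host. Fragments longer than the read are truncated by the read, as on a
sequencer, rather than discarded; only fragments shorter than 20 bp
(unmappable) are dropped, and counted. PCR duplication emits
`1 + Poisson(mean - 1)` copies per fragment sharing one UMI, optionally
with independent substitution errors.

`call_insertions()` inverts this: signature checks (exact by default; the
published tolerance for the 12-mer/Mu-end matches is not stated, so 0 is
the default and a flag), adapter trimming including partial adapter
suffixes at the read end, exact **seed-and-verify mapping** (k = 20 seed
index, full-length verification, both strands, circular wrap), UMI
deduplication keyed on `(position, strand, UMI)` — a 6-nt UMI alone
collides genome-wide — and SI classification requiring a *novel* junction
strictly inside a prophage, at least 5 bp away from the two resident end
junctions. Mismatch-tolerant alignment is out of scope for the built-in
mapper; externally aligned reads enter through SAM (`RX` tag carries the
UMI). Every run report satisfies
`reads_in = rejected + unmapped + ambiguous + counted` exactly, and
ambiguous (multi-hit) fragments never reach downstream statistics.

## Binning and normalization

The genome is partitioned into 200 bins of `ceiling(L / 200)` bp
(23,209 bp ≈ 23.2 kb for 4,641,652 bp); the final bin may be short — at
most 1 bp per bin of deviation from exactly equal widths, in exchange for
integer arithmetic. The exact published normalization formula is unavailable — the only
constraint is that the cohort maximum over non-starting bins sits just
under 1 — so both modes
are provided and named: `"depth"` scales rows by read depth and maps the
cohort maximum over non-starting bins to 0.995; `"max"` does the same
row-wise. Starting bins stay in the matrix, flagged, capped at 1 and
excluded from maxima.

## Immunity phase detection

The published phases were identified visually; the detector makes the
operationalization explicit:

* `first_insertion` — lower edge of the first nonzero 100-bp window,
  per end and combined (combined profiles *sum* the two ends, so bulk
  comparisons use twice the baseline mean with sd scaled by sqrt(2));
* `bulk_reach` — first distance from which 5 consecutive windows stay at
  or above the bulk mean minus one sd (where a profile reaches bulk is
  inherently a visual judgement; the k-run rule makes it explicit);
* `boundary_distance` — the argmax of centered slopes of the 3-window
  smoothed profile, slopes taken over a ±1 kb span. On an exact step
  profile the argmax plateau is symmetric around the step and its midpoint
  recovers the step position exactly; under count noise the wide span
  keeps the consensus-site overdispersion from mimicking a sharp rise;
* `n_phases` — 3 only when the slope maximum is *significant*: above
  twice the median slope over the searched range **and** above a robust
  noise threshold (median + z·1.4826·MAD, z the 1% Bonferroni quantile
  for the number of slopes examined). The two conditions together keep a
  noisy uniform ramp — the MuB-less signature — from being split into
  three phases; the 2×-median rule alone misclassifies such ramps at
  realistic densities.

## Ter boundary segmentation

The compartment is read from the cohort the way the binned matrices show
it: the contrast between in-Ter and out-of-Ter donors. Rows are scaled to
unit total (starting bins masked), the contrast is the difference of the
two group means per bin, and the boundary call is the exhaustive circular
two-changepoint segmentation — the bin vector is doubled and every
(start, length) segment with length < 200 is scored. The score is the
variance-weighted mean difference
`(mean_in − mean_out)·sqrt(n_in·n_out/n)`, the two-sample scan statistic:
the *unweighted* difference of segment means is degenerate (it is always
maximized by the single most extreme bin) and cannot recover an extended
compartment. Ties break toward the widest segment; boundaries are
reported at bin (~23 kb) resolution, matching the precision of the claim
being reproduced. A brute-force enumeration oracle checks the search on
small instances in the tests.

## Consensus fold statistic

The fold is a ratio of per-site rates:

```
fold = (consensus insertions / consensus genome sites)
     / (other insertions     / other genome sites)
```

This is the only reading under which a genomic-abundance-normalized
"7-fold" is meaningful — raw counts would conflate preference with site
abundance (triple-G pentamers are 3–4× more abundant than consensus sites
in GC-balanced genomes, which is exactly the historical confounder this
normalization removes). Genome sites are counted once per + strand anchor
with circular wrap (counts sum to L); reverse-complement occurrences are
not added separately because the consensus class is reverse-complement
closed. When either insertion count is zero a pseudocount of 0.5 is added
to both numerators and the result is flagged — folds must stay finite on
small fixtures. Extended patterns (`NCYSRGN`, `CYSRGNN`, `NNCYSRG`, or any
pattern containing the core) are scored in the *anchor frame*: a position
is in the extended class when the window around its core anchor matches
the pattern on either strand, so genome sites and insertions are
classified identically and a pure 5-mer preference yields extended folds
exactly equal to the core fold.

## Feature profiles

Gene-relative profiles anchor at the annotated +1 nt of the CDS (the TSS
is a fixed −125 display offset); offsets are zero-free (the base before
+1 is −1) and minus-strand features are flipped so downstream is positive.
The exclusion zone is the maximal run of *strictly zero* counts containing
the +1 offset — a "low counts" definition would need a depth-dependent
threshold, whereas the zero-run is exact and its sensitivity to depth is
the caller's to manage. tRNA rows are flagged when the mature region
[+1, +75] is empty while the leader [−200, −1] is not. Coding fractions
report the observed CDS share of a window's insertions next to the
uniform expectation (the CDS share of the window in bp).

## Problem sizes and determinism

All simulations are desk-scale by design: fold recovery uses 1e5 events
on a 1 Mb genome; Ter analyses use 2e4 events per donor on the full
4,641,652 bp coordinate system; immunity phase detection uses 2e5 events
around a prophage on a 200 kb genome; the end-to-end read-level runs use
1e4–2e5 events. At these sizes the recovered parameters sit within a few
percent of their generated values (the acceptance script recomputes them
from scratch). Every stochastic step takes an explicit seed, and a fixed
configuration plus seed reproduces byte-identical FASTQ.

## What the simulator does and does not emulate

It emulates the library *structure*: junction-anchored fragments,
restriction-digest ends, UMIs, adapter signatures, PCR duplication,
truncation at read length, and truth tags for validation. It does not
emulate base-quality profiles, sequencing-error spectra beyond uniform
substitutions, chimeric fragments, adapter dimers, or real chromosomal
context (replication forks, nucleoid-associated protein binding, actual
gene positions). Passing parameter-recovery tests therefore demonstrates
that the *pipeline* is correct and well-calibrated on data with the
declared structure — not that the biological model generating real data
has been validated.

## Known limitations

* The built-in mapper is exact-match only; reads with sequencing errors in
  the host fragment go unmapped rather than mismatch-aligned (use an
  external aligner and SAM import for error-tolerant mapping).
* The Ter model is two-compartment; it cannot express graded insulation
  or sub-compartment structure.
* Multi-hop simulation does not re-splice the reference, so late-stage
  coordinates ignore the physical lengthening of the chromosome by new
  prophage copies.
* `normalize_bins()` offers two plausible normalizations because the
  original formula is unpublished; cross-study comparisons should state
  which mode was used.
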