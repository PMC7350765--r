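# Generative sub-models for the insertion simulator. Defaults are the study
# conditions: a 7-fold (WT) / 20-fold (MuB-less) per-site preference for the
# CYSRG target consensus, a WT cis-immunity dead zone of 1.5 kb with phases
# near 2/5/7 kb, Ter compartment mixing calibrated to >40% retention for
# in-Ter donors and <15% leakage for outside donors, and the y-link
# target-enrichment chemistry (HinP1, 6-nt UMI, 12-mer adapter signature).

#' Target-consensus preference model
#'
#' Per-site multiplicative preference for sites whose 5-mer (on either
#' strand) matches a degenerate IUPAC pattern. The default pattern `CYSRG`
#' expands to 8 pentamers and is closed under reverse complement, so strand
#' choice does not affect class membership.
#'
#' @param pattern Degenerate IUPAC pattern (default `"CYSRG"`).
#' @param fold Preference multiplier, `>= 1`. Defaults: 7 for WT, 20 for
#'   MuB-deleted prophages (see [default_fold()]).
#' @return An object of class `consensus_model`.
#' @export
consensus_model <- function(pattern = "CYSRG", fold = 7) {
  if (fold < 1) stop("fold must be >= 1")
  if (length(expand_degenerate(pattern)) == 0L)
    stop("pattern expansion is empty")
  structure(list(pattern = toupper(pattern), fold = fold),
            class = "consensus_model")
}

#' Default consensus fold by MuB genotype
#' @param mub_status `"WT"` or `"dMuB"`.
#' @return 7 for WT, 20 for dMuB.
#' @export
default_fold <- function(mub_status) {
  switch(mub_status, WT = 7, dMuB = 20,
         stop("unknown mub_status: ", mub_status))
}

#' Cis-immunity distance model
#'
#' Piecewise-linear insertion-probability multiplier as a function of the
#' distance `d` (bp) from the nearest prophage end, built from named knots:
#'
#' * `WT_EST`: 0 below `d_zero` (1.5 kb dead zone), rising slowly to a low
#'   plateau (`plateau`, default 0.15) at `d_boundary` (5 kb), then sharply
#'   to 1 at `d_bulk` (7 kb) — the three-phase profile.
#' * `dMuB_EST`: 0 below `d_start` (550 bp), then a single linear ramp to 1
#'   at `d_bulk` (7 kb) — the two-phase profile.
#' * `dMuB_LST`: 0 below `d_start` (98 bp), ramping to 1 at `d_bulk` (2 kb).
#' * `none`: constant 1 (bulk sampling).
#'
#' The weight is 0 inside the dead zone, 1 at and beyond `d_bulk`, and
#' non-decreasing in between.
#'
#' @param kind One of `"WT_EST"`, `"dMuB_EST"`, `"dMuB_LST"`, `"none"`.
#' @param d_zero,d_boundary,d_bulk,d_start,plateau Knot overrides (bp and
#'   weight units).
#' @return An object of class `immunity_model` with a `knots` matrix
#'   (columns `d`, `w`).
#' @export
immunity_model <- function(kind = c("WT_EST", "dMuB_EST", "dMuB_LST", "none"),
                           d_zero = 1500, d_boundary = 5000, d_bulk = NULL,
                           d_start = NULL, plateau = 0.15) {
  kind <- match.arg(kind)
  knots <- switch(kind,
    WT_EST = {
      if (is.null(d_bulk)) d_bulk <- 7000
      cbind(d = c(d_zero, d_boundary, d_bulk), w = c(0, plateau, 1))
    },
    dMuB_EST = {
      if (is.null(d_start)) d_start <- 550
      if (is.null(d_bulk)) d_bulk <- 7000
      cbind(d = c(d_start, d_bulk), w = c(0, 1))
    },
    dMuB_LST = {
      if (is.null(d_start)) d_start <- 98
      if (is.null(d_bulk)) d_bulk <- 2000
      cbind(d = c(d_start, d_bulk), w = c(0, 1))
    },
    none = cbind(d = c(0, 0), w = c(1, 1)))
  if (is.unsorted(knots[, "d"]) || is.unsorted(knots[, "w"]))
    stop("immunity knots must be non-decreasing in distance and weight")
  structure(list(kind = kind, knots = knots,
                 d_dead = knots[1, "d"], d_bulk = knots[nrow(knots), "d"]),
            class = "immunity_model")
}

#' Evaluate the immunity weight at distances `d`
#'
#' @param model An [immunity_model()].
#' @param d Numeric distances (bp) from the nearest prophage end.
#' @return Weights in `[0, 1]`: 0 strictly below the dead-zone knot, 1 at and
#'   beyond the bulk knot, linear interpolation between knots.
#' @export
immunity_weight <- function(model, d) {
  k <- model$knots
  if (model$kind == "none") return(rep(1, length(d)))
  w <- stats::approx(k[, "d"], k[, "w"], xout = d, rule = 2, ties = "ordered")$y
  w[d < k[1, "d"]] <- 0
  w
}

#' Ter-compartment mixing model
#'
#' Two-compartment approximation of the Ter macrodomain's insulation: an
#' event from a donor resident in Ter places probability mass `retention`
#' inside the Ter interval; an event from an outside donor places mass
#' `exclusion` there. Defaults (0.45 and 0.12) sit inside the observed >40%
#' and <15% bounds. Default interval: 911-2200 kb on a 4,641,652 bp genome.
#'
#' @param left,right Ter interval (bp, 1-based inclusive).
#' @param retention In-Ter donor probability mass placed in Ter.
#' @param exclusion Out-of-Ter donor probability mass placed in Ter.
#' @return An object of class `ter_model`.
#' @export
ter_model <- function(left = 911000, right = 2200000,
                      retention = 0.45, exclusion = 0.12) {
  stopifnot(left >= 1, right > left,
            retention >= 0, retention <= 1,
            exclusion >= 0, exclusion <= 1)
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 retention = retention, exclusion = exclusion),
            class = "ter_model")
}

#' Target-enrichment library chemistry
#'
#' Parameters of the restriction-digest / y-link adapter protocol emulated
#' by the read simulator and assumed by the junction caller: HinP1 digestion
#' (`GCGC`, cut after the first base leaving a 2-nt 5' CG overhang), a
#' 12-mer adapter signature preceded by a random 6-nt UMI on read 2, and a
#' terminal Mu-end signature at the start of read 1.
#'
#' @param enzyme_site Recognition site (default `"GCGC"`).
#' @param cut_after Bases before the top-strand cut (default 1, i.e. G^CGC).
#' @param adapter_signature 12-mer unique to the y-link adapter.
#' @param umi_length UMI length (default 6).
#' @param mu_end_signature Terminal Mu-end sequence at the start of read 1
#'   (default an arbitrary 31-mer; the enrichment primer offset is a free
#'   parameter).
#' @param read_length Read length, paired (default 150).
#' @param pcr_duplication Mean reads per fragment (>= 1; default 1.5).
#' @param read_depth Nominal depth used for depth normalisation
#'   (default 10e6).
#' @return An object of class `library_chemistry`.
#' @export
library_chemistry <- function(enzyme_site = "GCGC", cut_after = 1L,
                              adapter_signature = "TACGGCTAGCAT",
                              umi_length = 6L,
                              mu_end_signature =
                                "TGTATTGATTCACTTGAAGTACGAAAAAAAC",
                              read_length = 150L, pcr_duplication = 1.5,
                              read_depth = 10e6) {
  if (nchar(adapter_signature) != 12L)
    stop("adapter_signature must be a 12-mer")
  if (umi_length != 6L)
    warning("umi_length differs from the protocol's 6 nt")
  if (pcr_duplication < 1)
    stop("pcr_duplication is a mean reads-per-fragment and must be >= 1")
  if (cut_after < 1L || cut_after >= nchar(enzyme_site))
    stop("cut_after must fall inside the enzyme site")
  structure(list(enzyme_site = toupper(enzyme_site),
                 cut_after = as.integer(cut_after),
                 adapter_signature = toupper(adapter_signature),
                 umi_length = as.integer(umi_length),
                 mu_end_signature = toupper(mu_end_signature),
                 read_length = as.integer(read_length),
                 pcr_duplication = pcr_duplication,
                 read_depth = read_depth),
            class = "library_chemistry")
}

#' Full simulation configuration
#'
#' Bundles the reference genome, resident prophages and all generative
#' sub-models. A given config plus a seed fully determines the simulator
#' output.
#'
#' @param genome A [reference_genome()].
#' @param prophages List of [prophage_locus()] (labels must be unique).
#' @param consensus A [consensus_model()], or `NULL` for no preference.
#' @param immunity An [immunity_model()].
#' @param ter A [ter_model()], or `NULL` for a well-mixed genome.
#' @param self_insertion_rate Per-event probability of a self-insertion
#'   (default 0; around 1e-6 for MuB-less late-stage transposition, the
#'   order of magnitude of 85 events in 90 M reads).
#' @param stage `"EST"` (single hop) or `"LST"` (multi-hop).
#' @param chem A [library_chemistry()].
#' @param propensity Optional per-nucleotide transcription propensity; sites
#'   are down-weighted by `exp(-propensity)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome, prophages, consensus = consensus_model(),
                       immunity = immunity_model("WT_EST"),
                       ter = NULL, self_insertion_rate = 0,
                       stage = c("EST", "LST"),
                       chem = library_chemistry(), propensity = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(genome, "reference_genome"))
  if (inherits(prophages, "prophage_locus")) prophages <- list(prophages)
  labs <- vapply(prophages, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("prophage labels must be unique")
  for (p in prophages)
    if (p$right_end > genome$length)
      stop("prophage ", p$label, " extends beyond the genome")
  if (self_insertion_rate < 0 || self_insertion_rate > 1)
    stop("self_insertion_rate must lie in [0, 1]")
  if (!is.null(propensity) && length(propensity) != genome$length)
    stop("propensity must have one value per genome nucleotide")
  structure(list(genome = genome, prophages = prophages,
                 consensus = consensus, immunity = immunity, ter = ter,
                 self_insertion_rate = self_insertion_rate, stage = stage,
                 chem = chem, propensity = propensity),
            class = "sim_config")
}
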