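# Insertion-event and sequencing-library simulator. Events are drawn from a
# per-position weight vector (consensus preference x cis-immunity x Ter
# mixing x optional transcription-propensity exclusion); the library stage
# then turns events into paired reads with the y-link enrichment structure.

# circular substring: start may run past the end of the sequence
.circ_substr <- function(seq, start, len, L) {
  start <- ((start - 1L) %% L) + 1L
  end <- start + len - 1L
  if (end <= L) return(substr(seq, start, end))
  paste0(substr(seq, start, L), substr(seq, 1L, end - L))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random reference genome
#'
#' I.i.d. bases at the requested GC content; deterministic for a given seed.
#'
#' @param length Genome length (bp); at least 10 kb for pipeline use (a
#'   lower floor of 10 bp is allowed for toys).
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed Integer RNG seed.
#' @param name Sequence name.
#' @param circular Circular genome (default `TRUE`).
#' @return A [reference_genome()].
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, name = "synthetic",
                            circular = TRUE) {
  if (length < 10) stop("degenerate genome length")
  if (gc <= 0 || gc >= 1)
    stop("gc must be strictly between 0 and 1")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  reference_genome(paste(bases, collapse = ""), name = name,
                   circular = circular)
}

#' Insert a prophage sequence into a host genome
#'
#' Splices a (generated) Mu sequence into the host at `at`, lengthening the
#' reference, and terminates the insert with the Mu-end signature on both
#' sides so junction reads carry it. Returns the new genome plus the
#' prophage locus on the new axis.
#'
#' @param genome Host [reference_genome()].
#' @param at Insertion point (the prophage occupies `at .. at+mu_length-1`).
#' @param mu_length Prophage length (default 37000, the approximate Mu
#'   genome size).
#' @param chem [library_chemistry()] providing the Mu-end signature.
#' @param seed Seed for the internal Mu sequence.
#' @param mub_status,label Passed to [prophage_locus()].
#' @return List with `genome` and `prophage`.
#' @export
insert_prophage <- function(genome, at, mu_length = 37000L,
                            chem = library_chemistry(), seed = 1L,
                            mub_status = "WT", label = "Mu") {
  stopifnot(at >= 1, at <= genome$length)
  sig <- chem$mu_end_signature
  core_len <- mu_length - 2L * nchar(sig)
  if (core_len < 0) stop("mu_length shorter than twice the end signature")
  core <- generate_genome(max(core_len, 10L), gc = 0.5, seed = seed)$sequence
  core <- substr(core, 1L, core_len)
  mu_seq <- paste0(.revcomp(sig), core, sig)
  new_seq <- paste0(substr(genome$sequence, 1L, at - 1L), mu_seq,
                    substr(genome$sequence, at, genome$length))
  list(genome = reference_genome(new_seq, name = genome$name,
                                 circular = genome$circular),
       prophage = prophage_locus(at, at + mu_length - 1L,
                                 mub_status = mub_status, label = label))
}

#' Positions whose 5-mer matches a degenerate consensus
#'
#' Start positions `p` (1-based, + strand frame) where the k-mer at
#' `p..p+k-1` matches the IUPAC pattern on either strand, with circular
#' wrap. For reverse-complement-closed patterns such as `CYSRG` the two
#' strands give the same set.
#'
#' @param genome A [reference_genome()].
#' @param pattern IUPAC pattern.
#' @return Sorted integer positions.
#' @export
consensus_site_positions <- function(genome, pattern) {
  L <- genome$length
  k <- nchar(pattern)
  ext <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
  else genome$sequence
  subj <- Biostrings::DNAString(ext)
  hit <- function(pat) {
    s <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                               fixed = FALSE))
    s[s <= L]
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  sort(unique(c(hit(pattern), hit(rc))))
}

# per-position sampling weights for non-self events, split by donor Ter
# compartment; returns list(weights = list(<class> = numeric(L)),
# donor_class = character(n_prophages))
.insertion_weights <- function(config) {
  g <- config$genome
  L <- g$length
  w <- rep(1, L)
  for (p in config$prophages)
    w[p$left_end:p$right_end] <- 0
  if (!is.null(config$propensity))
    w <- w * exp(-config$propensity)
  if (!is.null(config$consensus) && config$consensus$fold != 1) {
    pos <- consensus_site_positions(g, config$consensus$pattern)
    w[pos] <- w[pos] * config$consensus$fold
  }
  imm <- config$immunity
  if (!is.null(imm) && imm$kind != "none") {
    reach <- imm$d_bulk
    for (p in config$prophages) {
      for (end in c(p$left_end, p$right_end)) {
        cand <- (end - reach):(end + reach)
        cand <- ((cand - 1L) %% L) + 1L
        d <- .end_distance(cand, p, L, g$circular)
        keep <- !is.na(d)
        w[cand[keep]] <- w[cand[keep]] * immunity_weight(imm, d[keep])
      }
    }
  }
  ter <- config$ter
  if (is.null(ter)) {
    donor_class <- rep("all", length(config$prophages))
    weights <- list(all = w)
  } else {
    in_ter <- seq_len(L) >= ter$left & seq_len(L) <= ter$right
    frac <- (ter$right - ter$left + 1) / L
    mk <- function(mass_in) {
      f <- ifelse(in_ter, mass_in / frac, (1 - mass_in) / (1 - frac))
      w * f
    }
    donor_class <- vapply(config$prophages, function(p) {
      mid <- (p$left_end + p$right_end) / 2
      if (mid >= ter$left && mid <= ter$right) "in_ter" else "out_ter"
    }, "")
    weights <- list()
    if ("in_ter" %in% donor_class) weights$in_ter <- mk(ter$retention)
    if ("out_ter" %in% donor_class) weights$out_ter <- mk(ter$exclusion)
  }
  for (wv in weights)
    if (all(wv <= 0))
      stop("all-zero insertion weight vector: no position is a valid target",
           " (genome too small for the immunity dead zone?)")
  list(weights = weights, donor_class = donor_class)
}

#' Sample Mu insertion events
#'
#' Draws `n` insertion events. Each non-self event is placed at position `p`
#' with probability proportional to base weight x consensus fold (if the
#' 5-mer at `p` on either strand matches the pattern) x immunity weight
#' (distance to the nearest end of any resident prophage) x Ter compartment
#' factor (by the event's donor) x `exp(-propensity)`. With probability
#' `self_insertion_rate` an event is instead placed uniformly inside its
#' donor prophage and flagged `is_self`.
#'
#' @param config A [sim_config()].
#' @param n Number of events.
#' @param seed Optional integer seed.
#' @param donor Optional donor label(s) to restrict to; default all donors,
#'   sampled uniformly per event.
#' @return `data.frame` with columns `position`, `strand`, `donor`,
#'   `is_self`, `target_pentamer` (the + strand 5-mer at the site).
#' @export
sample_insertions <- function(config, n, seed = NULL, donor = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- config$genome
  L <- g$length
  ws <- .insertion_weights(config)
  labs <- vapply(config$prophages, `[[`, "", "label")
  use <- if (is.null(donor)) seq_along(labs) else match(donor, labs)
  if (anyNA(use)) stop("unknown donor label")
  donor_idx <- if (length(use) == 1L) rep(use, n)
               else sample(use, n, replace = TRUE)
  is_self <- stats::rbinom(n, 1L, config$self_insertion_rate) == 1L
  position <- integer(n)
  for (cls in unique(ws$donor_class[use])) {
    sel <- !is_self & ws$donor_class[donor_idx] == cls
    if (any(sel))
      position[sel] <- sample.int(L, sum(sel), replace = TRUE,
                                  prob = ws$weights[[cls]])
  }
  if (any(is_self)) {
    for (i in which(is_self)) {
      p <- config$prophages[[donor_idx[i]]]
      position[i] <- sample(seq.int(p$left_end + 5L, p$right_end - 5L), 1L)
    }
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ext <- paste0(g$sequence, substr(g$sequence, 1L, 4L))
  pent <- substring(ext, position, position + 4L)
  data.frame(position = position, strand = strand,
             donor = labs[donor_idx], is_self = is_self,
             target_pentamer = pent, stringsAsFactors = FALSE)
}

#' Multi-hop (late-stage) insertion sampling
#'
#' Approximates multi-round transposition: after each round, a few new
#' events become donor prophages themselves (intervals on the unchanged
#' coordinate axis) and the weight landscape is recomputed, letting the
#' copy number grow toward the 5-10 copies per cell seen after 2 h of
#' MuB-less transposition.
#'
#' @param config A [sim_config()] (typically `dMuB_LST` immunity).
#' @param n Total events, split evenly over rounds.
#' @param rounds Number of rounds (default 3).
#' @param new_donors_per_round New donor copies added per round (default 2).
#' @param seed Optional integer seed.
#' @return `data.frame` as [sample_insertions()] plus a `round` column.
#' @export
sample_insertions_lst <- function(config, n, rounds = 3L,
                                  new_donors_per_round = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- ceiling(n / rounds)
  out <- vector("list", rounds)
  mu_len <- config$prophages[[1L]]$mu_length
  for (r in seq_len(rounds)) {
    ev <- sample_insertions(config, min(per, n - (r - 1L) * per))
    ev$round <- r
    out[[r]] <- ev
    if (r < rounds) {
      cand <- ev[!ev$is_self, , drop = FALSE]
      cand <- cand[cand$position + mu_len - 1L <= config$genome$length, ,
                   drop = FALSE]
      k <- min(new_donors_per_round, nrow(cand))
      if (k > 0L) {
        picks <- cand[sample.int(nrow(cand), k), , drop = FALSE]
        for (j in seq_len(k)) {
          config$prophages <- c(config$prophages, list(prophage_locus(
            picks$position[j], picks$position[j] + mu_len - 1L,
            mub_status = "dMuB", label = sprintf("hop%d.%d", r, j))))
        }
      }
    }
  }
  do.call(rbind, out)
}

# enzyme cut coordinates on a circular genome: list with plus-strand cut
# ends (last base retained by a fragment running rightward into the cut)
# and minus-strand cut ends (last top-strand coordinate retained by a
# fragment running leftward on the bottom strand)
.cut_positions <- function(genome, chem) {
  L <- genome$length
  k <- nchar(chem$enzyme_site)
  ext <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
  else genome$sequence
  s <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(chem$enzyme_site), Biostrings::DNAString(ext)))
  s <- s[s <= L]
  if (length(s) == 0L)
    stop("enzyme site ", chem$enzyme_site, " absent from the genome; ",
         "the library would be empty")
  plus_end <- ((s + chem$cut_after - 1L - 1L) %% L) + 1L
  minus_end <- ((s + k - chem$cut_after - 1L) %% L) + 1L
  list(plus = sort(plus_end), minus = sort(minus_end))
}

# host fragments, vectorized: junction base outward to the nearest cut.
# + strand: [p .. cut] rightward; - strand: revcomp([cut .. p+4]) leftward.
# Sequences are capped at `cap` bases (a sequencing read never sees more);
# `len` records the true fragment length.
.host_fragments <- function(pos, strand, genome, cuts, cap) {
  L <- genome$length
  ext <- paste0(genome$sequence, substr(genome$sequence, 1L, min(L, cap + 4L)))
  n <- length(pos)
  len <- integer(n)
  start <- integer(n)
  seq <- character(n)
  plus <- strand == "+"
  if (any(plus)) {
    j <- pos[plus]
    idx <- findInterval(j - 1L, cuts$plus) + 1L
    wrap <- idx > length(cuts$plus)
    cp <- ifelse(wrap, cuts$plus[1L] + L, cuts$plus[pmin(idx, length(cuts$plus))])
    ln <- cp - j + 1L
    len[plus] <- ln
    start[plus] <- j
    seq[plus] <- substring(ext, j, j + pmin(ln, cap) - 1L)
  }
  if (any(!plus)) {
    j <- ((pos[!plus] + 4L - 1L) %% L) + 1L
    idx <- findInterval(j, cuts$minus)
    wrap <- idx < 1L
    cp <- ifelse(wrap, cuts$minus[length(cuts$minus)] - L, cuts$minus[pmax(idx, 1L)])
    ln <- j - cp + 1L
    st <- ((cp - 1L) %% L) + 1L
    use_len <- pmin(ln, cap)
    # keep the junction-proximal end when capping: trim from the cut side
    st_eff <- ((st + (ln - use_len) - 1L) %% L) + 1L
    len[!plus] <- ln
    start[!plus] <- st
    seq[!plus] <- .revcomp(substring(ext, st_eff, st_eff + use_len - 1L))
  }
  list(seq = seq, start = start, len = len)
}

.random_umi <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

.add_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < rate)
    if (length(hit) == 0L) return(r)
    ch <- strsplit(r, "")[[1L]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Build a target-enriched sequencing library from insertion events
#'
#' Emulates the y-link enrichment protocol: for each event the host fragment
#' runs from the Mu-host junction to the nearest restriction cut on the host
#' side (cut position after the first base of `GCGC` on each strand, so a
#' site planted `d` bp downstream of a junction yields a `d + 1` bp
#' fragment). Read 1 is `mu_end_signature + host + revcomp(adapter) +
#' revcomp(UMI)`; read 2 is `UMI + adapter_signature + revcomp(host) + ...`;
#' both are cut or A-padded to `read_length`. Each fragment is emitted
#' `1 + Poisson(pcr_duplication - 1)` times with the same UMI; copies may
#' carry independent substitution errors. FASTQ headers carry a truth tag
#' `evt<i>:<pos>:<strand>:<self>` used by the test oracles.
#'
#' Fragments shorter than `min_fragment` (junction nearly on a cut) are
#' dropped and counted.
#'
#' @param events `data.frame` from [sample_insertions()].
#' @param genome The [reference_genome()] the events live on.
#' @param chem A [library_chemistry()].
#' @param fastq1,fastq2 Output FASTQ paths.
#' @param truth_tsv Optional path for the truth event table.
#' @param seed Optional integer seed (UMIs, duplication, errors).
#' @param error_rate Per-base substitution probability (default 0).
#' @param min_fragment Minimum usable host-fragment length (default 20).
#' @return Invisibly, a list: `fastq1`, `fastq2`, `truth` (data.frame with
#'   per-event fragment coordinates, UMI and copy number), `n_pairs`,
#'   `n_dropped`.
#' @export
make_library <- function(events, genome, chem = library_chemistry(),
                         fastq1, fastq2, truth_tsv = NULL, seed = NULL,
                         error_rate = 0, min_fragment = 20L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(events)
  cuts <- .cut_positions(genome, chem)
  rl <- chem$read_length
  frags <- .host_fragments(events$position, events$strand, genome, cuts,
                           cap = rl)
  frag_len <- frags$len
  keep <- frag_len >= min_fragment
  umi <- .random_umi(n, chem$umi_length)
  copies <- 1L + stats::rpois(n, chem$pcr_duplication - 1)
  pad <- strrep("A", rl)
  host <- frags$seq[keep]
  a1 <- substr(paste0(chem$mu_end_signature, host,
                      .revcomp(chem$adapter_signature),
                      .revcomp(umi[keep]), pad), 1L, rl)
  a2 <- substr(paste0(umi[keep], chem$adapter_signature, .revcomp(host),
                      .revcomp(chem$mu_end_signature), pad), 1L, rl)
  cp <- copies[keep]
  ids <- sprintf("evt%d:%d:%s:%d/c%d",
                 rep(which(keep), cp), rep(events$position[keep], cp),
                 rep(events$strand[keep], cp),
                 rep(as.integer(events$is_self[keep]), cp),
                 sequence(cp))
  r1 <- .add_errors(rep(a1, cp), error_rate)
  r2 <- .add_errors(rep(a2, cp), error_rate)
  x1 <- Biostrings::DNAStringSet(r1)
  x2 <- Biostrings::DNAStringSet(r2)
  names(x1) <- names(x2) <- if (length(ids)) ids else character(0)
  Biostrings::writeXStringSet(x1, fastq1, format = "fastq")
  Biostrings::writeXStringSet(x2, fastq2, format = "fastq")
  truth <- data.frame(event = seq_len(n), position = events$position,
                      strand = events$strand, donor = events$donor,
                      is_self = events$is_self, frag_len = frag_len,
                      umi = umi, copies = copies, dropped = !keep,
                      stringsAsFactors = FALSE)
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(fastq1 = fastq1, fastq2 = fastq2, truth = truth,
                 n_pairs = length(ids), n_dropped = sum(!keep)))
}
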