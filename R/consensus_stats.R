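# Degenerate-consensus statistics: pentamer enumeration, genomic abundance,
# and the abundance-normalized insertion fold preference. The fold is a
# ratio of per-site rates — insertions per consensus genome site over
# insertions per non-consensus site — which is the only reading under which
# "normalized to genomic abundance" makes a 7-fold preference meaningful.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Expand a degenerate IUPAC pattern
#'
#' Full Cartesian expansion in a deterministic (lexicographic by position)
#' order. `CYSRG` expands to 8 pentamers; `NNNNN` to all 1024.
#'
#' @param pattern IUPAC string.
#' @return Character vector of concrete DNA strings.
#' @export
expand_degenerate <- function(pattern) {
  if (nchar(pattern) == 0L) stop("empty pattern")
  ch <- strsplit(toupper(pattern), "")[[1L]]
  bad <- setdiff(ch, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code: ", paste(unique(bad), collapse = ", "))
  sets <- lapply(ch, function(c) strsplit(.IUPAC[[c]], "")[[1L]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste,
             collapse = ""))
}

# does each string match the IUPAC pattern (same length) on the + strand?
.iupac_match <- function(strings, pattern) {
  ch <- strsplit(toupper(pattern), "")[[1L]]
  rx <- paste0("^", paste0("[", .IUPAC[ch], "]", collapse = ""), "$")
  grepl(rx, strings)
}

#' Tabulate pentamer abundance and insertion counts
#'
#' Counts every k-mer start position on the + strand with circular wrap
#' (each of the L positions starts exactly one k-mer, so genome counts sum
#' to L), and classifies each k-mer as `consensus` (member of the pattern
#' expansion or of its reverse complement's) or `other`. Reverse-complement
#' occurrences are not added separately: for reverse-complement-closed
#' patterns such as `CYSRG` that would double-count every site.
#'
#' @param genome A [reference_genome()].
#' @param pattern Degenerate consensus pattern (default `"CYSRG"`).
#' @param insertions Optional unique-insertion `data.frame` (with
#'   `target_pentamer` or `position`); adds an `insertions` column.
#' @return `data.frame` of class `pentamer_table`: `pentamer`,
#'   `genome_sites`, `class`, and optionally `insertions`.
#' @export
pentamer_table <- function(genome, pattern = "CYSRG", insertions = NULL) {
  k <- nchar(pattern)
  if (genome$length < k) stop("genome shorter than the pattern")
  L <- genome$length
  ext <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
  else genome$sequence
  n_kmer <- if (genome$circular) L else L - k + 1L
  kmers <- substring(ext, seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
  all_k <- expand_degenerate(strrep("N", k))
  counts <- table(factor(kmers, levels = all_k))
  members <- union(expand_degenerate(pattern),
                   .revcomp(expand_degenerate(pattern)))
  tab <- data.frame(pentamer = all_k,
                    genome_sites = as.integer(counts),
                    class = ifelse(all_k %in% members, "consensus", "other"),
                    stringsAsFactors = FALSE)
  if (!is.null(insertions)) {
    pent <- insertion_pentamers(insertions, genome, k)
    it <- table(factor(pent, levels = all_k))
    tab$insertions <- as.integer(it)
  }
  class(tab) <- c("pentamer_table", "data.frame")
  attr(tab, "pattern") <- toupper(pattern)
  tab
}

#' The + strand k-mer at each insertion site
#'
#' @param insertions Unique-insertion `data.frame` (uses `target_pentamer`
#'   if present and `k = 5`, else reads the genome at `position`).
#' @param genome A [reference_genome()].
#' @param k K-mer length (default 5).
#' @return Character vector.
#' @export
insertion_pentamers <- function(insertions, genome, k = 5L) {
  if (k == 5L && !is.null(insertions$target_pentamer))
    return(insertions$target_pentamer)
  pos <- if (is.data.frame(insertions)) insertions$position else insertions
  vapply(pos, function(p)
    .circ_substr(genome$sequence, p, k, genome$length), "")
}

#' Abundance-normalized consensus fold preference
#'
#' `(consensus insertions / consensus genome sites) /
#'  (other insertions / other genome sites)`.
#' When either insertion count is zero, a pseudocount of 0.5 is added to
#' both numerators and the result is flagged (`attr(x, "pseudocount")`).
#'
#' @param insertions Unique-insertion `data.frame`.
#' @param table A [pentamer_table()] for the same genome.
#' @param genome The [reference_genome()] (needed when `insertions` lacks
#'   `target_pentamer`).
#' @return The fold (numeric scalar), with attributes `pseudocount`
#'   (logical) and `counts`.
#' @export
fold_preference <- function(insertions, table, genome = NULL) {
  stopifnot(inherits(table, "pentamer_table"))
  g_c <- sum(table$genome_sites[table$class == "consensus"])
  g_o <- sum(table$genome_sites[table$class == "other"])
  if (g_c == 0L) {
    warning("no consensus sites in the genome; fold undefined")
    return(structure(NA_real_, pseudocount = FALSE))
  }
  k <- nchar(table$pentamer[1L])
  pent <- if (!is.null(insertions$target_pentamer) && k == 5L)
    insertions$target_pentamer
  else insertion_pentamers(insertions, genome, k)
  if (length(pent) == 0L) stop("no insertions")
  cls <- table$class[match(pent, table$pentamer)]
  i_c <- sum(cls == "consensus", na.rm = TRUE)
  i_o <- sum(cls == "other", na.rm = TRUE)
  pseudo <- i_c == 0L || i_o == 0L
  if (pseudo) { i_c <- i_c + 0.5; i_o <- i_o + 0.5 }
  structure((i_c / g_c) / (i_o / g_o), pseudocount = pseudo,
            counts = c(consensus_ins = i_c, other_ins = i_o,
                       consensus_sites = g_c, other_sites = g_o))
}

#' Extended consensus scan
#'
#' Re-computes the fold for extended patterns sharing the core consensus
#' (e.g. `CYSRGNN`, `NNCYSRG`, `NCYSRGN`): a site's extended window starts
#' `core offset` bases upstream of the insertion coordinate, and class
#' membership allows either strand (the pattern or its reverse complement).
#' When target choice is driven purely by the 5-mer core, extended folds
#' stay within a few percent of the core fold; a genuine flanking
#' preference pushes them apart.
#'
#' @param insertions Unique-insertion `data.frame`.
#' @param genome A [reference_genome()].
#' @param patterns Character vector of extended IUPAC patterns.
#' @param core Core pattern (default `"CYSRG"`).
#' @return `data.frame`: `pattern`, `fold`, `ratio_to_core`, plus the core
#'   row.
#' @export
extended_consensus_scan <- function(insertions, genome,
                                    patterns = c("CYSRGNN", "NNCYSRG",
                                                 "NCYSRGN"),
                                    core = "CYSRG") {
  if (length(patterns) == 0L)
    return(data.frame(pattern = character(), fold = numeric(),
                      ratio_to_core = numeric()))
  core_tab <- pentamer_table(genome, core)
  core_fold <- as.numeric(fold_preference(insertions, core_tab, genome))
  L <- genome$length
  kc <- nchar(core)
  # everything is counted in the anchor frame: a genome position (or an
  # insertion coordinate) is in the class when the extended window around
  # its core anchor matches the pattern on either strand, so genome sites
  # and insertion sites are classified identically
  one <- function(pat) {
    off <- regexpr(core, pat, fixed = TRUE) - 1L  # 0-based core offset
    if (off < 0L)
      stop("pattern ", pat, " does not contain the core ", core)
    k <- nchar(pat)
    rc_pat <- .revcomp(pat)
    off_rc <- k - kc - off
    ext <- if (genome$circular)
      paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
    else genome$sequence
    subj <- Biostrings::DNAString(ext)
    starts <- function(pp) {
      s <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(pp), subj, fixed = FALSE))
      ((s - 1L) %% L) + 1L
    }
    anchors <- unique(c(((starts(pat) + off - 1L) %% L) + 1L,
                        ((starts(rc_pat) + off_rc - 1L) %% L) + 1L))
    sites <- length(anchors)
    g_o <- L - sites
    win <- function(p, o) vapply(p, function(q)
      .circ_substr(genome$sequence, ((q - o - 1L) %% L) + 1L, k, L), "")
    inc <- .iupac_match(win(insertions$position, off), pat) |
      .iupac_match(win(insertions$position, off_rc), rc_pat)
    i_c <- sum(inc); i_o <- sum(!inc)
    if (i_c == 0L || i_o == 0L) { i_c <- i_c + 0.5; i_o <- i_o + 0.5 }
    (i_c / sites) / (i_o / g_o)
  }
  folds <- vapply(patterns, one, 0)
  out <- data.frame(pattern = c(core, patterns),
                    fold = c(core_fold, folds),
                    ratio_to_core = c(1, folds / core_fold),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
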