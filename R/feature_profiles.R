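# Insertion profiles relative to annotated features: gene-start (+1 nt)
# profiles with exclusion-zone calling, tRNA mature-region avoidance, and
# coding-fraction summaries for operon windows.
#
# Offset convention: the first nucleotide of the feature is offset +1 and
# there is no offset 0 (the base immediately upstream is -1), matching the
# way gene-relative insertion maps are drawn. Minus-strand features are
# flipped so downstream is always positive.

# signed, zero-free offset of positions relative to an anchor/strand
.feature_offset <- function(pos, anchor, strand) {
  off <- if (strand == "+") pos - anchor else anchor - pos
  ifelse(off >= 0L, off + 1L, off)
}

#' Gene-relative insertion profile
#'
#' Per-offset insertion counts in a window around a feature's +1 nt (the
#' first base of the CDS). The nominal transcription start site sits at a
#' fixed display offset (default -125).
#'
#' @param insertions Unique-insertion `data.frame` or position vector.
#' @param feature One-row `data.frame` (or list) with `name`, `start`,
#'   `end`, `strand`.
#' @param window `c(lower, upper)` offsets, default `c(-500, 500)`.
#' @param L Genome length (features must fit on the genome).
#' @param tss_offset Display offset of the expected TSS (default -125).
#' @return Object of class `gene_profile`: `gene`, `offsets` (zero-free),
#'   `counts`, `tss_offset`.
#' @export
gene_relative_profile <- function(insertions, feature, window = c(-500, 500),
                                  L = NULL, tss_offset = -125L) {
  if (!is.null(L) && (feature$start < 1 || feature$end > L))
    stop("feature lies outside the genome")
  pos <- if (is.data.frame(insertions)) {
    keep <- if (is.null(insertions$is_self)) TRUE else !insertions$is_self
    insertions$position[keep]
  } else insertions
  anchor <- if (feature$strand == "+") feature$start else feature$end
  off <- .feature_offset(pos, anchor, feature$strand)
  offsets <- setdiff(seq.int(window[1L], window[2L]), 0L)
  counts <- tabulate(match(off, offsets), nbins = length(offsets))
  structure(list(gene = feature$name, offsets = offsets, counts = counts,
                 tss_offset = as.integer(tss_offset)),
            class = "gene_profile")
}

#' Exclusion zone around the +1 nt
#'
#' The maximal run of strictly zero-count offsets containing the +1
#' position. `upstream_extent` counts zero offsets below +1 in the run,
#' `downstream_extent` counts those at and above +1. A nonzero count at +1
#' gives extents 0 and `spans_plus_one = FALSE`.
#'
#' @param profile A [gene_relative_profile()].
#' @return List of class `exclusion_zone`: `upstream_extent`,
#'   `downstream_extent`, `spans_plus_one`.
#' @export
exclusion_zone <- function(profile) {
  i1 <- match(1L, profile$offsets)
  if (is.na(i1)) stop("profile window does not cover offset +1")
  if (profile$counts[i1] != 0L)
    return(structure(list(upstream_extent = 0L, downstream_extent = 0L,
                          spans_plus_one = FALSE),
                     class = "exclusion_zone"))
  lo <- i1
  while (lo > 1L && profile$counts[lo - 1L] == 0L) lo <- lo - 1L
  hi <- i1
  while (hi < length(profile$counts) && profile$counts[hi + 1L] == 0L)
    hi <- hi + 1L
  structure(list(upstream_extent = i1 - lo,
                 downstream_extent = hi - i1 + 1L,
                 spans_plus_one = TRUE),
            class = "exclusion_zone")
}

#' tRNA-relative insertion matrix with mature-region avoidance flags
#'
#' One row per tRNA over offsets (default -200..+150, zero-free; +1 is the
#' first base of the mature tRNA, `e` at +75 its typical end). A row is
#' flagged as avoiding the mature region when `[+1, +75]` holds zero
#' insertions while the leader `[-200, -1]` holds at least one.
#'
#' @param insertions Unique-insertion `data.frame` or position vector.
#' @param trna_features `data.frame` with `name`, `start`, `end`, `strand`.
#' @param window `c(lower, upper)` offsets, default `c(-200, 150)`.
#' @param mature Mature-region offsets, default `c(1, 75)`.
#' @return List of class `trna_profile`: `matrix` (tRNAs x offsets),
#'   `offsets`, `flagged` (named logical).
#' @export
trna_profile <- function(insertions, trna_features, window = c(-200, 150),
                         mature = c(1, 75)) {
  offsets <- setdiff(seq.int(window[1L], window[2L]), 0L)
  if (nrow(trna_features) == 0L)
    return(structure(list(matrix = matrix(0L, 0L, length(offsets)),
                          offsets = offsets, flagged = logical(0)),
                     class = "trna_profile"))
  m <- t(vapply(seq_len(nrow(trna_features)), function(i) {
    f <- trna_features[i, ]
    gene_relative_profile(insertions, f, window = window)$counts
  }, integer(length(offsets))))
  rownames(m) <- trna_features$name
  mat_idx <- offsets >= mature[1L] & offsets <= mature[2L]
  lead_idx <- offsets < 0L
  flagged <- rowSums(m[, mat_idx, drop = FALSE]) == 0L &
    rowSums(m[, lead_idx, drop = FALSE]) > 0L
  structure(list(matrix = m, offsets = offsets, flagged = flagged),
            class = "trna_profile")
}

#' Coding fraction of insertions in a window
#'
#' Observed percentage of the window's insertions that fall inside coding
#' sub-features, next to the uniform expectation (the CDS share of the
#' window in bp).
#'
#' @param insertions Unique-insertion `data.frame` or position vector.
#' @param window `c(start, end)` genomic interval (bp).
#' @param cds_features `data.frame` with `start`, `end` of coding segments
#'   (clipped to the window; assumed non-overlapping).
#' @return List of class `coding_fraction`: `observed_pct`, `expected_pct`,
#'   `n_insertions`, `defined`.
#' @export
coding_fraction <- function(insertions, window, cds_features) {
  pos <- if (is.data.frame(insertions)) {
    keep <- if (is.null(insertions$is_self)) TRUE else !insertions$is_self
    insertions$position[keep]
  } else insertions
  pos <- pos[pos >= window[1L] & pos <= window[2L]]
  s <- pmax(cds_features$start, window[1L])
  e <- pmin(cds_features$end, window[2L])
  ok <- s <= e
  s <- s[ok]; e <- e[ok]
  cds_bp <- sum(e - s + 1L)
  win_bp <- window[2L] - window[1L] + 1L
  expected <- 100 * cds_bp / win_bp
  if (length(pos) == 0L)
    return(structure(list(observed_pct = NA_real_,
                          expected_pct = expected, n_insertions = 0L,
                          defined = FALSE),
                     class = "coding_fraction"))
  in_cds <- vapply(pos, function(p) any(p >= s & p <= e), TRUE)
  structure(list(observed_pct = 100 * mean(in_cds),
                 expected_pct = expected,
                 n_insertions = length(pos), defined = TRUE),
            class = "coding_fraction")
}
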