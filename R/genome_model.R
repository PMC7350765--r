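# Coordinate convention: every position in user-facing tables is 1-based
# inclusive; internal arithmetic that needs half-open intervals converts
# locally. Genomes are circular unless constructed otherwise.

#' Reference genome
#'
#' A light container for a single circular (or linear) DNA sequence that
#' serves as the coordinate frame for every downstream stage: insertion
#' events, bin matrices, distance profiles and consensus statistics all live
#' on its 1-based axis.
#'
#' @param sequence Character scalar over A/C/G/T (upper-cased on input).
#' @param name Sequence name.
#' @param circular Logical; circular chromosome arithmetic (default `TRUE`).
#' @return An object of class `reference_genome` with fields `sequence`,
#'   `length`, `circular`, `name`.
#' @examples
#' g <- reference_genome("ACGTACGT", name = "toy")
#' g$length
#' @export
reference_genome <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("empty genome sequence")
  if (grepl("[^ACGT]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T}")
  structure(
    list(sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular), name = as.character(name)),
    class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Prophage locus on the reference
#'
#' Describes one resident Mu prophage: the interval it occupies on the genome
#' axis (the prophage is part of the reference sequence, so self-insertions
#' share the same coordinates), its MuB genotype and a cohort-unique label.
#'
#' @param left_end,right_end 1-based inclusive ends of the prophage interval.
#' @param mub_status `"WT"` or `"dMuB"`.
#' @param label Unique label (e.g. `"OPL"`, `"Ter"`).
#' @param L Genome length, used to validate the interval (optional).
#' @return An object of class `prophage_locus`.
#' @export
prophage_locus <- function(left_end, right_end, mub_status = c("WT", "dMuB"),
                           label = "Mu", L = NULL) {
  mub_status <- match.arg(mub_status)
  stopifnot(left_end >= 1, right_end > left_end)
  if (!is.null(L) && right_end > L)
    stop("prophage interval extends beyond the genome")
  structure(
    list(left_end = as.integer(left_end), right_end = as.integer(right_end),
         mu_length = as.integer(right_end - left_end + 1L),
         mub_status = mub_status, label = as.character(label)),
    class = "prophage_locus")
}

#' Circular distance between two genome positions
#'
#' @param a,b 1-based positions.
#' @param L Genome length in bp.
#' @return The shorter arc `min(|a - b|, L - |a - b|)`; never exceeds `L / 2`.
#' @examples
#' circular_distance(10, 990, 1000)  # 20, wrapping through the origin
#' @export
circular_distance <- function(a, b, L) {
  if (any(a < 1 | a > L) || any(b < 1 | b > L))
    stop("position outside [1, L]")
  d <- abs(a - b)
  pmin(d, L - d)
}

#' Load a reference genome from FASTA
#'
#' Reads a single-record FASTA into a [reference_genome()]. Multi-record
#' files are rejected unless `allow_multi = TRUE`, in which case the first
#' record is used. Ambiguity codes are rejected unless `mask = TRUE`, which
#' replaces them with `A` (positions are preserved).
#'
#' @param path FASTA file.
#' @param circular Treat the sequence as circular.
#' @param allow_multi Accept multi-record files (first record wins).
#' @param mask Replace non-ACGT characters by `A` instead of failing.
#' @return A [reference_genome()].
#' @export
load_fasta <- function(path, circular = TRUE, allow_multi = FALSE,
                       mask = FALSE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path)
  if (length(set) > 1L && !allow_multi)
    stop("multi-record FASTA; pass allow_multi = TRUE to use the first record")
  seq <- toupper(as.character(set[[1L]]))
  if (grepl("[^ACGT]", seq)) {
    if (!mask)
      stop("FASTA record contains non-ACGT characters; pass mask = TRUE")
    seq <- gsub("[^ACGT]", "A", seq)
  }
  reference_genome(seq, name = names(set)[1L], circular = circular)
}

#' Write a reference genome to FASTA
#'
#' Round-trips bit-exactly through [load_fasta()].
#'
#' @param genome A [reference_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Annotation track
#'
#' Genomic features (genes, tRNAs, rRNA operons, named regions) plus an
#' optional per-nucleotide transcription-propensity vector, on the same axis
#' as the reference genome.
#'
#' @param features `data.frame` with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `kind` (one of `gene`, `tRNA`, `rRNA_operon`,
#'   `region`).
#' @param propensity Optional numeric vector of length `L` (non-negative).
#' @param L Genome length for validation (optional).
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(features, propensity = NULL, L = NULL) {
  need <- c("name", "start", "end", "strand", "kind")
  if (!all(need %in% names(features)))
    stop("features must have columns ", paste(need, collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(features$kind %in% c("gene", "tRNA", "rRNA_operon", "region")))
    stop("unknown feature kind")
  if (!is.null(L)) {
    if (any(features$start < 1 | features$end > L))
      stop("feature outside [1, L]")
    if (!is.null(propensity) && length(propensity) != L)
      stop("propensity must have one value per nucleotide")
  }
  if (!is.null(propensity) && any(propensity < 0))
    stop("propensity must be non-negative")
  structure(list(features = as.data.frame(features), propensity = propensity),
            class = "annotation_track")
}

#' Read features from BED
#'
#' Minimal BED dialect: chrom, start (0-based), end, name, score, strand.
#' Coordinates are converted to the package's 1-based inclusive convention.
#' The feature `kind` is taken from `kind`, recycled.
#'
#' @param path BED file.
#' @param kind Feature kind to assign (recycled).
#' @return `data.frame` suitable for [annotation_track()].
#' @export
read_bed_features <- function(path, kind = "gene") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L)
    stop("BED file needs 6 columns (chrom, start, end, name, score, strand)")
  data.frame(name = as.character(bed[[4L]]),
             start = as.integer(bed[[2L]]) + 1L,
             end = as.integer(bed[[3L]]),
             strand = as.character(bed[[6L]]),
             kind = rep_len(kind, nrow(bed)),
             stringsAsFactors = FALSE)
}

#' Read a per-nucleotide propensity track from TSV
#'
#' Two columns, `position<TAB>value`; missing positions get 0.
#'
#' @param path TSV file.
#' @param L Genome length.
#' @return Numeric vector of length `L`.
#' @export
read_propensity_tsv <- function(path, L) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)
  v <- numeric(L)
  pos <- as.integer(tab[[1L]])
  if (any(pos < 1 | pos > L)) stop("propensity position outside [1, L]")
  v[pos] <- as.numeric(tab[[2L]])
  v
}

# distance from each position in `pos` to the nearest prophage end, measured
# outward; positions inside the prophage get NA_real_
.end_distance <- function(pos, prophage, L, circular = TRUE) {
  dl <- if (circular) circular_distance(pos, prophage$left_end, L)
        else abs(pos - prophage$left_end)
  dr <- if (circular) circular_distance(pos, prophage$right_end, L)
        else abs(pos - prophage$right_end)
  d <- pmin(dl, dr)
  inside <- pos >= prophage$left_end & pos <= prophage$right_end
  d[inside] <- NA_real_
  d
}
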