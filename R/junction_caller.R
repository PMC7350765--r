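# Junction calling: paired target-enriched reads (or pre-aligned SAM) to a
# deduplicated table of nucleotide-precision unique insertions. The built-in
# mapper is an exact seed-and-verify k-mer mapper (k = 20); mismatch-tolerant
# alignment belongs to external aligners whose output enters via SAM.

# mismatch count of `sig` against each read at a fixed 0-based offset
.mm_at_offset <- function(reads, sig, offset) {
  k <- nchar(sig)
  mm <- integer(length(reads))
  for (j in seq_len(k))
    mm <- mm + (substr(reads, offset + j, offset + j) !=
                  substr(sig, j, j))
  mm
}

#' Locate a signature within a read
#'
#' Smallest 0-based offset at which `signature` occurs with at most
#' `max_mismatch` mismatches, or `NA` if absent (including when the
#' signature is longer than the read).
#'
#' @param read,signature DNA strings.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return Integer offset (0-based) or `NA`.
#' @export
find_signature <- function(read, signature, max_mismatch = 0L) {
  if (nchar(signature) == 0L) stop("empty signature")
  if (nchar(signature) > nchar(read)) return(NA_integer_)
  m <- Biostrings::matchPattern(Biostrings::DNAString(signature),
                                Biostrings::DNAString(read),
                                max.mismatch = max_mismatch)
  if (length(m) == 0L) return(NA_integer_)
  Biostrings::start(m)[1L] - 1L
}

#' Extract host fragments and UMIs from read pairs
#'
#' Read 1 must begin with the Mu-end signature (up to `max_mismatch`
#' mismatches); the remainder is the host fragment, trimmed at the first
#' occurrence of the reverse-complemented adapter signature when the
#' fragment is shorter than the read. Read 2 yields the UMI (first
#' `umi_length` bases, no Ns allowed) and must carry the adapter signature
#' immediately after it. Rejection reasons: `too_short`, `no_mu_end`,
#' `no_adapter`.
#'
#' @param reads1,reads2 Character vectors of read sequences (paired).
#' @param chem A [library_chemistry()].
#' @param max_mismatch Mismatches tolerated in the Mu-end and adapter
#'   signature checks (default 0).
#' @param min_map_len Minimum host-fragment length (default 20).
#' @return `data.frame` with columns `host`, `umi`, `reject` (`NA` when
#'   accepted).
#' @export
extract_junctions <- function(reads1, reads2, chem, max_mismatch = 0L,
                              min_map_len = 20L) {
  stopifnot(length(reads1) == length(reads2))
  n <- length(reads1)
  mu <- chem$mu_end_signature
  ad <- chem$adapter_signature
  ul <- chem$umi_length
  reject <- rep(NA_character_, n)
  reject[nchar(reads2) < ul + nchar(ad) |
           nchar(reads1) < nchar(mu) + min_map_len] <- "too_short"
  ok <- is.na(reject)
  mu_mm <- .mm_at_offset(reads1, mu, 0L)
  reject[ok & mu_mm > max_mismatch] <- "no_mu_end"
  ok <- is.na(reject)
  umi <- toupper(substr(reads2, 1L, ul))
  ad_mm <- .mm_at_offset(reads2, ad, ul)
  reject[ok & (ad_mm > max_mismatch | grepl("[^ACGT]", umi))] <- "no_adapter"
  ok <- is.na(reject)
  rest <- substr(reads1, nchar(mu) + 1L, nchar(reads1))
  rcad <- .revcomp(ad)
  trim_at <- regexpr(rcad, rest, fixed = TRUE)
  host <- ifelse(trim_at > 0L, substr(rest, 1L, trim_at - 1L), rest)
  # a fragment that nearly fills read 1 leaves only a partial adapter at the
  # read end; trim the longest read suffix matching an adapter prefix
  # (junctions sit at the fragment start, so a spurious short trim is safe)
  notrim <- trim_at <= 0L
  if (any(notrim)) {
    hl <- nchar(host)
    done <- !notrim
    for (k in seq.int(nchar(ad) - 1L, 1L)) {
      hit <- !done & hl > k &
        substr(host, hl - k + 1L, hl) == substr(rcad, 1L, k)
      host[hit] <- substr(host[hit], 1L, hl[hit] - k)
      done <- done | hit
    }
  }
  reject[ok & nchar(host) < min_map_len] <- "too_short"
  host[!is.na(reject)] <- NA_character_
  umi[!is.na(reject)] <- NA_character_
  data.frame(host = host, umi = umi, reject = reject,
             stringsAsFactors = FALSE)
}

#' Build the exact-match mapping index
#'
#' @param genome A [reference_genome()].
#' @param k Seed length (default 20); fragments shorter than `k` are
#'   unmappable.
#' @param max_query Longest query the index must verify (controls how much
#'   of the circular wrap is appended).
#' @return An index object for [map_fragments()].
#' @export
genome_index <- function(genome, k = 20L, max_query = 500L) {
  wrap <- if (genome$circular) min(genome$length, max_query + k) else 0L
  ext <- paste0(genome$sequence, substr(genome$sequence, 1L, wrap))
  structure(list(ext = ext, subject = Biostrings::DNAString(ext),
                 L = genome$length, k = as.integer(k),
                 circular = genome$circular),
            class = "genome_index")
}

#' Map host fragments by exact seed-and-verify
#'
#' Each fragment's first `k` bases are matched against the genome (both
#' strands); every seed hit is verified by full-length exact comparison.
#' Exactly one verified hit gives `mapq_class = "unique"` and the insertion
#' coordinate (first base of the 5-bp target site, + strand frame: the
#' junction-proximal base for + fragments, junction base minus 4 for
#' reverse fragments); several give `"ambiguous"`, none `"unmapped"`.
#'
#' @param frags Character vector of host fragments.
#' @param index A [genome_index()] (or a [reference_genome()], indexed on
#'   the fly).
#' @param min_map_len Fragments shorter than this are `unmapped` with a
#'   length flag (default 20).
#' @return `data.frame`: `position`, `strand`, `mapq_class`, `match_start`
#'   (leftmost + strand coordinate of the verified match), `frag_len`.
#' @export
map_fragments <- function(frags, index, min_map_len = 20L) {
  if (inherits(index, "reference_genome"))
    index <- genome_index(index, max_query = max(c(nchar(frags), 100L)))
  n <- length(frags)
  L <- index$L
  k <- index$k
  len <- nchar(frags)
  out <- data.frame(position = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    mapq_class = rep("unmapped", n),
                    match_start = rep(NA_integer_, n),
                    frag_len = len, stringsAsFactors = FALSE)
  cand <- which(len >= max(min_map_len, k) & !grepl("[^ACGT]", frags) &
                  len <= L)
  if (length(cand) == 0L) return(out)
  hits_for <- function(queries) {
    seeds <- substr(queries, 1L, k)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    m <- Biostrings::matchPDict(pd, index$subject)
    starts <- Biostrings::startIndex(m)
    qlen <- nchar(queries)
    qi <- rep(seq_along(queries), lengths(starts))
    s <- unlist(starts, use.names = FALSE)
    if (length(s) == 0L)
      return(data.frame(qi = integer(), s = integer()))
    e <- s + qlen[qi] - 1L
    keep <- e <= nchar(index$ext)
    qi <- qi[keep]; s <- s[keep]; e <- e[keep]
    okv <- substring(index$ext, s, e) == queries[qi]
    qi <- qi[okv]; s <- s[okv]
    canon <- ((s - 1L) %% L) + 1L
    unique(data.frame(qi = qi, s = canon))
  }
  fwd <- hits_for(frags[cand])
  rev <- hits_for(.revcomp(frags[cand]))
  tally <- function(h) {
    t <- integer(length(cand))
    if (nrow(h)) {
      tt <- table(h$qi)
      t[as.integer(names(tt))] <- as.integer(tt)
    }
    t
  }
  nf <- tally(fwd); nr <- tally(rev)
  total <- nf + nr
  amb <- total > 1L
  out$mapq_class[cand[amb]] <- "ambiguous"
  uniq_f <- which(total == 1L & nf == 1L)
  if (length(uniq_f)) {
    s <- fwd$s[match(uniq_f, fwd$qi)]
    i <- cand[uniq_f]
    out$position[i] <- s
    out$strand[i] <- "+"
    out$match_start[i] <- s
    out$mapq_class[i] <- "unique"
  }
  uniq_r <- which(total == 1L & nr == 1L)
  if (length(uniq_r)) {
    s <- rev$s[match(uniq_r, rev$qi)]
    i <- cand[uniq_r]
    j <- ((s + len[i] - 1L - 1L) %% L) + 1L       # junction base
    out$position[i] <- ((j - 4L - 1L) %% L) + 1L  # site first base
    out$strand[i] <- "-"
    out$match_start[i] <- s
    out$mapq_class[i] <- "unique"
  }
  out
}

#' Map a single fragment
#'
#' Convenience scalar wrapper around [map_fragments()].
#'
#' @inheritParams map_fragments
#' @param frag One host fragment.
#' @return One-row `data.frame` (see [map_fragments()]).
#' @export
map_fragment <- function(frag, index, min_map_len = 20L) {
  map_fragments(frag, index, min_map_len = min_map_len)
}

#' Collapse PCR duplicates into unique insertions
#'
#' Reads that agree on `(position, strand, umi)` are PCR duplicates of one
#' ligation event and count once toward `umi_count`; `read_count` preserves
#' raw support. One output row per `(position, strand)`, sorted. The 6-nt
#' UMI alone is not a dedup key — it collides genome-wide — which is why the
#' key is anchored at the mapped position.
#'
#' @param junctions `data.frame` with `position`, `strand`, `umi` (only
#'   uniquely mapped junctions).
#' @return `data.frame`: `position`, `strand`, `read_count`, `umi_count`,
#'   `is_self`, `donor`. Idempotent: a deduplicated table passes through
#'   unchanged (each row has its `read_count` as raw support).
#' @export
dedup <- function(junctions) {
  if (nrow(junctions) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      read_count = integer(), umi_count = integer(),
                      is_self = logical(), donor = character(),
                      stringsAsFactors = FALSE))
  dt <- data.table::as.data.table(junctions)
  if (is.null(dt$read_count)) dt$read_count <- 1L
  agg <- dt[, list(read_count = sum(read_count),
                   umi_count = data.table::uniqueN(toupper(umi))),
            by = c("position", "strand")]
  data.table::setorder(agg, position, strand)
  out <- as.data.frame(agg)
  out$is_self <- FALSE
  out$donor <- NA_character_
  out
}

#' Flag self-insertions
#'
#' An insertion is a self-insertion (SI) when its position lies strictly
#' inside a resident prophage interval and is *novel* — not one of the two
#' natural end junctions of the starting prophage (each whitelisted with a
#' +/- 4 bp target-duplication window). The containing prophage becomes the
#' attributed donor.
#'
#' @param insertions `data.frame` with a `position` column.
#' @param prophages List of [prophage_locus()] (must not overlap).
#' @param end_window Half-width of the natural-junction whitelist
#'   (default 4).
#' @return `insertions` with `is_self` and `donor` filled in.
#' @export
classify_self <- function(insertions, prophages, end_window = 4L) {
  if (inherits(prophages, "prophage_locus")) prophages <- list(prophages)
  if (length(prophages) > 1L) {
    iv <- t(vapply(prophages, function(p) c(p$left_end, p$right_end),
                   numeric(2)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      stop("overlapping prophage intervals")
  }
  insertions$is_self <- rep(FALSE, nrow(insertions))
  if (is.null(insertions$donor))
    insertions$donor <- rep(NA_character_, nrow(insertions))
  for (p in prophages) {
    inside <- insertions$position > p$left_end &
      insertions$position < p$right_end
    natural <- abs(insertions$position - p$left_end) <= end_window |
      abs(insertions$position - p$right_end) <= end_window
    hit <- inside & !natural
    insertions$is_self[hit] <- TRUE
    insertions$donor[hit] <- p$label
  }
  insertions
}

.empty_insertions <- function() {
  data.frame(position = integer(), strand = character(),
             read_count = integer(), umi_count = integer(),
             is_self = logical(), donor = character(),
             stringsAsFactors = FALSE)
}

.read_fastq_seqs <- function(path) {
  if (file.size(path) == 0) return(character(0))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

# parse junctions from a SAM of aligned host fragments (UMI in the RX tag);
# forward records give the insertion at POS, reverse records at the match's
# rightmost base minus 4
.read_sam_junctions <- function(sam) {
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "qwidth", "mapq"), tag = "RX")
  r <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(r$flag)
  umi <- r$tag$RX
  if (is.null(umi)) umi <- rep(NA_character_, n)
  unmapped <- bitwAnd(r$flag, 4L) > 0L
  reverse <- bitwAnd(r$flag, 16L) > 0L
  position <- ifelse(reverse, r$pos + r$qwidth - 1L - 4L, r$pos)
  mapq_class <- ifelse(unmapped, "unmapped",
                       ifelse(!is.na(r$mapq) & r$mapq == 0L,
                              "ambiguous", "unique"))
  data.frame(read_id = r$qname, position = position,
             strand = ifelse(reverse, "-", "+"),
             umi = umi, mapq_class = mapq_class,
             stringsAsFactors = FALSE)
}

#' Write mapped junctions as SAM
#'
#' Minimal SAM of the mapped host fragments (one record per read; UMI in
#' the `RX` tag) so a called run can be re-entered through the SAM path or
#' inspected in standard tools.
#'
#' @param mapped `data.frame` from [map_fragments()] with added `umi` and
#'   `read_id` columns and the fragment sequences in `host`.
#' @param genome The [reference_genome()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_junction_sam <- function(mapped, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length)),
             con)
  for (i in seq_len(nrow(mapped))) {
    if (mapped$mapq_class[i] != "unique") next
    rev <- mapped$strand[i] == "-"
    seq <- if (rev) .revcomp(mapped$host[i]) else mapped$host[i]
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tRX:Z:%s",
                       mapped$read_id[i], if (rev) 16L else 0L, genome$name,
                       mapped$match_start[i], 60L, nchar(seq), seq,
                       mapped$umi[i]), con)
  }
  invisible(path)
}

#' Call unique Mu insertions from reads
#'
#' The full junction-calling pipeline: FASTQ extraction (Mu-end and adapter
#' signature checks, UMI capture), exact seed-and-verify mapping, UMI
#' deduplication and self-insertion classification — or, in SAM mode, the
#' same downstream stages applied to pre-aligned host fragments. The run
#' report accounts for every input read exactly:
#' `reads_in = rejected + unmapped + ambiguous + counted`.
#'
#' @param fastq1,fastq2 Paired FASTQ paths (FASTQ mode).
#' @param sam SAM path of aligned host fragments (SAM mode).
#' @param genome A [reference_genome()] (FASTQ mode).
#' @param chem A [library_chemistry()].
#' @param prophages List of [prophage_locus()] for SI classification.
#' @param max_mismatch Signature mismatch tolerance (default 0).
#' @param min_map_len Minimum host fragment length (default 20).
#' @return List of class `mu_call`: `insertions` (the unique-insertion
#'   table), `junctions` (per-read), `report` (read accounting).
#' @export
call_insertions <- function(fastq1 = NULL, fastq2 = NULL, sam = NULL,
                            genome = NULL, chem = library_chemistry(),
                            prophages = list(), max_mismatch = 0L,
                            min_map_len = 20L) {
  if (!is.null(sam)) {
    jx <- .read_sam_junctions(sam)
    report <- list(mode = "sam", reads_in = nrow(jx),
                   rejected = c(no_mu_end = 0L, no_adapter = 0L,
                                too_short = 0L),
                   unmapped = sum(jx$mapq_class == "unmapped"),
                   ambiguous = sum(jx$mapq_class == "ambiguous"))
    jx <- jx[jx$mapq_class == "unique", , drop = FALSE]
  } else {
    if (is.null(fastq1) || is.null(fastq2) || is.null(genome))
      stop("FASTQ mode needs fastq1, fastq2 and a genome")
    r1 <- .read_fastq_seqs(fastq1)
    r2 <- .read_fastq_seqs(fastq2)
    if (length(r1) != length(r2))
      stop("read files differ in record count")
    ext <- extract_junctions(r1, r2, chem, max_mismatch = max_mismatch,
                             min_map_len = min_map_len)
    rej <- c(no_mu_end = sum(ext$reject == "no_mu_end", na.rm = TRUE),
             no_adapter = sum(ext$reject == "no_adapter", na.rm = TRUE),
             too_short = sum(ext$reject == "too_short", na.rm = TRUE))
    ok <- which(is.na(ext$reject))
    mapped <- if (length(ok)) {
      idx <- genome_index(genome, k = min_map_len,
                          max_query = max(nchar(ext$host[ok]), 100L))
      map_fragments(ext$host[ok], idx, min_map_len = min_map_len)
    } else {
      map_fragments(character(0), genome)
    }
    report <- list(mode = "fastq", reads_in = length(r1), rejected = rej,
                   unmapped = sum(mapped$mapq_class == "unmapped"),
                   ambiguous = sum(mapped$mapq_class == "ambiguous"))
    keep <- mapped$mapq_class == "unique"
    jx <- data.frame(read_id = names(r1)[ok][keep],
                     position = mapped$position[keep],
                     strand = mapped$strand[keep],
                     umi = ext$umi[ok][keep],
                     mapq_class = rep("unique", sum(keep)),
                     host = ext$host[ok][keep],
                     match_start = mapped$match_start[keep],
                     stringsAsFactors = FALSE)
  }
  report$counted <- nrow(jx)
  ins <- dedup(jx)
  ins <- classify_self(ins, prophages)
  report$unique_insertions <- nrow(ins)
  report$self_insertions <- sum(ins$is_self)
  structure(list(insertions = ins, junctions = jx, report = report),
            class = "mu_call")
}

#' @export
print.mu_call <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<mu_call> %s mode: %d reads in; rejected %d ",
                     "(mu_end %d, adapter %d, short %d); unmapped %d; ",
                     "ambiguous %d; counted %d -> %d unique insertions ",
                     "(%d self)\n"),
              r$mode, r$reads_in, sum(r$rejected), r$rejected["no_mu_end"],
              r$rejected["no_adapter"], r$rejected["too_short"], r$unmapped,
              r$ambiguous, r$counted, r$unique_insertions,
              r$self_insertions))
  invisible(x)
}

#' Write an insertion table as TSV and BED
#'
#' @param insertions Unique-insertion `data.frame`.
#' @param tsv Output TSV path (1-based positions).
#' @param bed Optional BED path (0-based half-open, for browsers).
#' @return `tsv`, invisibly.
#' @export
write_insertions <- function(insertions, tsv, bed = NULL) {
  utils::write.table(insertions, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = "genome",
                         start = insertions$position - 1L,
                         end = insertions$position + 4L,
                         name = ifelse(insertions$is_self, "SI", "ins"),
                         score = insertions$umi_count,
                         strand = insertions$strand)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv)
}
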