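# Genome-bin insertion matrices: the per-prophage 200-bin representation of
# genome-wide insertion patterns.

#' Bin width for an n-bin partition
#'
#' `ceiling(L / n_bins)`; the last bin may be short. On the 4,641,652 bp
#' chromosome at 200 bins this is 23,209 bp (~23.2 kb).
#'
#' @param L Genome length (bp).
#' @param n_bins Number of bins (default 200).
#' @return Bin width in bp.
#' @export
bin_width <- function(L, n_bins = 200L) {
  if (n_bins < 1L || n_bins > L) stop("n_bins must lie in [1, L]")
  as.integer(ceiling(L / n_bins))
}

#' Count insertions per genome bin
#'
#' Position `p` falls in 0-based bin `floor((p - 1) / bin_width)`; totals
#' are conserved exactly.
#'
#' @param positions Integer insertion positions (1-based).
#' @param L Genome length.
#' @param n_bins Number of bins (default 200).
#' @return Integer vector of length `n_bins`.
#' @export
bin_insertions <- function(positions, L, n_bins = 200L) {
  if (length(positions) && any(positions < 1 | positions > L))
    stop("insertion position outside [1, L]")
  bw <- bin_width(L, n_bins)
  idx <- (positions - 1L) %/% bw
  tabulate(idx + 1L, nbins = n_bins)
}

#' Normalize a bin-count matrix
#'
#' Two documented modes. `"depth"` divides each row by its read depth and
#' rescales the whole cohort so the maximum over non-starting bins maps to
#' `ceiling_value` (just under 1). `"max"` rescales each row by its own
#' maximum over non-starting bins. Starting bins are kept but excluded from
#' the maxima (they dominate counts) and values are capped at 1.
#'
#' @param raw Integer matrix, prophages x bins.
#' @param read_depth Per-row read depths (recycled).
#' @param mode `"depth"` or `"max"`.
#' @param start_bins Integer vector: 1-based starting-bin index per row
#'   (`NA` for none).
#' @param ceiling_value Value the cohort maximum maps to (default 0.995).
#' @return Numeric matrix in `[0, 1]`, same shape; all-zero rows stay zero
#'   with a warning.
#' @export
normalize_bins <- function(raw, read_depth, mode = c("depth", "max"),
                           start_bins = rep(NA_integer_, nrow(raw)),
                           ceiling_value = 0.995) {
  mode <- match.arg(mode)
  if (any(read_depth <= 0)) stop("read_depth must be positive")
  raw <- as.matrix(raw)
  read_depth <- rep_len(read_depth, nrow(raw))
  if (any(rowSums(raw) == 0))
    warning("all-zero insertion row(s); normalized row stays zero")
  rate <- raw / read_depth
  mask <- rate
  for (i in seq_len(nrow(raw)))
    if (!is.na(start_bins[i])) mask[i, start_bins[i]] <- NA
  if (mode == "depth") {
    m <- max(mask, na.rm = TRUE)
    norm <- if (m > 0) rate / m * ceiling_value else rate
  } else {
    rowmax <- apply(mask, 1L, max, na.rm = TRUE)
    rowmax[!is.finite(rowmax) | rowmax == 0] <- 1
    norm <- rate / rowmax * ceiling_value
  }
  pmin(norm, 1)
}

#' Build a per-prophage bin matrix
#'
#' @param insertion_sets Named list of unique-insertion `data.frame`s (or
#'   position vectors), one per prophage; self-insertions are excluded.
#' @param L Genome length.
#' @param prophages Optional list of [prophage_locus()] matching the names,
#'   used to flag each row's starting bin.
#' @param n_bins Number of bins (default 200).
#' @param read_depth Per-row depths for normalization (default 1).
#' @param mode Normalization mode (see [normalize_bins()]).
#' @return Object of class `bin_matrix`: `raw`, `values` (normalized),
#'   `n_bins`, `bin_width`, `start_bins`.
#' @export
bin_matrix <- function(insertion_sets, L, prophages = NULL, n_bins = 200L,
                       read_depth = 1, mode = "depth") {
  pos_of <- function(x) {
    if (is.data.frame(x)) x$position[!isTRUE_vec(x$is_self)] else x
  }
  isTRUE_vec <- function(v) if (is.null(v)) FALSE else v
  raw <- t(vapply(insertion_sets,
                  function(x) bin_insertions(pos_of(x), L, n_bins),
                  integer(n_bins)))
  rownames(raw) <- names(insertion_sets)
  bw <- bin_width(L, n_bins)
  start_bins <- rep(NA_integer_, nrow(raw))
  if (!is.null(prophages)) {
    labs <- vapply(prophages, `[[`, "", "label")
    for (i in seq_len(nrow(raw))) {
      j <- match(rownames(raw)[i], labs)
      if (!is.na(j))
        start_bins[i] <- (prophages[[j]]$left_end - 1L) %/% bw + 1L
    }
  }
  values <- normalize_bins(raw, read_depth, mode = mode,
                           start_bins = start_bins)
  structure(list(raw = raw, values = values, n_bins = as.integer(n_bins),
                 bin_width = bw, start_bins = start_bins, L = L),
            class = "bin_matrix")
}

#' Write a bin matrix as TSV (bins as columns)
#' @param mat A [bin_matrix()].
#' @param path Output TSV.
#' @param what `"values"` (normalized) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(mat, path, what = c("values", "raw")) {
  what <- match.arg(what)
  m <- mat[[what]]
  colnames(m) <- sprintf("bin%03d", seq_len(ncol(m)))
  utils::write.table(cbind(prophage = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
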