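# Cis-immunity analysis: insertion frequency per distance window outside the
# prophage ends, a genome-wide bulk baseline, and detection of the
# dead-zone / boundary / bulk phase structure.

#' Distance-resolved insertion profile around a prophage
#'
#' Counts insertions per `window`-bp distance window outward from each
#' prophage end, up to `max_dist`. Distances never span the prophage
#' interior; each insertion within range of an end contributes to exactly
#' one side (the nearer end); self-insertions are excluded. The combined
#' profile sums the two sides window-wise.
#'
#' @param insertions Unique-insertion `data.frame` (or position vector).
#' @param prophage A [prophage_locus()].
#' @param L Genome length.
#' @param window Window width in bp (default 100).
#' @param max_dist Profile reach in bp (default 25000).
#' @param circular Circular distance arithmetic (default `TRUE`).
#' @return Object of class `distance_profile`: `distance` (window lower
#'   edges), `left`, `right`, `combined` counts, plus the parameters.
#' @export
distance_profile <- function(insertions, prophage, L, window = 100L,
                             max_dist = 25000L, circular = TRUE) {
  if (window <= 0L) stop("window must be positive")
  pos <- if (is.data.frame(insertions)) {
    keep <- if (is.null(insertions$is_self)) TRUE else !insertions$is_self
    insertions$position[keep]
  } else insertions
  dl <- if (circular) circular_distance(pos, prophage$left_end, L)
        else abs(pos - prophage$left_end)
  dr <- if (circular) circular_distance(pos, prophage$right_end, L)
        else abs(pos - prophage$right_end)
  inside <- pos >= prophage$left_end & pos <= prophage$right_end
  nb <- as.integer(ceiling(max_dist / window))
  count_side <- function(d, other, take) {
    sel <- !inside & take & d <= other & d > 0 & d <= max_dist
    tabulate(pmin(d[sel] %/% window, nb - 1L) + 1L, nbins = nb)
  }
  # ties (equidistant) go to the left side
  left <- count_side(dl, dr, TRUE)
  right <- count_side(dr, dl, dr < dl)
  structure(list(distance = (seq_len(nb) - 1L) * window,
                 left = left, right = right, combined = left + right,
                 window = as.integer(window),
                 max_dist = as.integer(max_dist)),
            class = "distance_profile")
}

#' Bulk-genome insertion baseline
#'
#' Mean and standard deviation of insertions per `window`-bp over the
#' genome, omitting the prophage interval and an `exclusion_radius` around
#' it (defaults to the full immunity reach, 25 kb, since cis-immunity
#' decays gradually out to ~25 kb).
#'
#' @param insertions Unique-insertion `data.frame` or position vector.
#' @param prophage A [prophage_locus()].
#' @param L Genome length.
#' @param window Window width (default 100).
#' @param exclusion_radius Radius excluded around the prophage
#'   (default 25000).
#' @return Object of class `bulk_baseline`: `mean`, `sd`, `n_windows`,
#'   `window`, `exclusion_radius`.
#' @export
bulk_baseline <- function(insertions, prophage, L, window = 100L,
                          exclusion_radius = 25000L) {
  pos <- if (is.data.frame(insertions)) {
    keep <- if (is.null(insertions$is_self)) TRUE else !insertions$is_self
    insertions$position[keep]
  } else insertions
  lo <- prophage$left_end - exclusion_radius
  hi <- prophage$right_end + exclusion_radius
  excl_len <- hi - lo + 1L
  if (excl_len >= L) stop("exclusion zone covers the whole genome")
  if (length(pos) == 0L)
    return(structure(list(mean = 0, sd = 0, n_windows = 0L,
                          window = window,
                          exclusion_radius = exclusion_radius),
                     class = "bulk_baseline"))
  # rotate so the excluded arc is contiguous at the front, then window
  shift <- ((pos - lo) %% L) + 1L   # 1..L, excluded arc = 1..excl_len
  keep <- shift > excl_len
  rel <- shift[keep] - excl_len
  span <- L - excl_len
  nb <- span %/% window   # drop the short trailing window
  cnt <- tabulate((rel[rel <= nb * window] - 1L) %/% window + 1L,
                  nbins = nb)
  structure(list(mean = mean(cnt), sd = stats::sd(cnt), n_windows = nb,
                 window = as.integer(window),
                 exclusion_radius = as.integer(exclusion_radius)),
            class = "bulk_baseline")
}

# moving average (window w) keeping the vector length
.movavg <- function(x, w = 3L) {
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L))
  na <- is.na(y)
  y[na] <- x[na]
  y
}

#' Detect immunity phases in a distance profile
#'
#' Operationalizes the visually defined phase structure:
#' * `first_insertion`: lower edge of the first nonzero window, per end and
#'   combined.
#' * `bulk_reach`: first distance from which `k_run` consecutive combined
#'   windows stay at or above `mean - sd` of the bulk baseline.
#' * `boundary_distance`: distance of the maximum slope of the smoothed
#'   combined profile below `bulk_reach` (3-window moving average, slopes
#'   taken over a `slope_span`-window span to suppress count noise).
#' * `n_phases`: 3 when the slope maximum is significant — above twice the
#'   median slope over the rise and above a robust noise threshold
#'   (median + z * 1.4826 * MAD, z from a 1% Bonferroni bound) — so that a
#'   single uniform ramp (the MuB-less two-phase pattern) is not split.
#'
#' @param profile A [distance_profile()].
#' @param baseline A [bulk_baseline()] with the same window size.
#' @param k_run Consecutive windows required at bulk level (default 5).
#' @param slope_span Span, in windows, over which slopes are measured
#'   (default 20, a +/- 1 kb centered span at 100-bp windows; wide enough
#'   that consensus-site overdispersion does not mimic a sharp rise).
#' @return Object of class `phase_report`: `first_insertion` (named vector
#'   `left`, `right`, `combined`, bp), `boundary_distance`, `bulk_reach`
#'   (bp), `n_phases` (2 or 3), `defined` flag.
#' @export
detect_phases <- function(profile, baseline, k_run = 5L, slope_span = 20L) {
  if (profile$window != baseline$window)
    stop("profile and baseline window sizes differ")
  cnt <- profile$combined
  und <- structure(list(first_insertion = c(left = NA_real_,
                                            right = NA_real_,
                                            combined = NA_real_),
                        boundary_distance = NA_real_, bulk_reach = NA_real_,
                        n_phases = NA_integer_, defined = FALSE),
                   class = "phase_report")
  if (all(cnt == 0)) return(und)
  first_nz <- function(v)
    if (any(v > 0)) profile$distance[which(v > 0)[1L]] else NA_real_
  fi <- c(left = first_nz(profile$left), right = first_nz(profile$right),
          combined = first_nz(cnt))
  # the combined profile sums the two ends, so the bulk level for one
  # window is twice the baseline mean with sd scaled by sqrt(2)
  thresh <- 2 * baseline$mean - sqrt(2) * baseline$sd
  ok <- cnt >= thresh
  runs <- stats::filter(as.numeric(ok), rep(1, k_run), sides = 1L)
  reach_idx <- which(!is.na(runs) & runs == k_run)
  bulk_reach <- if (length(reach_idx))
    profile$distance[reach_idx[1L] - k_run + 1L] else NA_real_
  sm <- .movavg(cnt, 3L)
  # centered slopes over a +/- h window span: robust to count noise while
  # an exact step profile still localizes to its true edge (the argmax
  # plateau is symmetric around the step; ties resolve to its midpoint);
  # the slope search runs from the profile start to just past bulk_reach
  h <- max(1L, slope_span %/% 2L)
  top <- if (is.na(bulk_reach)) length(sm)
         else min(length(sm), which(profile$distance == bulk_reach) + h)
  slope <- rep(NA_real_, length(sm))
  idx <- seq.int(h + 1L, max(h + 1L, min(top, length(sm) - h)))
  slope[idx] <- (sm[idx + h] - sm[idx - h]) / (2 * h)
  cand <- idx
  sl <- slope[cand]
  sl <- sl[!is.na(sl)]
  if (length(sl) < 3L) {
    bd <- NA_real_
    n_phases <- 2L
  } else {
    at_max <- cand[which(slope[cand] == max(sl))]
    bd <- profile$distance[ceiling(mean(at_max))]
    med <- stats::median(sl)
    noise <- stats::mad(sl)
    z <- stats::qnorm(1 - 0.01 / length(sl))
    significant <- max(sl) > 2 * med && max(sl) > med + z * noise
    n_phases <- if (significant) 3L else 2L
    if (!significant) bd <- NA_real_
  }
  structure(list(first_insertion = fi, boundary_distance = bd,
                 bulk_reach = bulk_reach, n_phases = n_phases,
                 defined = TRUE),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf(paste0("<phase_report> %d phase(s); first insertion L/R: ",
                     "%s/%s bp; boundary %s bp; bulk reach %s bp\n"),
              x$n_phases, format(x$first_insertion["left"]),
              format(x$first_insertion["right"]),
              format(x$boundary_distance), format(x$bulk_reach)))
  invisible(x)
}

#' Write a distance profile as TSV
#' @param profile A [distance_profile()].
#' @param path Output TSV.
#' @param per_reads Optional denominator: counts are also reported per this
#'   many reads (e.g. 5e6) when `n_reads` is given.
#' @param n_reads Reads in the run the profile came from.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, per_reads = NULL, n_reads = NULL) {
  df <- data.frame(distance = profile$distance, left = profile$left,
                   right = profile$right, combined = profile$combined)
  if (!is.null(per_reads) && !is.null(n_reads))
    df$combined_normalized <- profile$combined * per_reads / n_reads
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
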