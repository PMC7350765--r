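# Shared fixtures, built in code. The moderate library fixture is cached per
# session so several test files can reuse one simulate -> sequence -> call
# cycle.

.fx <- new.env(parent = emptyenv())

# small host genome with one resident prophage
fixture_genome <- function(L = 5e4, mu_length = 5000L, at = NULL,
                           seed = 101L, label = "Mu") {
  key <- paste("g", L, mu_length, seed, label, sep = "_")
  if (is.null(.fx[[key]])) {
    g <- generate_genome(L, 0.5, seed = seed)
    if (is.null(at)) at <- L %/% 2
    pr <- insert_prophage(g, at = at, mu_length = mu_length,
                          seed = seed + 1L, label = label)
    .fx[[key]] <- pr
  }
  .fx[[key]]
}

# a full simulate -> library -> call run on a 200 kb genome, reused across
# junction-caller and immunity tests
fixture_called_run <- function() {
  if (is.null(.fx$run)) {
    fx <- fixture_genome(L = 2e5, mu_length = 10000L, seed = 201L,
                         label = "OPL")
    chem <- library_chemistry(pcr_duplication = 1.5)
    cfg <- sim_config(fx$genome, list(fx$prophage),
                      consensus = consensus_model(fold = 7),
                      immunity = immunity_model("WT_EST"), chem = chem)
    ev <- sample_insertions(cfg, 1000, seed = 301L)
    f1 <- tempfile(fileext = "_1.fq")
    f2 <- tempfile(fileext = "_2.fq")
    lib <- make_library(ev, fx$genome, chem, f1, f2, seed = 302L)
    res <- call_insertions(fastq1 = f1, fastq2 = f2, genome = fx$genome,
                           chem = chem, prophages = list(fx$prophage))
    .fx$run <- list(fx = fx, chem = chem, cfg = cfg, events = ev,
                    lib = lib, res = res, fastq1 = f1, fastq2 = f2)
  }
  .fx$run
}

# brute-force circular two-changepoint oracle (independent of the package's
# cumulative-sum search): enumerate every circular segment directly and
# score it with the same variance-weighted mean-difference statistic
brute_force_segment <- function(x, use = rep(TRUE, length(x))) {
  n <- length(x)
  n_used <- sum(use)
  best <- list(score = -Inf, start = NA, end = NA, len = -1L)
  for (s in seq_len(n)) for (l in seq_len(n - 1L)) {
    idx <- ((s - 1L + seq_len(l) - 1L) %% n) + 1L
    inside <- idx[use[idx]]
    outside <- setdiff(which(use), inside)
    if (length(inside) == 0L || length(outside) == 0L) next
    sc <- (mean(x[inside]) - mean(x[outside])) *
      sqrt(length(inside) * length(outside) / n_used)
    if (sc > best$score || (sc == best$score && l > best$len)) {
      e <- ((s - 1L + l - 1L) %% n) + 1L
      best <- list(score = sc, start = s, end = e, len = l)
    }
  }
  best
}

# brute-force signature scan oracle
brute_force_signature <- function(read, sig, mm) {
  n <- nchar(read); k <- nchar(sig)
  if (k > n) return(NA_integer_)
  for (o in 0:(n - k)) {
    d <- sum(strsplit(substr(read, o + 1L, o + k), "")[[1L]] !=
               strsplit(sig, "")[[1L]])
    if (d <= mm) return(o)
  }
  NA_integer_
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
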