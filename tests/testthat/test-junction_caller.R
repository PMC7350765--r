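test_that("find_signature matches a brute-force scan", {
  sig <- "TACGGCTAGCAT"
  read <- paste0("ACGTAC", sig, "GGGTTT")
  expect_equal(find_signature(read, sig, 0), 6L)
  expect_true(is.na(find_signature("ACGTACGTACGT", sig, 0)))
  expect_true(is.na(find_signature("ACG", sig, 0)))
  # planted single mismatch found at the same offset with tolerance 1
  read_mm <- read
  substr(read_mm, 9, 9) <- "A"
  expect_true(is.na(find_signature(read_mm, sig, 0)))
  expect_equal(find_signature(read_mm, sig, 1), 6L)
  set.seed(9)
  for (i in 1:20) {
    r <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    s <- substr(r, 25, 36)
    for (mm in 0:1)
      expect_equal(find_signature(r, s, mm),
                   brute_force_signature(r, s, mm))
  }
})

test_that("extraction recovers the truth host fragment and UMI", {
  run <- fixture_called_run()
  chem <- run$chem
  r1 <- as.character(Biostrings::readDNAStringSet(run$fastq1,
                                                  format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(run$fastq2,
                                                  format = "fastq"))
  ex <- extract_junctions(r1, r2, chem)
  expect_true(all(is.na(ex$reject)))
  # each read's truth tag names its event; the extracted UMI must match
  ev_idx <- as.integer(sub("^evt(\\d+):.*$", "\\1",
                           names(Biostrings::readDNAStringSet(
                             run$fastq1, format = "fastq"))))
  expect_identical(ex$umi, run$lib$truth$umi[ev_idx])
})

test_that("extraction rejects malformed reads with the right reason", {
  chem <- library_chemistry()
  mu <- chem$mu_end_signature
  good_host <- strrep("ACGT", 20)
  r1_ok <- paste0(mu, good_host)
  r2_ok <- paste0("ACACAC", chem$adapter_signature, strrep("T", 60))
  ex <- extract_junctions(
    c(substr(paste0("C", substr(r1_ok, 2, nchar(r1_ok))), 1, 150),
      "ACGT", r1_ok, r1_ok, r1_ok),
    c(r2_ok, r2_ok, paste0("ACACAC", "GGGGGGGGGGGG", strrep("T", 60)),
      paste0("ACANAC", chem$adapter_signature, strrep("T", 60)), r2_ok),
    chem, max_mismatch = 0)
  expect_equal(ex$reject,
               c("no_mu_end", "too_short", "no_adapter", "no_adapter", NA))
  expect_equal(ex$umi[5], "ACACAC")
})

test_that("the exact mapper recovers positions, flags repeats, honors k", {
  fx <- fixture_genome(L = 3e4, mu_length = 2000L, seed = 61L)
  g <- fx$genome
  frag <- substr(g$sequence, 501, 560)
  m <- map_fragment(frag, g)
  expect_equal(m$mapq_class, "unique")
  expect_equal(m$position, 501L)
  expect_equal(m$strand, "+")
  # reverse-strand fragment: junction at its first base
  rc <- revcomp_chr(substr(g$sequence, 701, 760))
  m2 <- map_fragment(rc, g)
  expect_equal(m2$mapq_class, "unique")
  expect_equal(m2$strand, "-")
  expect_equal(m2$position, 760L - 4L)
  # repeat-bearing toy: the same 60-mer twice -> ambiguous
  rep_seq <- paste0(strrep("AT", 200), substr(g$sequence, 501, 560),
                    strrep("TA", 200), substr(g$sequence, 501, 560),
                    strrep("GC", 50))
  m3 <- map_fragment(substr(g$sequence, 501, 560),
                     reference_genome(rep_seq))
  expect_equal(m3$mapq_class, "ambiguous")
  expect_equal(map_fragment("ACGTACGTAC", g)$mapq_class, "unmapped")
})

test_that("mapping a circular-wrap fragment canonicalizes the position", {
  g <- fixture_genome(L = 3e4, mu_length = 2000L, seed = 61L)$genome
  L <- g$length
  wrap_frag <- paste0(substr(g$sequence, L - 24, L), substr(g$sequence, 1, 25))
  m <- map_fragment(wrap_frag, g)
  expect_equal(m$mapq_class, "unique")
  expect_equal(m$position, L - 24L)
})

test_that("dedup collapses by (position, strand, UMI) and is idempotent", {
  jx <- data.frame(
    position = c(10L, 10L, 10L, 10L, 50L),
    strand = c("+", "+", "+", "+", "-"),
    umi = c("AAAAAA", "AAAAAA", "AAAAAA", "CCCCCC", "GGGGGG"),
    stringsAsFactors = FALSE)
  u <- dedup(jx)
  expect_equal(nrow(u), 2L)
  row10 <- u[u$position == 10L, ]
  expect_equal(row10$read_count, 4L)
  expect_equal(row10$umi_count, 2L)
  jx3 <- jx[1:3, ]
  u3 <- dedup(jx3)
  expect_equal(u3$read_count, 3L)
  expect_equal(u3$umi_count, 1L)
  # idempotence: feeding a deduplicated table back changes nothing
  u_again <- dedup(transform(u, umi = c("AAAAAA", "GGGGGG"))[
    , c("position", "strand", "umi", "read_count")])
  expect_equal(u_again$read_count, u$read_count)
  expect_equal(u_again$position, u$position)
})

test_that("self classification requires novelty inside a donor", {
  p <- prophage_locus(1000, 5999, "dMuB", "Mu")
  ins <- data.frame(position = c(3000L, 1000L, 1003L, 5996L, 800L, 6200L))
  out <- classify_self(ins, list(p))
  expect_equal(out$is_self, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$donor[1], "Mu")
  expect_error(classify_self(ins, list(p, prophage_locus(5000, 9999))),
               "overlapping")
})

test_that("simulated self-insertions are recovered within binomial bounds", {
  fx <- fixture_genome(L = 1e5, mu_length = 20000L, seed = 71L)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    immunity = immunity_model("none"),
                    self_insertion_rate = 5e-3)
  ev <- sample_insertions(cfg, 2e4, seed = 72L)
  called <- classify_self(data.frame(position = ev$position),
                          list(fx$prophage))
  n_si <- sum(called$is_self)
  bounds <- stats::qbinom(c(2.5e-4, 1 - 2.5e-4), 2e4, 5e-3)
  expect_gte(n_si, bounds[1])
  expect_lte(n_si, bounds[2])
})

test_that("end-to-end calling recovers every truth insertion exactly", {
  run <- fixture_called_run()
  res <- run$res
  r <- res$report
  expect_equal(r$reads_in,
               sum(r$rejected) + r$unmapped + r$ambiguous + r$counted)
  truth <- run$lib$truth[!run$lib$truth$dropped, ]
  called <- paste(res$insertions$position, res$insertions$strand)
  expect_true(all(paste(truth$position, truth$strand) %in% called))
  expect_true(all(called %in% paste(truth$position, truth$strand)))
  expect_equal(r$self_insertions, 0L)
})

test_that("the unique-insertion set is invariant to PCR duplication level", {
  fx <- fixture_genome(L = 1e5, mu_length = 5000L, seed = 81L)
  key_at <- function(dup) {
    chem <- library_chemistry(pcr_duplication = dup)
    cfg <- sim_config(fx$genome, list(fx$prophage),
                      immunity = immunity_model("none"), chem = chem)
    ev <- sample_insertions(cfg, 500, seed = 82L)
    f1 <- tempfile(); f2 <- tempfile()
    make_library(ev, fx$genome, chem, f1, f2, seed = 83L)
    res <- call_insertions(fastq1 = f1, fastq2 = f2, genome = fx$genome,
                           chem = chem)
    paste(res$insertions$position, res$insertions$strand)
  }
  expect_setequal(key_at(1), key_at(3))
})

test_that("empty FASTQ yields an empty table and a clean report", {
  f1 <- tempfile(); f2 <- tempfile()
  file.create(f1); file.create(f2)
  g <- fixture_genome(L = 3e4, mu_length = 2000L, seed = 61L)$genome
  res <- call_insertions(fastq1 = f1, fastq2 = f2, genome = g)
  expect_equal(nrow(res$insertions), 0L)
  expect_equal(res$report$reads_in, 0L)
})

test_that("SAM re-entry reproduces the FASTQ-mode insertion table", {
  run <- fixture_called_run()
  sam <- tempfile(fileext = ".sam")
  write_junction_sam(run$res$junctions, run$fx$genome, sam)
  res2 <- call_insertions(sam = sam, prophages = list(run$fx$prophage))
  a <- run$res$insertions
  b <- res2$insertions
  expect_equal(b[, c("position", "strand", "read_count", "umi_count")],
               a[, c("position", "strand", "read_count", "umi_count")])
})
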