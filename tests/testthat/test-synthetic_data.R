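test_that("genome generation is seed-deterministic with the right GC", {
  g1 <- generate_genome(1000, 0.5, seed = 1)
  g2 <- generate_genome(1000, 0.5, seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  expect_error(generate_genome(1000, gc = 1.0, seed = 1), "gc")
  expect_error(generate_genome(5, gc = 0.5, seed = 1), "length")
  g <- generate_genome(1e5, 0.5, seed = 7)
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) / g$length
  # binomial: sd of the GC estimate at n = 1e5 is ~0.0016
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("immunity weight is 0 in the dead zone, 1 at bulk, monotone", {
  for (kind in c("WT_EST", "dMuB_EST", "dMuB_LST")) {
    m <- immunity_model(kind)
    d <- seq(0, 30000, by = 50)
    w <- immunity_weight(m, d)
    expect_true(all(w[d < m$d_dead] == 0), info = kind)
    expect_true(all(w[d >= m$d_bulk] == 1), info = kind)
    expect_true(all(diff(w) >= -1e-12), info = kind)
    expect_true(all(w >= 0 & w <= 1), info = kind)
  }
  expect_true(all(immunity_weight(immunity_model("none"), 0:100) == 1))
})

test_that("the CYSRG expansion is reverse-complement closed, palindrome-free", {
  ex <- expand_degenerate("CYSRG")
  expect_length(ex, 8L)
  rc <- revcomp_chr(ex)
  expect_setequal(ex, rc)
  expect_true(all(ex != rc))  # 4 reverse-complement pairs, no palindromes
})

test_that("WT EST sampling leaves the 1.5 kb dead zone empty", {
  fx <- fixture_genome(L = 1e5, mu_length = 8000L, seed = 11L)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    immunity = immunity_model("WT_EST"))
  ev <- sample_insertions(cfg, 2e4, seed = 12L)
  p <- fx$prophage
  outside <- ev$position < p$left_end | ev$position > p$right_end
  expect_true(all(outside))
  d <- pmin(circular_distance(ev$position, p$left_end, fx$genome$length),
            circular_distance(ev$position, p$right_end, fx$genome$length))
  expect_true(all(d >= 1500))
})

test_that("the null model is uniform within multinomial noise", {
  fx <- fixture_genome(L = 1e5, mu_length = 1000L, seed = 21L)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    consensus = consensus_model(fold = 1),
                    immunity = immunity_model("none"))
  ev <- sample_insertions(cfg, 1e4, seed = 22L)
  # exclude the two bins holding the (excluded) prophage interval
  counts <- bin_insertions(ev$position, fx$genome$length, 20)
  p <- fx$prophage
  bw <- bin_width(fx$genome$length, 20)
  touched <- unique((c(p$left_end, p$right_end) - 1) %/% bw + 1)
  keep <- setdiff(seq_len(20), touched)
  chi <- stats::chisq.test(counts[keep])
  expect_gt(chi$p.value, 0.01)
})

test_that("events carry their + strand target pentamer and self flags", {
  fx <- fixture_genome(L = 5e4, mu_length = 5000L, seed = 31L)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    self_insertion_rate = 0.2,
                    immunity = immunity_model("none"))
  ev <- sample_insertions(cfg, 500, seed = 32L)
  g <- fx$genome
  pent <- vapply(ev$position, function(p)
    substr(g$sequence, p, p + 4L), "")
  expect_identical(ev$target_pentamer, pent)
  p <- fx$prophage
  inside <- ev$position > p$left_end & ev$position < p$right_end
  expect_identical(ev$is_self, inside)
})

test_that("library chemistry invariants are enforced", {
  expect_error(library_chemistry(adapter_signature = "ACGT"), "12-mer")
  expect_error(library_chemistry(pcr_duplication = 0.5), ">= 1")
  expect_error(library_chemistry(enzyme_site = "GCGC", cut_after = 4),
               "cut_after")
})

test_that("make_library emits one pair per event at duplication 1, with the
          adapter at the UMI offset and hand-computable fragment lengths", {
  fx <- fixture_genome(L = 5e4, mu_length = 5000L, seed = 41L)
  chem <- library_chemistry(pcr_duplication = 1)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    immunity = immunity_model("none"), chem = chem)
  ev <- sample_insertions(cfg, 300, seed = 42L)
  f1 <- tempfile(); f2 <- tempfile()
  lib <- make_library(ev, fx$genome, chem, f1, f2, seed = 43L)
  expect_equal(lib$n_pairs, sum(!lib$truth$dropped))
  r2 <- as.character(Biostrings::readDNAStringSet(f2, format = "fastq"))
  expect_true(all(substr(r2, chem$umi_length + 1L,
                         chem$umi_length + 12L) == chem$adapter_signature))
  # determinism: identical config + seed gives byte-identical FASTQ
  g1 <- tempfile(); g2 <- tempfile()
  ev_b <- sample_insertions(cfg, 300, seed = 42L)
  make_library(ev_b, fx$genome, chem, g1, g2, seed = 43L)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("fragments run from the junction to the enzyme cut (G^CGC)", {
  # A/T-only background: the only GCGC is the planted one, 80 bp downstream
  set.seed(5)
  base <- paste(sample(c("A", "T"), 400, replace = TRUE), collapse = "")
  seq <- paste0(substr(base, 1, 180), "GCGC", substr(base, 185, 400))
  g <- reference_genome(seq, circular = TRUE)
  chem <- library_chemistry(pcr_duplication = 1)
  ev <- data.frame(position = 101L, strand = "+", donor = "Mu",
                   is_self = FALSE, target_pentamer = "NNNNN")
  f1 <- tempfile(); f2 <- tempfile()
  lib <- make_library(ev, g, chem, f1, f2, seed = 1)
  # junction at 101, site starts at 181, top cut keeps the G: 101..181
  expect_equal(lib$truth$frag_len, 81L)
  # minus-strand event right of the site: bottom cut keeps through s+3
  ev2 <- data.frame(position = 240L, strand = "-", donor = "Mu",
                    is_self = FALSE, target_pentamer = "NNNNN")
  lib2 <- make_library(ev2, g, chem, f1, f2, seed = 1)
  # junction base 244, bottom fragment spans 184..244
  expect_equal(lib2$truth$frag_len, 61L)
})

test_that("multi-hop sampling adds donors and keeps events on the genome", {
  fx <- fixture_genome(L = 2e5, mu_length = 5000L, seed = 51L)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    immunity = immunity_model("dMuB_LST"))
  ev <- sample_insertions_lst(cfg, 3000, rounds = 3, seed = 52L)
  expect_equal(nrow(ev), 3000L)
  expect_setequal(unique(ev$round), 1:3)
  expect_true(all(ev$position >= 1 & ev$position <= fx$genome$length))
})
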