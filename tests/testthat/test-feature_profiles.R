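test_that("gene-relative offsets are zero-free and strand-oriented", {
  feat <- list(name = "geneA", start = 1000L, end = 2000L, strand = "+")
  prof <- gene_relative_profile(c(999L, 1000L, 1200L), feat)
  expect_equal(prof$counts[match(-1L, prof$offsets)], 1L)
  expect_equal(prof$counts[match(1L, prof$offsets)], 1L)
  expect_equal(prof$counts[match(201L, prof$offsets)], 1L)
  expect_false(0L %in% prof$offsets)
  # minus-strand gene: genomic upstream flips to positive offsets
  featm <- list(name = "geneB", start = 1000L, end = 2000L, strand = "-")
  profm <- gene_relative_profile(c(2001L), featm)
  expect_equal(profm$counts[match(-1L, profm$offsets)], 1L)
  profm2 <- gene_relative_profile(c(1999L), featm)
  expect_equal(profm2$counts[match(2L, profm2$offsets)], 1L)
  expect_error(gene_relative_profile(1L, list(name = "x", start = -5,
                                              end = 10, strand = "+"),
                                     L = 100), "outside")
})

test_that("orientation involution: flipping strand and mirroring insertions
          leaves the profile unchanged", {
  set.seed(17)
  anchor <- 5000L
  ins <- anchor + sample(-400:400, 200, replace = TRUE)
  feat_p <- list(name = "g", start = anchor, end = anchor + 900L,
                 strand = "+")
  # mirror positions around the anchor for the minus-strand version
  feat_m <- list(name = "g", start = anchor - 900L, end = anchor,
                 strand = "-")
  mirrored <- 2L * anchor - ins
  a <- gene_relative_profile(ins, feat_p)
  b <- gene_relative_profile(mirrored, feat_m)
  expect_equal(a$counts, b$counts)
  # conservation: every insertion inside the window is counted once
  expect_equal(sum(a$counts), sum(ins - anchor >= -500 & ins - anchor <= 499))
})

test_that("exclusion zones are maximal zero runs around +1", {
  feat <- list(name = "g", start = 1000L, end = 2000L, strand = "+")
  # insertions everywhere except [-100, +200] around the start
  pos <- c(seq(500L, 899L, by = 1L), seq(1200L, 1500L, by = 1L))
  prof <- gene_relative_profile(pos, feat)
  z <- exclusion_zone(prof)
  expect_true(z$spans_plus_one)
  expect_equal(z$upstream_extent, 100L)
  expect_equal(z$downstream_extent, 200L)
  # no zeros at +1: empty zone
  prof2 <- gene_relative_profile(seq(500L, 1500L), feat)
  z2 <- exclusion_zone(prof2)
  expect_false(z2$spans_plus_one)
  expect_equal(z2$upstream_extent + z2$downstream_extent, 0L)
})

test_that("a planted exclusion zone is recovered from simulated data", {
  fx <- fixture_genome(L = 1e5, mu_length = 2000L, seed = 601L)
  cfg <- sim_config(fx$genome, list(fx$prophage),
                    immunity = immunity_model("none"))
  ev <- sample_insertions(cfg, 1e6, seed = 602L)
  anchor <- 20000L
  keep <- !(ev$position >= anchor - 50L & ev$position <= anchor + 150L)
  feat <- list(name = "g", start = anchor, end = anchor + 1000L,
               strand = "+")
  z <- exclusion_zone(gene_relative_profile(ev$position[keep], feat))
  expect_true(z$spans_plus_one)
  expect_equal(z$upstream_extent, 50L)
  expect_equal(z$downstream_extent, 151L)  # +1..+151 covers anchor..+150
})

test_that("tRNA rows are flagged only for mature-region avoidance", {
  trnas <- data.frame(name = c("tA", "tB", "tC"),
                      start = c(1000L, 3000L, 5000L),
                      end = c(1075L, 3075L, 5075L),
                      strand = c("+", "+", "+"))
  # tA: leader hits only; tB: hits everywhere; tC: nothing at all
  ins <- c(950L, 960L, 2950L, 3020L, 3050L)
  tp <- trna_profile(ins, trnas)
  expect_true(tp$flagged[["tA"]])
  expect_false(tp$flagged[["tB"]])
  expect_false(tp$flagged[["tC"]])
  empty <- trna_profile(ins, trnas[0, ])
  expect_equal(nrow(empty$matrix), 0L)
  # uniform insertions at depth flag (almost) nothing
  set.seed(19)
  dense <- sample.int(6000, 3000, replace = TRUE)
  tp2 <- trna_profile(dense, trnas)
  expect_equal(sum(tp2$flagged), 0L)
})

test_that("coding fractions report observed vs uniform expectation", {
  cds <- data.frame(start = c(100L, 300L), end = c(250L, 500L))
  cf <- coding_fraction(seq(50L, 550L, by = 1L), c(1L, 530L), cds)
  expect_equal(cf$expected_pct, 100 * (151 + 201) / 530, tolerance = 1e-10)
  got <- sum(seq(50L, 530L) >= 100 & seq(50L, 530L) <= 250) +
    sum(seq(50L, 530L) >= 300 & seq(50L, 530L) <= 500)
  expect_equal(cf$observed_pct, 100 * got / length(seq(50L, 530L)))
  cf0 <- coding_fraction(c(260L, 270L), c(1L, 530L), cds)
  expect_equal(cf0$observed_pct, 0)
  cfe <- coding_fraction(integer(0), c(1L, 530L), cds)
  expect_false(cfe$defined)
  # simulated down-weighting of CDS: the closed-form mixture is recovered
  set.seed(23)
  w <- rep(1, 10000); w[2001:10000] <- 0.3   # CDS covers 80% of the window
  pos <- sample.int(10000, 3e4, replace = TRUE, prob = w)
  cds2 <- data.frame(start = 2001L, end = 10000L)
  cf2 <- coding_fraction(pos, c(1L, 10000L), cds2)
  expected <- 100 * 0.3 * 0.8 / (0.3 * 0.8 + 0.2)
  expect_lt(abs(cf2$observed_pct - expected), 2)
})
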