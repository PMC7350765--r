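test_that("distance windows are end-relative with the floor convention", {
  p <- prophage_locus(40000, 44999, "WT", "Mu")
  L <- 100000
  prof <- distance_profile(c(45149L), p, L, window = 100)
  expect_equal(prof$right[2], 1L)   # 150 bp right of the right end
  expect_equal(sum(prof$left), 0L)
  prof0 <- distance_profile(c(45000L), p, L, window = 100)
  expect_equal(prof0$right[1], 1L)  # adjacent base, window 0
  expect_equal(prof$combined, prof$left + prof$right)
  expect_error(distance_profile(1L, p, L, window = 0), "window")
  # interior positions never count
  profi <- distance_profile(c(42000L), p, L)
  expect_equal(sum(profi$combined), 0L)
})

test_that("bulk baseline matches the closed-form Poisson expectation", {
  p <- prophage_locus(400000, 436999, "WT", "Mu")
  L <- 1000000
  set.seed(7)
  n <- 2e5
  pos <- sample.int(L, n, replace = TRUE)
  outside <- pos < p$left_end - 25000 | pos > p$right_end + 25000
  b <- bulk_baseline(pos[outside], p, L, window = 100,
                     exclusion_radius = 25000)
  span <- L - (p$mu_length + 2 * 25000)
  expected <- sum(outside) * 100 / span
  expect_lt(abs(b$mean - expected) / expected, 0.01)
  expect_lt(abs(b$sd - sqrt(b$mean)) / sqrt(b$mean), 0.15)
  b0 <- bulk_baseline(integer(0), p, L)
  expect_equal(c(b0$mean, b0$sd), c(0, 0))
  expect_error(bulk_baseline(pos, p, L, exclusion_radius = L), "covers")
})

test_that("a step profile yields a boundary at the step, exactly", {
  d <- seq(0, 24900, by = 100)
  prof <- structure(list(distance = d, left = rep(0L, length(d)),
                         right = rep(0L, length(d)),
                         combined = ifelse(d >= 5000, 60L, 0L),
                         window = 100L, max_dist = 25000L),
                    class = "distance_profile")
  base <- structure(list(mean = 30, sd = 0.5, n_windows = 1000,
                         window = 100L, exclusion_radius = 25000L),
                    class = "bulk_baseline")
  ph <- detect_phases(prof, base)
  expect_equal(ph$boundary_distance, 5000)
  expect_equal(ph$bulk_reach, 5000)
  # all-zero profile: undefined report with explicit flag
  prof0 <- prof
  prof0$combined <- prof0$left
  und <- detect_phases(prof0, base)
  expect_false(und$defined)
})

test_that("simulated immunity kinds produce their phase signatures", {
  fx <- fixture_genome(L = 2e5, mu_length = 10000L, seed = 201L,
                       label = "OPL")
  run_phases <- function(kind, seed) {
    cfg <- sim_config(fx$genome, list(fx$prophage),
                      consensus = consensus_model(fold = 7),
                      immunity = immunity_model(kind))
    ev <- sample_insertions(cfg, 2e5, seed = seed)
    detect_phases(distance_profile(ev, fx$prophage, fx$genome$length),
                  bulk_baseline(ev, fx$prophage, fx$genome$length))
  }
  wt <- run_phases("WT_EST", 211L)
  expect_equal(wt$n_phases, 3L)
  expect_gte(wt$first_insertion[["combined"]], 1500)
  expect_lte(wt$first_insertion[["combined"]], 2100)
  expect_gte(wt$boundary_distance, 4500)
  expect_lte(wt$boundary_distance, 7000)
  expect_gte(wt$bulk_reach, 6000)
  expect_lte(wt$bulk_reach, 9000)
  mub <- run_phases("dMuB_EST", 212L)
  expect_equal(mub$n_phases, 2L)
  expect_gte(mub$first_insertion[["combined"]], 450)
  expect_lte(mub$first_insertion[["combined"]], 900)
  lst <- run_phases("dMuB_LST", 213L)
  expect_equal(lst$n_phases, 2L)
  # first insertions near 100 bp, bulk by ~2 kb, each within one window
  expect_lte(lst$first_insertion[["combined"]], 200)
  expect_gte(lst$bulk_reach, 1200)
  expect_lte(lst$bulk_reach, 2800)
})

test_that("per-end first-insertion distances agree across seeds", {
  fx <- fixture_genome(L = 15e4, mu_length = 8000L, seed = 221L)
  lefts <- rights <- numeric(0)
  for (s in 1:20) {
    cfg <- sim_config(fx$genome, list(fx$prophage),
                      immunity = immunity_model("WT_EST"))
    ev <- sample_insertions(cfg, 3e4, seed = 300L + s)
    prof <- distance_profile(ev, fx$prophage, fx$genome$length)
    base <- bulk_baseline(ev, fx$prophage, fx$genome$length)
    ph <- detect_phases(prof, base)
    lefts <- c(lefts, ph$first_insertion[["left"]])
    rights <- c(rights, ph$first_insertion[["right"]])
  }
  # symmetric immunity: per-end means within sampling error of each other
  expect_lt(abs(mean(lefts) - mean(rights)),
            3 * sqrt(var(lefts) / 20 + var(rights) / 20) + 100)
})
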