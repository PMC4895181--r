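test_that("call_regions collapses significant runs with gap tolerance", {
  map <- toy_map(10, spacing = 1e6)
  expect_equal(nrow(call_regions(rep(0.5, 10), map, alpha = 0.05)), 0)
  p <- c(rep(0.01, 5), rep(0.5, 5))
  r <- call_regions(p, map, alpha = 0.05)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end, r$n_snps), c(1e6, 5e6, 5))
  # pattern S S n S: one region with max_gap_snps = 1, two with 0
  p2 <- c(0.01, 0.01, 0.5, 0.01, rep(0.9, 6))
  r1 <- call_regions(p2, map, alpha = 0.05, max_gap_snps = 1)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end, r1$n_snps), c(1e6, 4e6, 3))
  r0 <- call_regions(p2, map, alpha = 0.05, max_gap_snps = 0)
  expect_equal(nrow(r0), 2)
  expect_equal(r0$end, c(2e6, 4e6))
})

test_that("snp_windows builds, clips and merges point windows", {
  w <- snp_windows(1, 10e6, w = 1e6)
  expect_equal(c(w$start, w$end), c(9e6, 11e6))
  # clipped at chromosome bounds
  wc <- snp_windows(1, 0.5e6, w = 1e6, chrom_lengths = 3e6)
  expect_equal(c(wc$start, wc$end), c(1, 1.5e6))
  # two SNPs 0.5 Mb apart merge into one window
  wm <- snp_windows(c(1, 1), c(10e6, 10.5e6), w = 1e6)
  expect_equal(nrow(wm), 1)
  expect_equal(c(wm$start, wm$end), c(9e6, 11.5e6))
  wu <- snp_windows(c(1, 1), c(10e6, 10.5e6), w = 1e6, merge = FALSE)
  expect_equal(nrow(wu), 2)
})

test_that("count_overlaps counts set-2 intervals touching set 1", {
  s1 <- sweep_set(c(1, 2), c(100, 100), c(200, 200))
  s2 <- sweep_set(c(3, 4), c(100, 100), c(200, 200))
  expect_equal(count_overlaps(s1, s2), 0L)
  expect_equal(count_overlaps(s1, s1), 2L)
  # closed-interval touch counts: prior interval 16.6-20.6 Mb vs a +-1 Mb
  # window around an outlier at 20.60 Mb
  prior <- sweep_set(15, 16.6e6, 20.6e6)
  win <- snp_windows(15, 20.6e6, w = 1e6)
  expect_equal(count_overlaps(prior, win), 1L)
  touch <- sweep_set(1, 200, 300)
  expect_equal(count_overlaps(sweep_set(1, 100, 200), touch), 1L)
  expect_error(count_overlaps(s1, s2, chromosomes = 1:3), "unknown chromosome")
})

test_that("merge_sweep_set collapses touching intervals in order", {
  s <- sweep_set(c(1, 1, 1, 2), c(300, 100, 200, 100),
                 c(400, 150, 320, 200))
  m <- merge_sweep_set(s)
  expect_equal(nrow(m), 3)
  expect_equal(m$start, c(100, 200, 100))
  expect_equal(m$end, c(150, 400, 200))
})

test_that("circular permutation matches exhaustive shift enumeration", {
  # toy map of 10 SNPs; set1 occupies SNPs 1-2, set2 SNPs 5-6; of the 10
  # possible shifts exactly 3 give an overlap, so P(count > 0) = 3/10
  map <- toy_map(10, spacing = 100)
  s1 <- sweep_set(1, 100, 200)
  s2 <- sweep_set(1, 500, 600)
  pr <- circular_permutation_test(s1, s2, map, n_perm = 40000, seed = 1)
  expect_equal(pr$observed, 0L)
  se <- sqrt(0.3 * 0.7 / pr$n_perm)
  expect_lt(abs(pr$p_value - 0.3), 4 * se)
  expect_equal(length(pr$counts), 40000)
  # independent exhaustive oracle on a random map/set configuration
  set.seed(42)
  M <- 60
  occ1 <- sort(sample(M, 8))
  map2 <- toy_map(M, spacing = 50)
  s1b <- sweep_set(rep(1, 8), occ1 * 50, occ1 * 50)
  s2b <- sweep_set(c(1, 1), c(10, 40) * 50, c(12, 44) * 50)
  pr2 <- circular_permutation_test(s1b, s2b, map2, n_perm = 30000, seed = 2)
  # oracle: boolean occupancy, all M shifts enumerated
  occ <- rep(FALSE, M)
  occ[occ1] <- TRUE
  idx2 <- list(10:12, 40:44)
  cnt <- vapply(1:M, function(d) {
    sum(vapply(idx2, function(ii) any(occ[(ii + d - 1) %% M + 1]),
               logical(1)))
  }, numeric(1))
  p_exact <- mean(cnt > pr2$observed)
  se2 <- sqrt(p_exact * (1 - p_exact) / pr2$n_perm)
  expect_lt(abs(pr2$p_value - p_exact), 4 * se2 + 1e-12)
})

test_that("overlap counting is invariant to rotating both sets together", {
  map <- toy_map(50, spacing = 100)
  s1 <- sweep_set(c(1, 1), c(500, 2000), c(800, 2400))
  s2 <- sweep_set(c(1, 1), c(700, 3000), c(900, 3100))
  obs0 <- circular_permutation_test(s1, s2, map, n_perm = 1, seed = 1)$observed
  shift_bp <- 10 * 100
  sh <- function(s) sweep_set(s$chrom, s$start + shift_bp, s$end + shift_bp)
  obs1 <- circular_permutation_test(sh(s1), sh(s2), map, n_perm = 1,
                                    seed = 1)$observed
  expect_equal(obs0, obs1)
})

test_that("the bootstrapped P is valid when set 2 is randomly placed", {
  # rotate a fixed interval template to a uniform random offset (the null
  # of the test) and check the resulting P-values are conservative at the
  # nominal level and centred, up to the discreteness of the count
  # a uniformly random placement of set 2 is exactly one null shift, so
  # draw null overlap counts from the test itself and compute each
  # replicate's P against the others
  M <- 240
  map <- toy_map(M, spacing = 100)
  set.seed(77)
  occ1 <- sort(sample(M, 14))
  s1 <- sweep_set(rep(1, 14), occ1 * 100, occ1 * 100)
  st <- c(5, 40, 80, 120, 160, 200)
  s2 <- sweep_set(rep(1, 6), st * 100, (st + 4) * 100)
  counts <- circular_permutation_test(s1, s2, map, n_perm = 2000,
                                      seed = 5)$counts
  # the tie-inclusive rank P is super-uniform (a valid conservative test)
  p_ge <- vapply(1:200, function(r) mean(counts[-r] >= counts[r]),
                 numeric(1))
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p_ge <= t), t + 3 * sqrt(t * (1 - t) / 200) + 0.01)
  }
  # the strict "exceeds" convention can only be smaller, by the tie mass;
  # on maps where counts are spread out the two agree
  p_gt <- vapply(1:200, function(r) mean(counts[-r] > counts[r]),
                 numeric(1))
  expect_true(all(p_gt <= p_ge))
})

test_that("intervals without SNPs are dropped with a warning", {
  map <- toy_map(10, spacing = 1000)
  s1 <- sweep_set(1, 1000, 2000)
  s2 <- sweep_set(c(1, 1), c(100, 5000), c(200, 6000))  # first has no SNP
  expect_warning(pr <- circular_permutation_test(s1, s2, map, n_perm = 10,
                                                 seed = 1), "dropped")
  expect_equal(pr$n_dropped, 1)
})

test_that("permutation count defaults and the plus-one estimator", {
  expect_equal(formals(circular_permutation_test)$n_perm, 10000)
  map <- toy_map(10, spacing = 100)
  s <- sweep_set(1, 100, 200)
  pr <- circular_permutation_test(s, s, map, n_perm = 10, seed = 3,
                                  plus_one = TRUE)
  b <- sum(pr$counts > pr$observed)
  expect_equal(pr$p_value, (b + 1) / 11)
})

test_that("sweep sets round-trip through TSV including BED conversion", {
  s <- sweep_set(c(1, 2), c(100, 5000), c(900, 5100), label = c("a", "b"),
                 source = "test")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_set(s, f)
  back <- read_sweep_set(f)
  expect_equal(back$start, s$start)
  write_sweep_set(s, f, to_bed = TRUE)
  back2 <- read_sweep_set(f, from_bed = TRUE)
  expect_equal(back2$start, s$start)
  expect_equal(back2$end, s$end)
})
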