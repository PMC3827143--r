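test_that("shuffled regions keep their lengths and respect exclusions", {
  set.seed(19)
  regions <- random_intervals(12, 1e6)
  ex <- data.frame(start = c(2e5, 6e5), end = c(3e5, 7e5))
  for (i in 1:20) {
    sh <- shuffle_regions(regions, 1e6, excluded = ex)
    expect_equal(sh$end - sh$start, regions$end - regions$start)
    expect_true(all(sh$start >= 0 & sh$end <= 1e6))
    for (g in 1:2)
      expect_true(all(pmax(0, pmin(sh$end, ex$end[g]) -
                             pmax(sh$start, ex$start[g])) == 0))
  }
  # same seed reproduces the same placement
  s1 <- shuffle_regions(regions, 1e6, excluded = ex, seed = 5)
  s2 <- shuffle_regions(regions, 1e6, excluded = ex, seed = 5)
  expect_equal(s1, s2)
})

test_that("a region is placed uniformly over admissible starts", {
  set.seed(20)
  one <- data.frame(start = 0, end = 5000)
  draws <- replicate(2000, shuffle_regions(one, 1e5)$start)
  # start ~ Uniform{0 .. L - len}
  ks <- suppressWarnings(ks.test(draws / (1e5 - 5000), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("forced placement puts a region in the only admissible slot", {
  one <- data.frame(start = 0, end = 1000)
  ex <- data.frame(start = c(0, 41000), end = c(40000, 1e5))
  sh <- shuffle_regions(one, 1e5, excluded = ex)
  expect_equal(c(sh$start, sh$end), c(40000, 41000))
  # region longer than any allowed stretch
  big <- data.frame(start = 0, end = 2000)
  expect_error(shuffle_regions(big, 1e5, excluded = ex), "cannot place")
})

test_that("overlap statistics match the quadratic all-pairs oracle", {
  a <- data.frame(start = c(0, 100), end = c(50, 150))
  b <- data.frame(start = 200, end = 300)
  for (m in c("region_hits", "feature_hits", "bp"))
    expect_equal(overlap_statistic(a, b, m), 0)
  expect_equal(overlap_statistic(a, a, "region_hits"), 2)
  expect_equal(overlap_statistic(a, a, "bp"), 100)
  set.seed(21)
  for (i in 1:15) {
    r <- random_intervals(sample(3:12, 1), 5e4, 100, 3000)
    f <- random_intervals(sample(3:12, 1), 5e4, 100, 3000)
    for (m in c("region_hits", "feature_hits", "bp"))
      expect_equal(overlap_statistic(r, f, m), quad_overlap(r, f, m))
    expect_equal(overlap_statistic(r, f, "bp"), overlap_statistic(f, r, "bp"))
  }
  expect_error(overlap_statistic(a, b, "banana"), "arg")
})

test_that("permutation enrichment is maximal for planted features and reproducible", {
  set.seed(22)
  regions <- data.frame(start = c(1e4, 5e4, 9e4), end = c(2e4, 6e4, 1e5))
  feats <- data.frame(start = regions$start + 2000, end = regions$start + 4000)
  res <- permutation_enrichment(regions, feats, chrom_length = 1e6, N = 199,
                                seed = 7)
  expect_equal(res$p_empirical, 1 / 200)
  expect_gt(res$p_empirical, 0)  # plus-one smoothing: never zero
  res2 <- permutation_enrichment(regions, feats, chrom_length = 1e6, N = 199,
                                 seed = 7)
  expect_equal(res$null_draws, res2$null_draws)
  expect_error(permutation_enrichment(regions, feats, 1e6, N = 50), "at least 100")
})

test_that("gene density counts genes over the union length", {
  regions <- data.frame(start = 0, end = 1e5)
  genes <- data.frame(start = c(1e4, 5e4), end = c(1.2e4, 5.5e4))
  expect_equal(gene_density(regions, genes), 2 / 100)
  # duplicated regions collapse to the same union
  expect_equal(gene_density(rbind(regions, regions), genes), 2 / 100)
  # hand-counted random fixture
  set.seed(23)
  r <- random_intervals(10, 2e5, 2000, 8000)
  g <- random_intervals(20, 2e5, 500, 1500)
  u <- fourcbricks:::.reduce_intervals(r$start, r$end)
  hand_hits <- 0
  for (j in seq_len(nrow(g))) {
    hit <- FALSE
    for (k in seq_along(u$start))
      if (min(g$end[j], u$end[k]) > max(g$start[j], u$start[k])) hit <- TRUE
    hand_hits <- hand_hits + hit
  }
  expect_equal(gene_density(r, g), hand_hits / (sum(u$end - u$start) / 1000))
  expect_error(gene_density(r[0, ], g), "empty")
})

test_that("coverage matrix reports per-viewpoint and pairwise coverage", {
  a <- data.frame(start = c(0, 2e4), end = c(1e4, 3e4))      # 20 kb
  b <- data.frame(start = 5e4, end = 6e4)                    # 10 kb, disjoint
  nested <- data.frame(start = 2e3, end = 8e3)               # inside a
  m <- coverage_matrix(list(A = a, B = b, C = nested), 1e5)
  expect_equal(diag(m), c(A = 20, B = 10, C = 6))
  expect_equal(m["A", "B"], 0)
  expect_equal(m["A", "C"], 6)  # nested: intersection = smaller coverage
  expect_equal(m, t(m))
  m2 <- coverage_matrix(list(A = a, B = a), 1e5)
  expect_equal(m2["A", "B"], m2["A", "A"])
  expect_error(coverage_matrix(list(A = a), 1e5), "at least 2")
})
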