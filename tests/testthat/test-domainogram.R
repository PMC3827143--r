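test_that("rank transform handles order, ties and missing fragments", {
  n <- 10
  expect_equal(rank_transform(seq_len(n)), seq_len(n) / n)
  expect_equal(rank_transform(rep(2.5, n)), rep((n + 1) / (2 * n), n))
  set.seed(12)
  x <- rnorm(50)
  expect_equal(rank_transform(x), order(order(x)) / 50)  # argsort oracle
  x[c(3, 7)] <- NA
  u <- rank_transform(x)
  expect_true(all(is.na(u[c(3, 7)])))
  expect_equal(sort(u[-c(3, 7)]), seq_len(48) / 48)
  expect_error(rank_transform(c(NA, NA, 1)), "at least 2")
})

test_that("window p-values match closed forms and exhaustive enumeration", {
  # w = 1, top rank, at chromosome scale: the iid-uniform limit
  # z = sqrt(12)*0.5 = 1.73, p ~ 0.0416
  n <- 2000
  sc1 <- window_pvalues(seq_len(n) / n, wmax = 1)
  expect_equal(sc1$p_value[n], pnorm(sqrt(3), lower.tail = FALSE),
               tolerance = 1e-2)
  expect_equal(sc1$p_value[n], 0.0416, tolerance = 1e-2)
  # a window at mean rank 1/2 has p ~ 1/2 (exactly 1/2 in the limit)
  u_big <- rank_transform(rnorm(n))
  scf <- window_pvalues(u_big, wmax = 19)
  w19 <- scf[scf$window_w == 19, ]
  i_mid <- which.min(abs(w19$mean_rank - 0.5))
  expect_equal(w19$p_value[i_mid], 0.5, tolerance = 2e-2)
  # n = 7, w = 3: within 0.05 of the exhaustively enumerated tail
  # (mid-p convention: the exact tail is a step function with atoms up to
  # 0.14, so this is the comparison a continuous approximation can meet)
  u <- rank_transform(c(3, 1, 7, 2, 6, 4, 5))
  sc <- window_pvalues(u, wmax = 3)
  w3 <- sc[sc$window_w == 3, ]
  for (i in seq_len(nrow(w3))) {
    exact <- exact_window_tail(7, 3, w3$mean_rank[i], mid = TRUE)
    expect_lt(abs(w3$p_value[i] - exact), 0.05)
  }
})

test_that("window p-values are monotone in mean rank and skip missing windows", {
  set.seed(13)
  u <- rank_transform(rnorm(60))
  sc <- window_pvalues(u, wmax = 10)
  expect_equal(nrow(sc), sum(60 - seq_len(10) + 1))
  for (w in c(3, 10)) {
    s <- sc[sc$window_w == w, ]
    o <- order(s$mean_rank)
    expect_true(all(diff(s$p_value[o]) <= 1e-15))
  }
  u[30] <- NA
  sc2 <- window_pvalues(u, wmax = 10)
  hits30 <- sc2$start_frag <= 30 & sc2$start_frag + sc2$window_w - 1 >= 30
  expect_false(any(hits30))
})

test_that("a planted block of top ranks yields exactly one covering Brick", {
  fmap <- make_fmap(1000, 4000)
  srw <- short_range_window("chrT", 0, 4e6)
  set.seed(14)
  hits <- replicate(20, {
    vals <- rnorm(1000)
    p0 <- sample(100:880, 1)
    vals[p0:(p0 + 19)] <- max(vals) + runif(20, 1, 2)  # top-ranked block
    sc <- window_pvalues(rank_transform(vals), wmax = 200)
    b <- call_bricks(sc, fmap, fdr_short = 0.1, srw = srw)
    sum(b$end_frag >= p0 & b$start_frag <= p0 + 19)
  })
  expect_gte(mean(hits == 1), 0.95)
})

test_that("called Bricks are disjoint and invariant to signal shifts", {
  set.seed(15)
  fmap <- make_fmap(400, 4000)
  srw <- short_range_window("chrT", 0, 1.6e6)
  vals <- rnorm(400)
  vals[100:119] <- vals[100:119] + 10
  sc <- window_pvalues(rank_transform(vals), wmax = 50)
  b <- call_bricks(sc, fmap, srw = srw)
  expect_gt(nrow(b), 0)
  if (nrow(b) > 1) {
    o <- order(b$start_frag)
    expect_true(all(b$start_frag[o][-1] > b$end_frag[o][-nrow(b)]))
  }
  # adding a constant leaves ranks, hence Bricks, unchanged
  sc2 <- window_pvalues(rank_transform(vals + 42), wmax = 50)
  b2 <- call_bricks(sc2, fmap, srw = srw)
  expect_equal(b2, b)
})

test_that("tier assignment sends border-straddling windows to the long tier", {
  fmap <- make_fmap(100, 1000)
  # short-range window covers fragments 1..50 exactly
  srw <- short_range_window("chrT", 0, 5e4)
  u <- rank_transform(seq_len(100))  # increasing: top ranks at the right end
  sc <- window_pvalues(u, wmax = 20)
  b <- call_bricks(sc, fmap, fdr_short = 0.1, fdr_long = 0.1, srw = srw)
  straddle <- b$start < 5e4 & b$end > 5e4
  expect_true(all(b$tier[straddle] == "long_range"))
  inside <- b$end <= 5e4
  expect_true(all(b$tier[inside] == "short_range"))
})

test_that("empty significant sets give empty Brick sets", {
  fmap <- make_fmap(50, 1000)
  u <- rank_transform(rep(c(0.4, 0.6), 25))
  sc <- window_pvalues(u, wmax = 10)
  b <- call_bricks(sc, fmap, fdr_short = 1e-6, fdr_long = 1e-9)
  expect_equal(nrow(b), 0)
  expect_equal(nrow(merge_bricks(b)), 0)
})

test_that("merging consecutive Bricks is correct and idempotent", {
  mk <- function(sf, ef, p = 0.001) {
    data.frame(chrom = "chrT", start = (sf - 1) * 1000, end = ef * 1000,
               start_frag = sf, end_frag = ef, window_w = ef - sf + 1L,
               p_value = p, tier = "short_range", sign = "positive",
               stringsAsFactors = FALSE)
  }
  # adjacent Bricks merge into one region
  b <- rbind(mk(1, 5, 0.01), mk(6, 9, 0.002))
  r <- merge_bricks(b)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start_frag, r$end_frag, r$n_bricks), c(1, 9, 2))
  expect_equal(r$summary_p, 0.002)
  # separated by more than merge_gap: unchanged
  b2 <- rbind(mk(1, 5), mk(10, 12))
  expect_equal(nrow(merge_bricks(b2, merge_gap = 1)), 2)
  expect_equal(nrow(merge_bricks(b2, merge_gap = 5)), 1)
  # idempotence on random disjoint sets
  set.seed(16)
  for (i in 1:5) {
    sf <- sort(sample(seq(1, 300, by = 4), 30))
    b3 <- do.call(rbind, lapply(sf, function(s) mk(s, s + sample(0:2, 1))))
    r1 <- merge_bricks(b3)
    r2 <- merge_bricks(r1[, c("chrom", "start", "end", "start_frag",
                              "end_frag", "n_bricks", "summary_p")] |>
                         transform(p_value = summary_p, sign = "positive"),
                       merge_gap = 1)
    expect_equal(r2$start_frag, r1$start_frag)
    expect_equal(r2$end_frag, r1$end_frag)
  }
  # overlapping input is rejected
  expect_error(merge_bricks(rbind(mk(1, 5), mk(4, 8))), "overlap")
})
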