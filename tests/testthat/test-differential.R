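test_that("log2 ratio is zero for identical tracks and antisymmetric", {
  fmap <- make_fmap(50, 1000)
  set.seed(17)
  a <- make_signal(fmap, rlnorm(50, 3, 0.5))
  b <- make_signal(fmap, rlnorm(50, 3, 0.5))
  expect_equal(log2_ratio(a, a)$values, rep(0, 50))
  # two-fold decrease with values >> eps gives r ~ -1
  half <- a
  half$values <- a$values / 2
  r <- log2_ratio(half, a, eps = 1e-9)
  expect_equal(r$values, rep(-1, 50), tolerance = 1e-6)
  # swap(case, ctrl) negates the track
  r_ab <- log2_ratio(a, b)
  r_ba <- log2_ratio(b, a)
  expect_equal(r_ab$values, -r_ba$values)
  expect_error(log2_ratio(a, b, eps = 0), "eps")
  expect_error(log2_ratio(a, b, eps = -1), "eps")
})

test_that("a zero ratio track yields empty positive and negative sets", {
  fmap <- make_fmap(300, 4000)
  a <- make_signal(fmap, rep(100, 300))
  rt <- log2_ratio(a, a)
  nob <- data.frame(start = numeric(0), end = numeric(0))
  rb <- ratio_bricks(rt, nob, nob, gaps = nob, wmax = 50)
  expect_equal(nrow(rb$positive), 0)
  expect_equal(nrow(rb$negative), 0)
})

test_that("planted signed blocks are recovered as correctly signed ratio Bricks", {
  hits <- sapply(1:10, function(s) {
    fx <- make_ratio_fixture(s)
    nob <- data.frame(start = numeric(0), end = numeric(0))
    rb <- ratio_bricks(fx$ratio, fx$anchors, nob, gaps = nob, wmax = 100)
    neg_span <- c(fx$fmap$start[fx$neg0], fx$fmap$end[fx$neg0 + 29])
    pos_span <- c(fx$fmap$start[fx$pos0], fx$fmap$end[fx$pos0 + 29])
    c(any(rb$negative$end > neg_span[1] & rb$negative$start < neg_span[2]),
      any(rb$positive$end > pos_span[1] & rb$positive$start < pos_span[2]))
  })
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("ratio Brick sets obey their structural invariants", {
  for (s in 11:16) {
    fx <- make_ratio_fixture(s)
    gaps <- data.frame(start = fx$fmap$start[c(100, 400)],
                       end = fx$fmap$start[c(100, 400)] + 6000)
    rb <- ratio_bricks(fx$ratio, fx$anchors, fx$anchors[1, , drop = FALSE],
                       gaps = gaps, wmax = 100)
    both <- rbind(rb$positive, rb$negative)
    if (nrow(rb$positive) > 0 && nrow(rb$negative) > 0) {
      for (i in seq_len(nrow(rb$positive))) {
        ov <- pmax(0, pmin(rb$positive$end[i], rb$negative$end) -
                      pmax(rb$positive$start[i], rb$negative$start))
        shorter <- pmin(rb$positive$end[i] - rb$positive$start[i],
                        rb$negative$end - rb$negative$start)
        expect_true(all(ov / shorter <= 0.05))
      }
    }
    if (nrow(both) > 0) {
      # no Brick intersects a genome gap
      for (g in seq_len(nrow(gaps))) {
        ov <- pmax(0, pmin(both$end, gaps$end[g]) -
                      pmax(both$start, gaps$start[g]))
        expect_true(all(ov == 0))
      }
      # every Brick is anchored in a condition Brick
      anch <- rbind(fx$anchors, fx$anchors[1, ])
      for (i in seq_len(nrow(both))) {
        ov <- pmax(0, pmin(both$end[i], anch$end) - pmax(both$start[i], anch$start))
        expect_true(any(ov > 0))
      }
    }
  }
})

test_that("swapping conditions maps positive and negative sets onto each other", {
  fx <- make_ratio_fixture(21)
  nob <- data.frame(start = numeric(0), end = numeric(0))
  rt_swap <- log2_ratio(fx$ctrl, fx$case)
  rb <- ratio_bricks(fx$ratio, fx$anchors, nob, gaps = nob, wmax = 100)
  rb_swap <- ratio_bricks(rt_swap, nob, fx$anchors, gaps = nob, wmax = 100)
  expect_equal(rb$positive[, c("start", "end")],
               rb_swap$negative[, c("start", "end")])
  expect_equal(rb$negative[, c("start", "end")],
               rb_swap$positive[, c("start", "end")])
})

test_that("gap subtraction splits Bricks that span a gap", {
  fx <- make_ratio_fixture(31)
  nob <- data.frame(start = numeric(0), end = numeric(0))
  # place a gap right through the middle of the planted negative block
  mid <- fx$fmap$start[fx$neg0 + 15]
  gaps <- data.frame(start = mid, end = mid + 4000)
  rb <- ratio_bricks(fx$ratio, fx$anchors, nob, gaps = gaps, wmax = 100)
  left <- rb$negative$end <= mid
  right <- rb$negative$start >= mid + 4000
  expect_true(any(left) && any(right))
  expect_true(all(left | right))
})

test_that("missing gap input skips gap removal with a warning", {
  fx <- make_ratio_fixture(41)
  nob <- data.frame(start = numeric(0), end = numeric(0))
  expect_warning(ratio_bricks(fx$ratio, fx$anchors, nob, wmax = 50),
                 "gap removal skipped")
})

test_that("rank-sum test matches exact split enumeration (nA + nB <= 12)", {
  # worked example: maximally separated triples, p = 2/20
  expect_equal(rank_sum_test(c(10, 11, 12), c(1, 2, 3))$p_value, 0.1)
  expect_equal(exact_wilcox_p(c(10, 11, 12), c(1, 2, 3)), 0.1)
  set.seed(18)
  for (na in 2:5) {
    for (nb in seq(2, 12 - na)) {
      a <- rnorm(na)
      b <- rnorm(nb, 0.5)
      expect_equal(rank_sum_test(a, b)$p_value, exact_wilcox_p(a, b),
                   tolerance = 1e-12)
    }
  }
  # identical multisets: p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_warning(res <- rank_sum_test(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(res$p_value, 1)
})

test_that("region count test separates high-count regions from outside Bricks", {
  fmap <- make_fmap(60, 1000)
  vp <- make_vp(fmap, 1, exclusion_k = 0L)
  counts <- rep(1, 60)
  # three Bricks with high counts (regions), three with low counts (outside)
  bricks <- data.frame(chrom = "chrT",
                       start = fmap$start[c(5, 15, 25, 35, 45, 55)],
                       end = fmap$end[c(7, 17, 27, 37, 47, 57)],
                       start_frag = c(5, 15, 25, 35, 45, 55),
                       end_frag = c(7, 17, 27, 37, 47, 57))
  counts[c(5:7, 15:17, 25:27)] <- c(400, 30, 30, 500, 40, 40, 600, 50, 50)
  counts[c(35, 45, 55)] <- c(2, 3, 4)  # distinct low-count outside Bricks
  ctrl <- count_track(fmap, vp, counts)
  case <- count_track(fmap, vp, counts)
  regions <- data.frame(start = bricks$start[1:3], end = bricks$end[1:3])
  res <- region_count_test(ctrl, case, regions, bricks)
  expect_equal(res$n_regions, 3)
  expect_equal(res$n_outside_bricks, 3)
  expect_equal(res$p_value, 0.1)  # most extreme 3-vs-3 split
})

test_that("interval change summary gives the median and a bootstrap CI", {
  fmap <- make_fmap(100, 1000)
  a <- make_signal(fmap, rep(200, 100))
  b <- a
  b$values <- a$values / 2
  rt <- log2_ratio(b, a, eps = 1e-9)
  ics <- interval_change_summary(rt, c(20000, 50000), n_boot = 200, seed = 3)
  expect_equal(ics$median, -1, tolerance = 1e-6)
  expect_equal(ics$ci_low, ics$ci_high, tolerance = 1e-9)  # constant track
  # unchanged interval: median ~ 0
  rt0 <- log2_ratio(a, a)
  expect_equal(interval_change_summary(rt0, c(20000, 50000),
                                       n_boot = 50)$median, 0)
  expect_error(interval_change_summary(rt, c(0, 3000)), "fewer than 5")
})
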