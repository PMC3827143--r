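# Shared fixture builders (generated in code; no stored data).

# uniform fragment map: n fragments of equal length
make_fmap <- function(n, len = 4000, chrom = "chrT") {
  fragment_map(chrom, (seq_len(n) - 1) * len, seq_len(n) * len)
}

# viewpoint in the middle of fragment `frag`
make_vp <- function(fmap, frag, exclusion_k = 2L, name = "VPt") {
  viewpoint_spec(name, fmap$chrom, (fmap$start[frag] + fmap$end[frag]) / 2,
                 exclusion_k = exclusion_k)
}

make_signal <- function(fmap, values, stage = "corrected", vp = NULL,
                        condition = "control") {
  if (is.null(vp)) vp <- make_vp(fmap, 1, exclusion_k = 0L)
  signal_track(fmap, vp, values, stage = stage, condition = condition)
}

# ratio-track fixture: one strongly negative and one strongly positive
# 30-fragment block over mild noise, with condition Bricks anchoring both
make_ratio_fixture <- function(seed, n = 600) {
  set.seed(seed)
  fmap <- make_fmap(n, 4000)
  base <- rlnorm(n, 5, 0.15)
  delta <- rnorm(n, 0, 0.1)
  neg0 <- sample(50:(n / 2 - 60), 1)
  pos0 <- sample((n / 2):(n - 60), 1)
  delta[neg0:(neg0 + 29)] <- -1.5
  delta[pos0:(pos0 + 29)] <- 1.5
  ctrl <- make_signal(fmap, base)
  case <- make_signal(fmap, base * 2^delta)
  anchors <- data.frame(
    start = fmap$start[c(neg0, pos0)] - 8000,
    end = fmap$end[c(neg0 + 29, pos0 + 29)] + 8000
  )
  list(fmap = fmap, ctrl = ctrl, case = case, neg0 = neg0, pos0 = pos0,
       anchors = anchors, ratio = log2_ratio(case, ctrl))
}

# random disjoint interval set on [0, L)
random_intervals <- function(n, L, min_len = 500, max_len = 5000) {
  starts <- sort(sample.int(L - max_len, n))
  lens <- sample(min_len:max_len, n, replace = TRUE)
  ends <- pmin(starts + lens, c(starts[-1], L))
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}
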