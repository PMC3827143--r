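# Independent brute-force oracles. These deliberately avoid the code paths
# they check: plain loops and enumeration only.

# boundaries of a digestion by naive substring scan (0-based cut positions)
naive_digest <- function(seq, motif = "AGATCT") {
  L <- nchar(seq)
  m <- nchar(motif)
  cuts <- integer(0)
  for (i in seq_len(L - m + 1)) {
    if (substr(seq, i, i + m - 1) == motif) cuts <- c(cuts, i - 1)
  }
  bounds <- sort(unique(c(0, cuts, L)))
  keep <- diff(bounds) > 0
  list(start = bounds[-length(bounds)][keep], end = bounds[-1][keep])
}

# O(n*w) running mean with shrinking symmetric windows
naive_running_mean <- function(x, w) {
  n <- length(x)
  k <- (w - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(k, i - 1, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

# exact upper-tail probability of the mean of w ranks drawn without
# replacement from (1..n)/n, by exhaustive enumeration of all subsets;
# mid-p (half weight on the observed atom) is the continuity-matched tail
# that a continuous approximation should be compared against
exact_window_tail <- function(n, w, m, tol = 1e-12, mid = FALSE) {
  sets <- utils::combn(n, w)
  means <- colMeans(sets) / n
  if (mid) mean(means > m + tol) + mean(abs(means - m) < tol) / 2
  else mean(means >= m - tol)
}

# exact two-sided rank-sum p-value by enumeration of all splits of the
# pooled sample (average ranks for ties)
exact_wilcox_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  splits <- utils::combn(length(pooled), na)
  sums <- apply(splits, 2, function(idx) sum(r[idx]))
  p_lo <- mean(sums <= obs + 1e-12)
  p_hi <- mean(sums >= obs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}

# quadratic all-pairs interval overlap statistics (0-based half-open)
quad_overlap <- function(regions, features, mode) {
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  if (mode == "region_hits") {
    hits <- 0
    for (i in seq_len(nrow(regions))) {
      any_hit <- FALSE
      for (j in seq_len(nrow(features)))
        if (ov(regions$start[i], regions$end[i],
               features$start[j], features$end[j]) > 0) any_hit <- TRUE
      hits <- hits + any_hit
    }
    return(hits)
  }
  if (mode == "feature_hits") return(quad_overlap(features, regions, "region_hits"))
  # bp: total intersection of the two unions, by per-base sweep
  L <- max(regions$end, features$end)
  cov_r <- logical(L)
  cov_f <- logical(L)
  for (i in seq_len(nrow(regions)))
    cov_r[(regions$start[i] + 1):regions$end[i]] <- TRUE
  for (j in seq_len(nrow(features)))
    cov_f[(features$start[j] + 1):features$end[j]] <- TRUE
  sum(cov_r & cov_f)
}

# per-fragment read counts by brute-force containment
naive_assign <- function(pos, starts, ends) {
  counts <- integer(length(starts))
  for (p in pos) {
    for (i in seq_along(starts)) {
      if (p >= starts[i] && p < ends[i]) {
        counts[i] <- counts[i] + 1L
        break
      }
    }
  }
  counts
}
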