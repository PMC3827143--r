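#' Log2 condition ratio of smoothed, profile-corrected tracks
#'
#' Computes `r_i = log2((max(case_i, 0) + eps) / (max(ctrl_i, 0) + eps))` per
#' fragment. The pseudocount `eps` stabilizes the ratio where the corrected
#' signal is near or below zero; its default is 5% of the pooled median
#' positive corrected signal of the two tracks. The track is antisymmetric
#' under swapping the two conditions.
#'
#' @param case,ctrl Corrected [signal_track]s of equal length (case =
#'   rearranged condition, ctrl = control).
#' @param eps Pseudocount, `> 0`; `NULL` for the default.
#' @return A `ratio_track`: list with `values` (log2 ratios, `NA` where either
#'   input is missing), `pseudocount`, `fmap`, `viewpoint`.
#' @export
log2_ratio <- function(case, ctrl, eps = NULL) {
  stopifnot(inherits(case, "signal_track"), inherits(ctrl, "signal_track"))
  if (length(case$values) != length(ctrl$values))
    stop("case and ctrl tracks must have equal length")
  if (is.null(eps)) {
    pooled <- c(case$values, ctrl$values)
    pos <- pooled[!is.na(pooled) & pooled > 0]
    if (length(pos) == 0) stop("no positive signal to derive a pseudocount from")
    eps <- 0.05 * stats::median(pos)
  }
  if (eps <= 0) stop("pseudocount eps must be > 0")
  r <- log2((pmax(case$values, 0) + eps) / (pmax(ctrl$values, 0) + eps))
  structure(
    list(values = r, pseudocount = eps, fmap = case$fmap,
         viewpoint = case$viewpoint,
         case_condition = case$condition, ctrl_condition = ctrl$condition),
    class = "ratio_track"
  )
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("ratio_track: %s, log2(%s/%s), pseudocount %.4g\n",
              x$viewpoint$name, x$case_condition, x$ctrl_condition,
              x$pseudocount))
  invisible(x)
}

# overlap length between one interval and a set of intervals (bp, half-open)
.overlap_len <- function(s, e, starts, ends) {
  pmax(0, pmin(e, ends) - pmax(s, starts))
}

# subtract a set of (reduced) gap intervals from one [s, e) span; returns a
# matrix with columns start, end of the surviving pieces (possibly none)
.subtract_gaps <- function(s, e, gap_starts, gap_ends) {
  ov <- gap_ends > s & gap_starts < e
  gs <- pmax(gap_starts[ov], s)
  ge <- pmin(gap_ends[ov], e)
  if (length(gs) == 0L) return(cbind(start = s, end = e))
  o <- order(gs)
  gs <- gs[o]; ge <- ge[o]
  starts <- c(s, ge)
  ends <- c(gs, e)
  keep <- ends > starts
  cbind(start = starts[keep], end = ends[keep])
}

#' Call positive and negative ratio Bricks
#'
#' Runs the domainogram Brick caller twice on a log2 ratio track — once as-is
#' (high positive ratios on top: candidate gained interactions) and once on
#' the negated track (high negative ratios on top: candidate lost
#' interactions) — groups consecutive Bricks, then applies three filters:
#' (1) any positive/negative pair overlapping by more than `overlap_threshold`
#' of the shorter member (or reciprocally, see `overlap_mode`) is removed from
#' both sets; (2) genome-gap intervals are subtracted from Brick spans,
#' splitting Bricks that are bisected; (3) Bricks that do not overlap any
#' selected Brick of either input condition are discarded.
#'
#' @param ratio A `ratio_track` from [log2_ratio].
#' @param ctrl_bricks,case_bricks Brick sets called per condition
#'   (data frames with `start`, `end`), used for condition anchoring.
#' @param gaps Optional data frame of genome gap intervals (`start`, `end`);
#'   if `NULL`, gap removal is skipped with a warning.
#' @param wmax,fdr_short,fdr_long,srw,merge_gap Passed to the domainogram
#'   caller ([window_pvalues], [call_bricks], [merge_bricks]).
#' @param overlap_threshold Cross-set overlap fraction above which a
#'   positive/negative pair is removed (default 0.05).
#' @param overlap_mode `"shorter"` (fraction of the shorter member, default)
#'   or `"reciprocal"` (both fractions must exceed the threshold).
#' @return List with `positive` and `negative` Brick data frames (`chrom`,
#'   `start`, `end`, `p_value`, `sign`) and `provenance`, a per-step record of
#'   how many Bricks each filter removed.
#' @export
ratio_bricks <- function(ratio, ctrl_bricks, case_bricks, gaps = NULL,
                         wmax = 200, fdr_short = 0.1, fdr_long = 0.001,
                         srw = NULL, merge_gap = 1,
                         overlap_threshold = 0.05,
                         overlap_mode = c("shorter", "reciprocal")) {
  stopifnot(inherits(ratio, "ratio_track"))
  overlap_mode <- match.arg(overlap_mode)
  fmap <- ratio$fmap

  call_one <- function(values, sgn) {
    u <- rank_transform(values)
    sc <- window_pvalues(u, wmax = wmax)
    b <- call_bricks(sc, fmap, fdr_short = fdr_short, fdr_long = fdr_long,
                     srw = srw, sign = sgn)
    reg <- merge_bricks(b, merge_gap = merge_gap)
    data.frame(chrom = as.character(reg$chrom), start = reg$start,
               end = reg$end, p_value = reg$summary_p,
               sign = rep_len(sgn, nrow(reg)), stringsAsFactors = FALSE)
  }
  pos <- call_one(ratio$values, "positive")
  neg <- call_one(-ratio$values, "negative")
  prov <- list(candidates = c(positive = nrow(pos), negative = nrow(neg)))

  # step 2: drop pos/neg pairs with cross-set overlap > threshold
  if (nrow(pos) > 0L && nrow(neg) > 0L) {
    drop_pos <- logical(nrow(pos)); drop_neg <- logical(nrow(neg))
    for (i in seq_len(nrow(pos))) {
      ov <- .overlap_len(pos$start[i], pos$end[i], neg$start, neg$end)
      lp <- pos$end[i] - pos$start[i]
      ln <- neg$end - neg$start
      frac <- switch(overlap_mode,
                     shorter = ov / pmin(lp, ln),
                     reciprocal = pmin(ov / lp, ov / ln))
      hit <- frac > overlap_threshold
      if (any(hit)) { drop_pos[i] <- TRUE; drop_neg[hit] <- TRUE }
    }
    prov$removed_shared <- c(positive = sum(drop_pos), negative = sum(drop_neg))
    pos <- pos[!drop_pos, , drop = FALSE]
    neg <- neg[!drop_neg, , drop = FALSE]
  } else {
    prov$removed_shared <- c(positive = 0L, negative = 0L)
  }

  # step 3: subtract genome gaps, splitting bisected Bricks
  trim_gaps <- function(b) {
    if (nrow(b) == 0L) return(b)
    gr <- .reduce_intervals(gaps$start, gaps$end)
    pieces <- lapply(seq_len(nrow(b)), function(i) {
      m <- .subtract_gaps(b$start[i], b$end[i], gr$start, gr$end)
      if (nrow(m) == 0L) return(NULL)
      data.frame(chrom = b$chrom[i], start = m[, "start"], end = m[, "end"],
                 p_value = b$p_value[i], sign = b$sign[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    if (is.null(out))
      out <- b[0, , drop = FALSE]
    out
  }
  if (is.null(gaps)) {
    warning("no genome-gap intervals supplied; gap removal skipped")
    prov$gap_trimmed <- FALSE
  } else {
    pos <- trim_gaps(pos)
    neg <- trim_gaps(neg)
    prov$gap_trimmed <- TRUE
  }

  # step 4: keep only Bricks anchored in a selected Brick of either condition
  anchors <- rbind(
    if (nrow(ctrl_bricks) > 0L) ctrl_bricks[, c("start", "end")],
    if (nrow(case_bricks) > 0L) case_bricks[, c("start", "end")]
  )
  anchor_one <- function(b) {
    if (nrow(b) == 0L) return(b)
    if (is.null(anchors) || nrow(anchors) == 0L) return(b[0, , drop = FALSE])
    hit <- vapply(seq_len(nrow(b)), function(i) {
      any(.overlap_len(b$start[i], b$end[i], anchors$start, anchors$end) > 0)
    }, logical(1))
    b[hit, , drop = FALSE]
  }
  n_before <- c(positive = nrow(pos), negative = nrow(neg))
  pos <- anchor_one(pos)
  neg <- anchor_one(neg)
  prov$removed_unanchored <- n_before - c(positive = nrow(pos), negative = nrow(neg))

  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg, provenance = prov)
}

#' Two-sample rank-sum test helper
#'
#' Two-sided Wilcoxon rank-sum test with tie correction; the exact null
#' distribution is used when `min(nA, nB) <= 10` and there are no ties,
#' the normal approximation (with continuity and tie correction) otherwise.
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` (rank-sum W of `a`), `p_value`, `n_a`, `n_b`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("all observations tied; p = 1")
    return(list(statistic = NA_real_, p_value = 1,
                n_a = length(a), n_b = length(b)))
  }
  ties <- any(duplicated(c(a, b)))
  use_exact <- min(length(a), length(b)) <= 10 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(a), n_b = length(b))
}

#' Read-count validation of ratio regions
#'
#' Quantifies raw reads (control + case) inside each Brick, averages the
#' per-Brick `log(count + 1)` over the member Bricks of each ratio region, and
#' compares that distribution against the same quantity for Bricks outside
#' all ratio regions, with a two-sided Wilcoxon rank-sum test. A small p-value
#' indicates the selected ratio regions carry significantly different read
#' mass than ordinary Bricks.
#'
#' @param ctrl_track,case_track [count_track]s on the same fragment map.
#' @param ratio_regions Data frame of ratio regions (`start`, `end` in bp).
#' @param all_bricks Data frame of condition Bricks (`start`, `end`,
#'   `start_frag`, `end_frag`).
#' @return List: `statistic`, `p_value`, `n_regions`, `n_outside_bricks`.
#' @export
region_count_test <- function(ctrl_track, case_track, ratio_regions, all_bricks) {
  stopifnot(inherits(ctrl_track, "count_track"),
            inherits(case_track, "count_track"))
  if (nrow(ratio_regions) < 1L || nrow(all_bricks) < 1L)
    stop("need at least one ratio region and one Brick")
  total <- ctrl_track$counts + case_track$counts
  cs <- c(0, cumsum(total))
  brick_counts <- cs[all_bricks$end_frag + 1L] - cs[all_bricks$start_frag]
  in_region <- vapply(seq_len(nrow(all_bricks)), function(i) {
    any(.overlap_len(all_bricks$start[i], all_bricks$end[i],
                     ratio_regions$start, ratio_regions$end) > 0)
  }, logical(1))
  a <- vapply(seq_len(nrow(ratio_regions)), function(r) {
    memb <- .overlap_len(ratio_regions$start[r], ratio_regions$end[r],
                         all_bricks$start, all_bricks$end) > 0
    mean(log(brick_counts[memb] + 1))
  }, numeric(1))
  a <- a[!is.na(a)]
  b <- log(brick_counts[!in_region] + 1)
  if (length(a) < 1L || length(b) < 1L)
    stop("need at least one region with member Bricks and one outside Brick")
  res <- rank_sum_test(a, b)
  list(statistic = res$statistic, p_value = res$p_value,
       n_regions = res$n_a, n_outside_bricks = res$n_b)
}

#' Median interaction change within a genomic interval
#'
#' Median of the per-fragment log2 ratios over all fragments overlapping the
#' interval, with a 95% percentile-bootstrap confidence interval obtained by
#' resampling fragments.
#'
#' @param ratio A `ratio_track`.
#' @param interval Length-2 numeric, interval bounds in bp (half-open).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return List: `median`, `ci_low`, `ci_high`, `n_fragments`.
#' @export
interval_change_summary <- function(ratio, interval, n_boot = 1000,
                                    conf = 0.95, seed = NULL) {
  stopifnot(inherits(ratio, "ratio_track"))
  fmap <- ratio$fmap
  inside <- fmap$end > interval[1] & fmap$start < interval[2]
  r <- ratio$values[inside]
  r <- r[!is.na(r)]
  if (length(r) < 5)
    stop("interval overlaps fewer than 5 usable fragments")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(r, length(r), replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  list(median = stats::median(r), ci_low = ci[1], ci_high = ci[2],
       n_fragments = length(r))
}
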