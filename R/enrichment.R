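#' @importFrom IRanges IRanges countOverlaps reduce start end width
NULL

# intervals (0-based half-open numeric vectors) -> IRanges (1-based closed)
.to_iranges <- function(starts, ends) {
  IRanges::IRanges(start = as.integer(starts) + 1L, end = as.integer(ends))
}

# union of intervals; returns list(start, end) in 0-based half-open coords
.reduce_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(list(start = numeric(), end = numeric()))
  r <- IRanges::reduce(.to_iranges(starts, ends))
  list(start = IRanges::start(r) - 1, end = IRanges::end(r))
}

.check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("start", "end") %in% names(x)))
    stop(sprintf("%s must be a data frame with start and end columns", what))
  if (nrow(x) > 0 && any(x$end <= x$start))
    stop(sprintf("%s must have end > start", what))
  invisible(x)
}

#' Genomic feature set
#'
#' Light wrapper building a sorted interval data frame for enrichment and gap
#' masking. Intervals are 0-based half-open and may overlap each other.
#'
#' @param chrom Chromosome name (recycled).
#' @param start,end Interval coordinates.
#' @param name Label for the set.
#' @param kind One of `"genes"`, `"marks"`, `"regulatory"`, `"gaps"`.
#' @export
feature_set <- function(chrom, start, end, name = "features", kind = "genes") {
  kind <- match.arg(kind, c("genes", "marks", "regulatory", "gaps"))
  out <- data.frame(chrom = chrom, start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  .check_intervals(out, name)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_name") <- name
  attr(out, "kind") <- kind
  out
}

#' Shuffle regions uniformly outside excluded intervals
#'
#' Each region is independently placed uniformly at random on its chromosome,
#' outside the excluded (gap) intervals, with its length preserved; shuffled
#' regions may overlap each other. Placement is exact-uniform over all
#' admissible start positions (each maximal allowed stretch is weighted by
#' the number of starts it can host), so no rejection sampling is needed.
#'
#' @param regions Data frame with `start`, `end` (single chromosome).
#' @param chrom_length Chromosome length in bp.
#' @param excluded Optional data frame of excluded intervals (`start`, `end`).
#' @param seed Optional integer seed.
#' @return Data frame of shuffled regions, same lengths, same order.
#' @export
shuffle_regions <- function(regions, chrom_length, excluded = NULL, seed = NULL) {
  .check_intervals(regions, "regions")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(excluded) || nrow(excluded) == 0L) {
    gap_s <- 0
    gap_e <- chrom_length
  } else {
    ex <- .reduce_intervals(pmax(excluded$start, 0),
                            pmin(excluded$end, chrom_length))
    gap_s <- c(0, ex$end)
    gap_e <- c(ex$start, chrom_length)
    ok <- gap_e > gap_s
    gap_s <- gap_s[ok]
    gap_e <- gap_e[ok]
  }
  if (length(gap_s) == 0L)
    stop("excluded intervals cover the whole chromosome")
  lens <- regions$end - regions$start
  new_start <- vapply(lens, function(len) {
    slots <- gap_e - gap_s - len + 1
    slots[slots < 0] <- 0
    if (sum(slots) <= 0)
      stop("region longer than any allowed stretch; cannot place")
    g <- sample.int(length(gap_s), 1L, prob = slots)
    gap_s[g] + sample.int(slots[g], 1L) - 1
  }, numeric(1))
  out <- regions
  out$start <- new_start
  out$end <- new_start + lens
  out
}

#' Overlap statistic between two interval sets
#'
#' `region_hits` counts regions overlapping at least one feature,
#' `feature_hits` counts features overlapping at least one region, and `bp`
#' is the total intersection length of the two interval unions (symmetric).
#' Overlap requires at least 1 bp in common (half-open coordinates).
#'
#' @param regions,features Data frames with `start`, `end` (one chromosome).
#' @param mode `"region_hits"` (default), `"feature_hits"` or `"bp"`.
#' @return A non-negative number.
#' @export
overlap_statistic <- function(regions, features,
                              mode = c("region_hits", "feature_hits", "bp")) {
  mode <- match.arg(mode)
  .check_intervals(regions, "regions")
  .check_intervals(features, "features")
  if (nrow(regions) == 0L || nrow(features) == 0L)
    return(0)
  ri <- .to_iranges(regions$start, regions$end)
  fi <- .to_iranges(features$start, features$end)
  switch(mode,
    region_hits = sum(IRanges::countOverlaps(ri, fi) > 0),
    feature_hits = sum(IRanges::countOverlaps(fi, ri) > 0),
    bp = sum(IRanges::width(
      BiocGenerics::intersect(IRanges::reduce(ri), IRanges::reduce(fi)))))
}

#' Permutation test of region/feature overlap
#'
#' Compares the observed overlap statistic against `N` random shufflings of
#' the regions (lengths preserved, placement uniform outside `excluded`).
#' The empirical p-value uses plus-one smoothing,
#' `p = (1 + #(null >= observed)) / (N + 1)`, so it is never zero.
#'
#' @param regions,features Data frames with `start`, `end` (one chromosome).
#' @param chrom_length Chromosome length in bp.
#' @param N Number of permutations (default 10000, minimum 100).
#' @param mode Overlap statistic, see [overlap_statistic].
#' @param excluded Optional excluded intervals for the shuffle.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @param seed Optional integer seed; the same seed reproduces the same null
#'   draws exactly.
#' @return List of class `enrichment_result`: `observed`, `null_draws`,
#'   `p_empirical`, `N`, `mode`, `alternative`, `seed`.
#' @export
permutation_enrichment <- function(regions, features, chrom_length, N = 10000,
                                   mode = "region_hits", excluded = NULL,
                                   alternative = c("greater", "less"),
                                   seed = NULL) {
  alternative <- match.arg(alternative)
  if (N < 100) stop("N must be at least 100")
  observed <- overlap_statistic(regions, features, mode)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  null_draws <- vapply(seq_len(N), function(i) {
    overlap_statistic(shuffle_regions(regions, chrom_length, excluded),
                      features, mode)
  }, numeric(1))
  hits <- if (alternative == "greater") sum(null_draws >= observed)
          else sum(null_draws <= observed)
  structure(
    list(observed = observed, null_draws = null_draws,
         p_empirical = (1 + hits) / (N + 1), N = N, mode = mode,
         alternative = alternative, seed = seed),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: observed %s = %g, p = %.4g (N = %d, %s)\n",
              x$mode, x$observed, x$p_empirical, x$N, x$alternative))
  invisible(x)
}

#' Gene density of a region set
#'
#' Number of genes overlapping the union of the regions, per kilobase of
#' union length. Duplicated or overlapping regions are collapsed first, so
#' the density is a property of the covered territory.
#'
#' @param regions Data frame with `start`, `end`.
#' @param genes Data frame with `start`, `end`.
#' @return Genes per kilobase.
#' @export
gene_density <- function(regions, genes) {
  .check_intervals(regions, "regions")
  .check_intervals(genes, "genes")
  if (nrow(regions) == 0L) stop("empty region set")
  u <- .reduce_intervals(regions$start, regions$end)
  union_bp <- sum(u$end - u$start)
  if (union_bp <= 0) stop("zero-length region union")
  udf <- data.frame(start = u$start, end = u$end)
  n_genes <- overlap_statistic(genes, udf, mode = "region_hits")
  n_genes / (union_bp / 1000)
}

#' Viewpoint coverage/overlap matrix
#'
#' Symmetric matrix whose diagonal is the percent of the chromosome covered
#' by each viewpoint's Bricks and whose off-diagonal entries are the percent
#' of the chromosome covered by the pairwise intersection of two viewpoints'
#' Bricks — a compact display of how strongly interaction territories are
#' shared between viewpoints.
#'
#' @param brick_sets Named list (one element per viewpoint) of Brick data
#'   frames with `start`, `end`.
#' @param chrom_length Chromosome length in bp.
#' @return A symmetric numeric matrix of percentages.
#' @export
coverage_matrix <- function(brick_sets, chrom_length) {
  if (length(brick_sets) < 2L) stop("need Brick sets for at least 2 viewpoints")
  nms <- names(brick_sets)
  if (is.null(nms)) nms <- paste0("vp", seq_along(brick_sets))
  unions <- lapply(brick_sets, function(b) {
    if (nrow(b) == 0L) return(IRanges::IRanges())
    IRanges::reduce(.to_iranges(b$start, b$end))
  })
  k <- length(unions)
  m <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    for (j in i:k) {
      cov_bp <- if (i == j) sum(IRanges::width(unions[[i]]))
                else sum(IRanges::width(BiocGenerics::intersect(unions[[i]],
                                                                unions[[j]])))
      m[i, j] <- m[j, i] <- 100 * cov_bp / chrom_length
    }
  }
  m
}
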