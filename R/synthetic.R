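#' Simulation configuration for synthetic 4C data
#'
#' Defines the generative model the pipeline's statistics assume: a power-law
#' distance decay around a single viewpoint (slope -1 in log-log space) on
#' top of a uniform random-ligation floor, planted interaction peaks as
#' multiplicative fold enrichments, an optional hemizygous deletion in which
#' the case condition loses one allele's contacts (expected intensity halved),
#' and replicate count sampling with Poisson or negative-binomial dispersion.
#'
#' Per-fragment expected intensity:
#' `lambda_i ∝ (c / d_i + beta) * peak_fold(i) * allele_factor(i)`,
#' scaled so expected intensities sum to `library_size`; `d_i` is the distance
#' of the fragment midpoint from the viewpoint and `allele_factor` is 0.5
#' inside the deletion for the case condition, 1 otherwise.
#'
#' @param chrom_length Chromosome length in bp (default 20 Mb).
#' @param mean_fragment_length Mean restriction-fragment length (default
#'   4096 bp, the expected spacing of a 6-cutter such as BglII).
#' @param viewpoint_pos Viewpoint coordinate (default 2 Mb).
#' @param viewpoint_name Viewpoint label.
#' @param decay_constant `c` of the power-law term `c / d`.
#' @param noise_floor `beta`, the uniform per-fragment background weight in
#'   the same relative units as `c / d` (default `3e-6`; the floor then
#'   carries most chromosome-wide read mass while the decay term dominates
#'   within roughly `c / beta` = 330 kb of the viewpoint).
#' @param peaks Data frame `start`, `end`, `fold` (fold >= 1) of planted
#'   interaction peaks; optional column `condition`
#'   (`"both"`/`"control"`/`"case"`) for condition-specific peaks.
#' @param deletion `NULL` or length-2 numeric: the hemizygously deleted
#'   interval for the case condition.
#' @param library_size Expected reads per replicate (default `1e5`).
#' @param replicates Replicates per condition (default 2).
#' @param dispersion `"poisson"` (default) or `"nb"` (negative binomial,
#'   size `nb_size`, for overdispersion stress tests).
#' @param nb_size Negative-binomial size parameter (default 10).
#' @param exclusion_k Viewpoint exclusion radius passed to the viewpoint spec.
#' @param seed Optional integer seed recorded in the config; generator
#'   functions set it when present.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_length = 2e7,
                       mean_fragment_length = 4096,
                       viewpoint_pos = 2e6,
                       viewpoint_name = "VP1",
                       decay_constant = 1,
                       noise_floor = 3e-6,
                       peaks = data.frame(
                         start = c(2.9e6, 4.0e6, 1.40e7),
                         end   = c(2.98e6, 4.08e6, 1.408e7),
                         fold  = 4),
                       deletion = NULL,
                       library_size = 1e5,
                       replicates = 2,
                       dispersion = c("poisson", "nb"),
                       nb_size = 10,
                       exclusion_k = 2,
                       seed = NULL) {
  dispersion <- match.arg(dispersion)
  if (chrom_length < 10 * mean_fragment_length)
    stop("chrom_length must be at least 10 mean fragment lengths")
  if (library_size <= 0) stop("library_size must be positive")
  if (viewpoint_pos <= 0 || viewpoint_pos >= chrom_length)
    stop("viewpoint must lie inside the chromosome")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    if (any(peaks$fold < 1)) stop("peak fold must be >= 1")
    if (any(peaks$start < 0 | peaks$end > chrom_length | peaks$end <= peaks$start))
      stop("peaks must be proper intervals within the chromosome")
    if (is.null(peaks$condition)) peaks$condition <- "both"
  }
  if (!is.null(deletion)) {
    if (length(deletion) != 2 || deletion[1] >= deletion[2] ||
        deletion[1] < 0 || deletion[2] > chrom_length)
      stop("deletion must be a proper interval within the chromosome")
  }
  structure(
    list(chrom_length = chrom_length,
         mean_fragment_length = mean_fragment_length,
         viewpoint_pos = viewpoint_pos, viewpoint_name = viewpoint_name,
         decay_constant = decay_constant, noise_floor = noise_floor,
         peaks = peaks, deletion = deletion, library_size = library_size,
         replicates = replicates, dispersion = dispersion, nb_size = nb_size,
         exclusion_k = exclusion_k, seed = seed),
    class = "sim_config"
  )
}

.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Simulate a restriction-fragment map
#'
#' Fragment lengths are drawn iid exponential with the configured mean
#' (restriction-site spacing of a fixed motif in random sequence is
#' geometric), with a floor of 200 bp, and laid end to end until the
#' chromosome is covered; the last fragment is truncated at the chromosome
#' end.
#'
#' @param config A [sim_config].
#' @param chrom Chromosome name.
#' @return A [fragment_map].
#' @export
simulate_fragment_map <- function(config, chrom = "chrS") {
  .maybe_seed(config$seed)
  L <- config$chrom_length
  mfl <- config$mean_fragment_length
  n_guess <- ceiling(L / mfl * 1.5) + 10
  lens <- pmax(round(stats::rexp(n_guess, rate = 1 / mfl)), 200)
  while (sum(lens) < L)
    lens <- c(lens, pmax(round(stats::rexp(n_guess, rate = 1 / mfl)), 200))
  ends <- cumsum(lens)
  ends <- c(ends[ends < L], L)
  starts <- c(0, ends[-length(ends)])
  keep <- ends > starts
  fragment_map(chrom, starts[keep], ends[keep])
}

# random DNA as a character vector of single bases
.random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate a genome sequence realizing a fragment map
#'
#' Generates a random DNA sequence in which the enzyme motif occurs exactly
#' at the internal fragment boundaries of a simulated map (unintended motif
#' occurrences are mutated away), so that [digest_genome] applied to the
#' emitted sequence reproduces the map exactly.
#'
#' @param config A [sim_config] (use a modest `chrom_length` here; counts can
#'   be simulated on much longer fragment maps without a sequence).
#' @param chrom Chromosome name.
#' @return List with `sequences` (a [Biostrings::DNAStringSet]) and `fmap`
#'   (the realized [fragment_map]).
#' @export
simulate_genome <- function(config, chrom = "chrS") {
  fmap <- simulate_fragment_map(config, chrom = chrom)
  motif <- fmap$enzyme_motif
  mlen <- nchar(motif)
  motif_chars <- strsplit(motif, "")[[1]]
  L <- chrom_size(fmap)
  bases <- .random_bases(L)
  bounds <- fmap$start[-1]  # internal boundaries, 0-based motif starts
  for (b in bounds)
    bases[(b + 1):(b + mlen)] <- motif_chars
  seq1 <- paste(bases, collapse = "")
  # repair pass: mutate any motif occurrence that is not an intended boundary
  for (iter in 1:100) {
    hits <- Biostrings::start(
      Biostrings::matchPattern(motif, Biostrings::DNAString(seq1))) - 1
    rogue <- setdiff(hits, bounds)
    if (length(rogue) == 0L) break
    for (r in rogue) {
      pos <- r + 3  # middle of the occurrence, 1-based is pos + 1
      cur <- substr(seq1, pos + 1, pos + 1)
      substr(seq1, pos + 1, pos + 1) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  if (length(rogue) > 0L)
    stop("failed to remove unintended motif occurrences")
  seqs <- Biostrings::DNAStringSet(stats::setNames(seq1, chrom))
  list(sequences = seqs, fmap = fmap)
}

# per-fragment expected intensity weights (before library scaling)
.intensity_weights <- function(fmap, config, condition) {
  mid <- fragment_mid(fmap)
  d <- abs(mid - config$viewpoint_pos)
  d <- pmax(d, (fmap$end - fmap$start) / 2)
  w <- config$decay_constant / d + config$noise_floor
  if (!is.null(config$peaks) && nrow(config$peaks) > 0) {
    for (i in seq_len(nrow(config$peaks))) {
      pc <- config$peaks$condition[i]
      if (pc != "both" && pc != condition) next
      inside <- mid >= config$peaks$start[i] & mid < config$peaks$end[i]
      w[inside] <- w[inside] * config$peaks$fold[i]
    }
  }
  if (condition == "case" && !is.null(config$deletion)) {
    inside <- mid >= config$deletion[1] & mid < config$deletion[2]
    w[inside] <- w[inside] * 0.5
  }
  w
}

#' Simulate replicate 4C count tracks for one condition
#'
#' Draws per-fragment counts around the expected intensities of the
#' generative model (see [sim_config]) for `config$replicates` replicates.
#' Exclusion-zone fragments receive counts like any other fragment — the
#' self-ligation filter in [count_track] is expected to remove them.
#'
#' @param fmap A [fragment_map] (typically from [simulate_fragment_map]).
#' @param config A [sim_config].
#' @param condition `"control"` or `"case"`.
#' @return List with `tracks` (list of [count_track]s) and `truth` (a
#'   `synthetic_truth`: planted peaks, deletion, per-fragment expected
#'   intensities for this condition).
#' @export
simulate_counts <- function(fmap, config, condition = c("control", "case")) {
  condition <- match.arg(condition)
  vp <- viewpoint_spec(config$viewpoint_name, fmap$chrom,
                       config$viewpoint_pos, exclusion_k = config$exclusion_k)
  w <- .intensity_weights(fmap, config, condition)
  # scale by the control-condition total so that the deletion halves the
  # case expectation exactly (one allele lost, fixed input material); the
  # realized case library is then slightly smaller, which the total-read
  # normalization step absorbs, as with real 4C libraries
  w_ref <- .intensity_weights(fmap, config, "control")
  lambda <- config$library_size * w / sum(w_ref)
  n <- n_fragments(fmap)
  tracks <- lapply(seq_len(config$replicates), function(r) {
    counts <- if (config$dispersion == "poisson") stats::rpois(n, lambda)
              else stats::rnbinom(n, mu = lambda, size = config$nb_size)
    count_track(fmap, vp, counts, condition = condition,
                replicate = paste0("rep", r))
  })
  truth <- structure(
    list(peaks = config$peaks, deletion = config$deletion,
         expected = lambda, condition = condition),
    class = "synthetic_truth"
  )
  list(tracks = tracks, truth = truth)
}

#' Simulate a full two-condition 4C experiment
#'
#' Fragment map plus replicate count tracks for the control and case
#' conditions, with ground truth. Inside the deletion the case expectation is
#' exactly half the control expectation (one allele lost); outside they are
#' equal up to condition-specific peaks and the global library rescaling.
#'
#' @param config A [sim_config].
#' @param chrom Chromosome name.
#' @return List: `fmap`, `viewpoint`, `control`/`case` (lists of
#'   [count_track]s), `truth` (peaks, deletion, per-condition expected
#'   intensities).
#' @export
simulate_experiment <- function(config, chrom = "chrS") {
  .maybe_seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL  # one seed for the whole experiment, set above
  fmap <- simulate_fragment_map(cfg_noseed, chrom = chrom)
  ctrl <- simulate_counts(fmap, cfg_noseed, "control")
  case <- simulate_counts(fmap, cfg_noseed, "case")
  vp <- viewpoint_spec(config$viewpoint_name, fmap$chrom,
                       config$viewpoint_pos, exclusion_k = config$exclusion_k)
  truth <- structure(
    list(peaks = config$peaks, deletion = config$deletion,
         expected_control = ctrl$truth$expected,
         expected_case = case$truth$expected),
    class = "synthetic_truth"
  )
  list(fmap = fmap, viewpoint = vp, control = ctrl$tracks, case = case$tracks,
       truth = truth, config = config)
}

#' Simulate a feature set correlated with planted peaks
#'
#' Each feature is placed inside a randomly chosen planted peak with
#' probability `enrich_prob`, and uniformly on the chromosome otherwise; at
#' `enrich_prob = 0` features are independent of the truth (the calibration
#' case for permutation enrichment).
#'
#' @param fmap A [fragment_map] (supplies the chromosome bounds).
#' @param truth A `synthetic_truth` with planted peaks (may be `NULL` when
#'   `enrich_prob = 0`).
#' @param n_genes Number of features to place.
#' @param enrich_prob Probability in `[0, 1]` of peak placement.
#' @param feature_length Feature length in bp (default 10 kb).
#' @param seed Optional integer seed.
#' @return A [feature_set] data frame with exactly `n_genes` rows.
#' @export
simulate_features <- function(fmap, truth = NULL, n_genes = 50,
                              enrich_prob = 0, feature_length = 1e4,
                              seed = NULL) {
  if (enrich_prob < 0 || enrich_prob > 1)
    stop("enrich_prob must be in [0, 1]")
  peaks <- if (!is.null(truth)) truth$peaks else NULL
  if (enrich_prob > 0 && (is.null(peaks) || nrow(peaks) == 0))
    stop("enrich_prob > 0 requires planted peaks in truth")
  .maybe_seed(seed)
  L <- chrom_size(fmap)
  starts <- vapply(seq_len(n_genes), function(i) {
    if (enrich_prob > 0 && stats::runif(1) < enrich_prob) {
      k <- sample.int(nrow(peaks), 1)
      lo <- peaks$start[k]
      hi <- max(lo + 1, peaks$end[k] - feature_length)
      stats::runif(1, lo, hi)
    } else {
      stats::runif(1, 0, L - feature_length)
    }
  }, numeric(1))
  starts <- round(starts)
  feature_set(fmap$chrom, starts, pmin(starts + feature_length, L),
              name = "simulated_genes", kind = "genes")
}

#' Write a simulation manifest
#'
#' Records the full configuration (including the seed) as YAML next to an
#' emitted dataset, so any run can be reproduced exactly.
#'
#' @param config A [sim_config].
#' @param path Output file path.
#' @export
write_manifest <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$peaks)) x$peaks <- as.list(as.data.frame(x$peaks))
  yaml::write_yaml(x, path)
  invisible(path)
}
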