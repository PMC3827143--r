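#' Viewpoint signal profile: counts to corrected track
#'
#' Standard per-viewpoint processing chain: normalize each replicate to the
#' total read count, smooth with a running mean, average the replicates,
#' fit the slope -1 distance-decay background and subtract it.
#'
#' @param tracks List of [count_track]s (replicates of one condition).
#' @param w Running-mean window in fragments (default 19).
#' @param scale Normalization scale (default `1e6`, reads per million).
#' @param fit_range,estimator Passed to [fit_background].
#' @return List: `corrected` (signal track, stage `"corrected"`), `smoothed`
#'   (replicate-averaged smoothed track), `model` (the [background_model]).
#' @export
viewpoint_profile <- function(tracks, w = 19, scale = 1e6, fit_range = NULL,
                              estimator = "median") {
  if (!is.list(tracks) || inherits(tracks, "count_track"))
    tracks <- list(tracks)
  smoothed <- lapply(tracks, function(t) running_mean(normalize_track(t, scale), w))
  avg <- average_replicates(smoothed)
  model <- fit_background(avg, fit_range = fit_range, estimator = estimator)
  corrected <- profile_correct(avg, model)
  list(corrected = corrected, smoothed = avg, model = model)
}

#' Call Bricks and interacting regions for one corrected track
#'
#' Rank-transforms the corrected signal, scores all multi-scale windows,
#' calls tiered-FDR Bricks and merges consecutive Bricks into interacting
#' regions.
#'
#' @param corrected A corrected [signal_track].
#' @param wmax Maximum window width in fragments (default 200).
#' @param fdr_short,fdr_long,srw,sign Passed to [call_bricks].
#' @param merge_gap Passed to [merge_bricks].
#' @return List: `bricks` (disjoint Brick data frame), `regions` (merged
#'   interacting regions).
#' @export
call_viewpoint_bricks <- function(corrected, wmax = 200, fdr_short = 0.1,
                                  fdr_long = 0.001, srw = NULL,
                                  merge_gap = 1, sign = "positive") {
  u <- rank_transform(corrected)
  scores <- window_pvalues(u, wmax = wmax)
  bricks <- call_bricks(scores, corrected$fmap, fdr_short = fdr_short,
                        fdr_long = fdr_long, srw = srw, sign = sign)
  regions <- merge_bricks(bricks, merge_gap = merge_gap)
  list(bricks = bricks, regions = regions)
}
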