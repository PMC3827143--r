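#' Per-fragment signal track
#'
#' Real-valued signal for one viewpoint/condition at a named processing stage.
#' Stages advance raw -> normalized -> smoothed -> corrected; the fragment
#' dimension is preserved throughout. `NA` marks fragments excluded from the
#' analysis (the viewpoint exclusion zone after profile correction).
#'
#' @param fmap A [fragment_map].
#' @param viewpoint A [viewpoint_spec].
#' @param values Numeric vector, one per fragment.
#' @param stage One of `"raw"`, `"normalized"`, `"smoothed"`, `"corrected"`.
#' @param condition Label.
#' @param scale_factor Reads-per-`scale` normalizer used, if any.
#' @param model Optional [background_model] attached after correction.
#' @export
signal_track <- function(fmap, viewpoint, values, stage, condition = "",
                         scale_factor = NA_real_, model = NULL) {
  stage <- match.arg(stage, c("raw", "normalized", "smoothed", "corrected"))
  if (length(values) != n_fragments(fmap))
    stop("values length must equal the number of fragments")
  structure(
    list(fmap = fmap, viewpoint = viewpoint, condition = condition,
         stage = stage, values = as.numeric(values),
         scale_factor = scale_factor, model = model),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %s [%s], stage %s, %d fragments\n",
              x$viewpoint$name, x$condition, x$stage, n_fragments(x$fmap)))
  invisible(x)
}

#' Normalize a count track to the total number of reads
#'
#' Values become `counts * scale / library_size` (reads per million with the
#' default scale), so tracks from libraries of different depth are comparable.
#'
#' @param track A [count_track].
#' @param scale Target total (default `1e6`).
#' @return A [signal_track] at stage `"normalized"`.
#' @export
normalize_track <- function(track, scale = 1e6) {
  stopifnot(inherits(track, "count_track"))
  if (track$library_size <= 0)
    stop("cannot normalize an empty library")
  signal_track(track$fmap, track$viewpoint,
               track$counts * scale / track$library_size,
               stage = "normalized", condition = track$condition,
               scale_factor = scale)
}

# Centered running mean with a symmetrically shrinking window at the edges:
# at position i the half-width is min((w-1)/2, i-1, n-i), so the track length
# is preserved and no signal is fabricated beyond the chromosome ends.
running_mean_vec <- function(x, w) {
  n <- length(x)
  if (w %% 2 == 0) stop("window w must be odd")
  if (w < 1 || w > n) stop("window w must be between 1 and the track length")
  if (w == 1) return(x)
  k <- (w - 1) / 2
  i <- seq_len(n)
  h <- pmin(k, i - 1, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
}

#' Running-mean smoothing
#'
#' Centered mean over `w` fragments (default 19). At the chromosome edges the
#' window shrinks symmetrically to the available fragments.
#'
#' @param x A [signal_track] (stage `"normalized"` or later) or a plain
#'   numeric vector.
#' @param w Odd window width in fragments, default 19.
#' @return Same type as `x`; tracks advance to stage `"smoothed"`.
#' @export
running_mean <- function(x, w = 19) {
  if (inherits(x, "signal_track")) {
    out <- x
    out$values <- running_mean_vec(x$values, w)
    out$stage <- "smoothed"
    return(out)
  }
  running_mean_vec(as.numeric(x), w)
}

#' Average replicate tracks pointwise
#'
#' @param tracks List of [signal_track]s at the same stage, viewpoint and
#'   condition.
#' @return A single [signal_track], the arithmetic mean of the inputs.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) < 1L) stop("need at least one track")
  ref <- tracks[[1]]
  for (t in tracks) {
    if (!inherits(t, "signal_track")) stop("all inputs must be signal_tracks")
    if (t$stage != ref$stage || t$viewpoint$name != ref$viewpoint$name ||
        t$condition != ref$condition)
      stop("tracks must share stage, viewpoint and condition")
    if (length(t$values) != length(ref$values))
      stop("tracks must have equal length")
  }
  vals <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "values")))
  out <- ref
  out$values <- vals
  out
}

#' Power-law background model of 4C distance decay
#'
#' Expected signal at distance `d` from the viewpoint is `10^intercept / d`:
#' a straight line of fixed slope -1 in log-log space. Only the intercept is
#' estimated.
#'
#' @param intercept Intercept in log10 units.
#' @param fit_range Length-2 numeric, distance range (bp) used in the fit.
#' @param side `"both"`, `"upstream"` or `"downstream"`.
#' @param diagnostic_slope Slope of an unconstrained log-log regression over
#'   the fit range, as a goodness-of-fit diagnostic (close to -1 when the
#'   power law holds).
#' @param n_points Number of fragments used in the fit.
#' @export
background_model <- function(intercept, fit_range, side = "both",
                             diagnostic_slope = NA_real_, n_points = NA_integer_) {
  if (fit_range[1] <= 0) stop("fit_range lower bound must be positive")
  structure(
    list(intercept = intercept, slope = -1, fit_range = fit_range, side = side,
         diagnostic_slope = diagnostic_slope, n_points = n_points),
    class = "background_model"
  )
}

#' Expected background signal at given distances
#' @param model A [background_model].
#' @param d Distances from the viewpoint (bp), positive.
#' @export
expected_background <- function(model, d) 10^model$intercept / d

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(paste0("background_model: expected(d) = 10^%.4f / d ",
                     "(fit on %d fragments, %.3g-%.3g bp, side %s; ",
                     "diagnostic slope %.3f)\n"),
              x$intercept, x$n_points, x$fit_range[1], x$fit_range[2],
              x$side, x$diagnostic_slope))
  invisible(x)
}

#' Fit the distance-decay background with fixed slope -1
#'
#' With the slope pinned at -1 in log-log space, the intercept is the robust
#' location (median, i.e. a least-absolute-deviation fit) of
#' `log10(value) + log10(distance)` over fragments in the fit range; a
#' least-squares option is available. Zero or negative values are excluded
#' from the fit (but stay in the track), as are exclusion-zone fragments.
#'
#' @param track A smoothed [signal_track].
#' @param fit_range Length-2 numeric: distance range (bp) to fit over. The
#'   default spans from the first fragment outside the viewpoint exclusion
#'   zone to 2.5 Mb. For data whose distal signal is dominated by a flat
#'   random-ligation floor, restrict the upper bound to the decay-dominated
#'   zone (see the methods vignette).
#' @param side Fit on `"both"` (pooled), `"upstream"` or `"downstream"`
#'   fragments.
#' @param estimator `"median"` (robust, default) or `"lsq"`.
#' @return A [background_model].
#' @export
fit_background <- function(track, fit_range = NULL,
                           side = c("both", "upstream", "downstream"),
                           estimator = c("median", "lsq")) {
  stopifnot(inherits(track, "signal_track"))
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  fmap <- track$fmap
  vp <- track$viewpoint
  mid <- fragment_mid(fmap)
  d <- abs(mid - vp$position)
  excl <- viewpoint_exclusion(fmap, vp)
  usable <- setdiff(seq_len(n_fragments(fmap)), excl)
  if (is.null(fit_range))
    fit_range <- c(min(d[usable]), 2.5e6)
  keep <- logical(n_fragments(fmap))
  keep[usable] <- TRUE
  keep <- keep & d >= fit_range[1] & d <= fit_range[2] &
    !is.na(track$values) & track$values > 0
  if (side == "upstream") keep <- keep & mid < vp$position
  if (side == "downstream") keep <- keep & mid > vp$position
  if (sum(keep) < 10)
    stop("fewer than 10 positive fragments in the fit range; widen fit_range")
  ly <- log10(track$values[keep])
  ld <- log10(d[keep])
  a <- if (estimator == "median") stats::median(ly + ld) else mean(ly + ld)
  diag_fit <- stats::lm.fit(cbind(1, ld), ly)
  background_model(a, fit_range = fit_range, side = side,
                   diagnostic_slope = unname(diag_fit$coefficients[2]),
                   n_points = sum(keep))
}

#' Remove the distance-decay background from a smoothed track
#'
#' Subtracts the model expectation `10^intercept / d` from every fragment,
#' keeping signed residuals: positive values are signal above the local
#' background, negative values below. Exclusion-zone fragments become `NA`.
#'
#' @param track A smoothed [signal_track].
#' @param model A [background_model] fitted on the same viewpoint, or `NULL`
#'   to fit one with [fit_background] defaults (extra arguments are passed
#'   through).
#' @param ... Passed to [fit_background] when `model` is `NULL`.
#' @return A [signal_track] at stage `"corrected"` with the model attached.
#' @export
profile_correct <- function(track, model = NULL, ...) {
  stopifnot(inherits(track, "signal_track"))
  if (is.null(model)) model <- fit_background(track, ...)
  fmap <- track$fmap
  d <- abs(fragment_mid(fmap) - track$viewpoint$position)
  d <- pmax(d, (fmap$end - fmap$start) / 2)  # viewpoint fragment: d > 0
  vals <- track$values - expected_background(model, d)
  vals[viewpoint_exclusion(fmap, track$viewpoint)] <- NA_real_
  signal_track(fmap, track$viewpoint, vals, stage = "corrected",
               condition = track$condition, scale_factor = track$scale_factor,
               model = model)
}
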