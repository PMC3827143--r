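# Plain-text track/interval output. BED and bedGraph are tab-separated with
# 0-based half-open coordinates, which is the package's internal convention,
# so writing is direct.

.fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write intervals as BED
#'
#' Writes BED3 (chrom/start/end) plus optional `name` and `score` columns
#' (BED4/BED6 with a `.` strand).
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom, start = .fmt_coord(x$start),
                    end = .fmt_coord(x$end))
  if (!is.null(x$name)) out$name <- x$name
  if (!is.null(x$score)) {
    if (is.null(out$name)) out$name <- "."
    out$score <- x$score
    out$strand <- "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' Reads the first three to six columns of a BED file into a data frame
#' (`chrom`, `start`, `end`, then `name`, `score`, `strand` when present).
#'
#' @param path File path.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  x
}

#' Write a fragment map as BED4
#'
#' One row per fragment with a sequential fragment id in the name column.
#'
#' @param fmap A [fragment_map].
#' @param path Output path.
#' @export
write_fragment_map <- function(fmap, path) {
  write_bed(data.frame(chrom = fmap$chrom, start = fmap$start, end = fmap$end,
                       name = paste0("frag_", seq_len(n_fragments(fmap)))),
            path)
}

#' Write a signal or ratio track as bedGraph
#'
#' Missing values (viewpoint exclusion zone) are written as 0 with the
#' fragments listed, keeping the file aligned with the fragment map.
#'
#' @param track A [signal_track] or `ratio_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  vals <- track$values
  vals[is.na(vals)] <- 0
  out <- data.frame(chrom = track$fmap$chrom,
                    start = .fmt_coord(track$fmap$start),
                    end = .fmt_coord(track$fmap$end),
                    value = vals)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write Bricks or regions as BED6
#'
#' Name encodes tier (and sign for ratio Bricks); score is `-log10(p)`.
#'
#' @param bricks Brick data frame from [call_bricks] or a ratio-Brick set
#'   member.
#' @param path Output path.
#' @export
write_bricks_bed <- function(bricks, path) {
  p <- if (!is.null(bricks$p_value)) bricks$p_value else bricks$summary_p
  nm <- if (!is.null(bricks$tier)) bricks$tier else "region"
  if (!is.null(bricks$sign)) nm <- paste(nm, bricks$sign, sep = "_")
  write_bed(data.frame(chrom = bricks$chrom, start = bricks$start,
                       end = bricks$end, name = nm,
                       score = round(-log10(p), 3)),
            path)
}

#' Write a background model as a YAML sidecar
#'
#' @param model A [background_model].
#' @param path Output path.
#' @export
write_background_model <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}
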