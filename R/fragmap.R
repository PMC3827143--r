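#' Virtual restriction-fragment map
#'
#' A `fragment_map` is the coordinate system of all 4C signal: the ordered,
#' gap-free tiling of one chromosome by restriction fragments. All coordinates
#' are 0-based half-open (BED convention).
#'
#' @param chrom Chromosome name.
#' @param starts,ends Fragment coordinates, 0-based half-open. Must tile the
#'   chromosome: strictly increasing starts, `starts[1] == 0`, and
#'   `starts[i+1] == ends[i]`.
#' @param enzyme_motif Recognition sequence of the restriction enzyme
#'   (default BglII, `"AGATCT"`).
#' @return An object of class `fragment_map`.
#' @export
fragment_map <- function(chrom, starts, ends, enzyme_motif = "AGATCT") {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("starts and ends must be non-empty and of equal length")
  if (any(ends <= starts))
    stop("all fragments must have positive width")
  if (is.unsorted(starts, strictly = TRUE))
    stop("fragment starts must be strictly increasing")
  if (starts[1] != 0)
    stop("first fragment must start at 0")
  n <- length(starts)
  if (n > 1L && any(starts[-1] != ends[-n]))
    stop("fragments must tile the chromosome without gaps or overlaps")
  structure(
    list(chrom = as.character(chrom), start = starts, end = ends,
         enzyme_motif = enzyme_motif),
    class = "fragment_map"
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %s, %d fragments over %s bp (motif %s)\n",
              x$chrom, n_fragments(x), format(chrom_size(x), big.mark = ","),
              x$enzyme_motif))
  invisible(x)
}

#' Number of fragments in a fragment map
#' @param fmap A `fragment_map`.
#' @export
n_fragments <- function(fmap) length(fmap$start)

#' Chromosome length covered by a fragment map
#' @param fmap A `fragment_map`.
#' @export
chrom_size <- function(fmap) fmap$end[n_fragments(fmap)]

#' Fragment midpoints (bp)
#' @param fmap A `fragment_map`.
#' @export
fragment_mid <- function(fmap) (fmap$start + fmap$end) / 2

#' In-silico digestion of a genome
#'
#' Cuts each input sequence at every occurrence of the enzyme recognition
#' motif, producing a virtual fragment library. The cut is placed at the motif
#' start, so every internal fragment boundary coincides with a motif
#' occurrence; the exact in-vitro overhang offset is irrelevant to the
#' analysis, which only needs a consistent tiling.
#'
#' @param sequences Named character vector of DNA sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param motif Recognition sequence (uppercase ACGT), default BglII
#'   `"AGATCT"`.
#' @return Named list of [fragment_map] objects, one per input sequence.
#' @examples
#' digest_genome(c(chrS = "AAAAAAAAAAAGATCTTTTT"))
#' @export
digest_genome <- function(sequences, motif = "AGATCT") {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L ||
      grepl("[^ACGT]", motif))
    stop("motif must be a non-empty uppercase ACGT string")
  if (inherits(sequences, "DNAStringSet")) {
    seqs <- sequences
  } else {
    if (!is.character(sequences) || length(sequences) == 0L)
      stop("sequences must be a non-empty named character vector or DNAStringSet")
    seqs <- Biostrings::DNAStringSet(sequences)
  }
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence")
  nms <- names(seqs)
  if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
  maps <- lapply(seq_along(seqs), function(i) {
    L <- Biostrings::width(seqs)[i]
    hits <- Biostrings::matchPattern(motif, seqs[[i]])
    cuts <- Biostrings::start(hits) - 1  # 0-based motif starts
    bounds <- sort(unique(c(0, cuts, L)))
    keep <- diff(bounds) > 0
    starts <- bounds[-length(bounds)][keep]
    ends <- bounds[-1][keep]
    fragment_map(nms[i], starts, ends, enzyme_motif = motif)
  })
  names(maps) <- nms
  maps
}

#' Viewpoint definition
#'
#' The viewpoint (bait) is the restriction fragment anchoring a 4C experiment;
#' all signal measures contact with this fragment. Reads mapping to the
#' viewpoint fragment and its `exclusion_k` neighbours per side are
#' self-ligation / undigested-circle artifacts and are removed.
#'
#' @param name Viewpoint (gene) name.
#' @param chrom Chromosome.
#' @param position Base coordinate inside the viewpoint fragment.
#' @param exclusion_k Number of adjacent fragments masked on each side
#'   (default 2).
#' @export
viewpoint_spec <- function(name, chrom, position, exclusion_k = 2L) {
  if (exclusion_k < 0) stop("exclusion_k must be >= 0")
  structure(
    list(name = as.character(name), chrom = as.character(chrom),
         position = as.numeric(position), exclusion_k = as.integer(exclusion_k)),
    class = "viewpoint_spec"
  )
}

#' Index of the fragment containing the viewpoint
#' @param fmap A `fragment_map`.
#' @param vp A `viewpoint_spec`.
#' @export
viewpoint_fragment <- function(fmap, vp) {
  idx <- findInterval(vp$position, fmap$start)
  if (idx < 1L || vp$position >= fmap$end[idx])
    stop("viewpoint position does not fall inside any fragment of the map")
  idx
}

#' Fragment indices masked around the viewpoint
#'
#' The viewpoint fragment plus `exclusion_k` fragments per side.
#' @inheritParams viewpoint_fragment
#' @export
viewpoint_exclusion <- function(fmap, vp) {
  idx <- viewpoint_fragment(fmap, vp)
  seq(max(1L, idx - vp$exclusion_k), min(n_fragments(fmap), idx + vp$exclusion_k))
}

#' Per-fragment count track
#'
#' Container for one replicate of one condition at one viewpoint. Counts at
#' the viewpoint-adjacent exclusion-zone fragments are zeroed (self-ligation
#' filter) and `library_size` is the post-filter total.
#'
#' @param fmap A [fragment_map].
#' @param viewpoint A [viewpoint_spec] on the same chromosome.
#' @param counts Non-negative integer vector, one entry per fragment
#'   (pre-filter; the constructor applies the viewpoint mask).
#' @param condition,replicate Labels.
#' @param n_skipped Number of input reads that fell outside the chromosome
#'   (bookkeeping from [assign_reads]).
#' @export
count_track <- function(fmap, viewpoint, counts, condition = "", replicate = "",
                        n_skipped = 0L) {
  stopifnot(inherits(fmap, "fragment_map"), inherits(viewpoint, "viewpoint_spec"))
  if (length(counts) != n_fragments(fmap))
    stop("counts length must equal the number of fragments")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (fmap$chrom != viewpoint$chrom)
    stop("viewpoint chromosome does not match the fragment map")
  counts <- as.numeric(counts)
  excl <- viewpoint_exclusion(fmap, viewpoint)
  n_masked <- sum(counts[excl])
  counts[excl] <- 0
  library_size <- sum(counts)
  if (library_size == 0)
    warning("empty track: library size is 0 after viewpoint filtering")
  structure(
    list(fmap = fmap, viewpoint = viewpoint, condition = condition,
         replicate = replicate, counts = counts, library_size = library_size,
         n_discarded = n_masked + n_skipped),
    class = "count_track"
  )
}

#' @export
print.count_track <- function(x, ...) {
  cat(sprintf("count_track: %s [%s/%s], %s reads retained (%s discarded)\n",
              x$viewpoint$name, x$condition, x$replicate,
              format(x$library_size, big.mark = ","),
              format(x$n_discarded, big.mark = ",")))
  invisible(x)
}

#' Assign aligned reads to restriction fragments
#'
#' Each read is assigned to the fragment containing its 5' coordinate
#' (half-open tiling: a read starting exactly on a boundary belongs to the
#' fragment starting there). Reads on the viewpoint fragment or its
#' exclusion-zone neighbours are discarded as self-ligation/undigested
#' artifacts and excluded from the library size; reads outside the chromosome
#' are skipped with a warning.
#'
#' @param reads Numeric vector of 5' positions (0-based), or a data frame with
#'   columns `start`, `end` and optionally `strand` (`"-"` reads use `end - 1`
#'   as the 5' coordinate).
#' @param fmap A [fragment_map].
#' @param vp A [viewpoint_spec].
#' @param condition,replicate Labels passed to the track.
#' @return A [count_track].
#' @export
assign_reads <- function(reads, fmap, vp, condition = "", replicate = "") {
  if (is.data.frame(reads)) {
    pos <- reads$start
    if (!is.null(reads$strand)) {
      neg <- reads$strand == "-"
      pos[neg] <- reads$end[neg] - 1
    }
  } else {
    pos <- as.numeric(reads)
  }
  L <- chrom_size(fmap)
  inside <- !is.na(pos) & pos >= 0 & pos < L
  n_skipped <- sum(!inside)
  if (n_skipped > 0)
    warning(sprintf("%d read(s) outside chromosome bounds skipped", n_skipped))
  idx <- findInterval(pos[inside], fmap$start)
  counts <- tabulate(idx, nbins = n_fragments(fmap))
  count_track(fmap, vp, counts, condition = condition, replicate = replicate,
              n_skipped = n_skipped)
}

#' Read a per-fragment count table (bedGraph-like TSV)
#'
#' Expects four tab-separated columns: chrom, start, end, count, one row per
#' fragment in fragment order. If `fmap` is supplied the rows must match it
#' exactly; otherwise a fragment map is reconstructed from the rows.
#'
#' @param path File path.
#' @param viewpoint A [viewpoint_spec].
#' @param fmap Optional [fragment_map] to validate against.
#' @param condition,replicate Labels.
#' @param enzyme_motif Motif recorded when reconstructing the map.
#' @return A [count_track].
#' @export
read_count_table <- function(path, viewpoint, fmap = NULL,
                             condition = "", replicate = "",
                             enzyme_motif = "AGATCT") {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("chrom", "start", "end", "count"))
  for (col in c("start", "end", "count")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0)
      stop(sprintf("malformed numeric value in column '%s' at line %d of %s",
                   col, bad[1], path))
    raw[[col]] <- vals
  }
  if (is.null(fmap)) {
    fmap <- fragment_map(raw$chrom[1], raw$start, raw$end,
                         enzyme_motif = enzyme_motif)
  } else {
    if (nrow(raw) != n_fragments(fmap))
      stop(sprintf("row count (%d) does not match fragment map (%d fragments)",
                   nrow(raw), n_fragments(fmap)))
    if (any(raw$start != fmap$start) || any(raw$end != fmap$end))
      stop("fragment coordinates in file do not match the fragment map")
  }
  count_track(fmap, viewpoint, raw$count, condition = condition,
              replicate = replicate)
}

#' Write a count track as a bedGraph-like TSV
#'
#' @param track A [count_track].
#' @param path Output file path.
#' @export
write_count_table <- function(track, path) {
  out <- data.frame(chrom = track$fmap$chrom,
                    start = format(track$fmap$start, scientific = FALSE, trim = TRUE),
                    end = format(track$fmap$end, scientific = FALSE, trim = TRUE),
                    count = track$counts)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
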