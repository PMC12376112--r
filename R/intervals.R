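# Interval arithmetic. All heavy lifting is delegated to IRanges; these
# wrappers fix the package-wide semantics (union lengths, window tiling,
# per-window clipped union).

#' Total length of the union of a set of intervals
#'
#' Overlapping and duplicated intervals are counted once; abutting intervals
#' are disjoint (half-open semantics: `[0,5) + [5,10) = 10` bp).
#'
#' @param x An `IRanges`, a `GRanges` (all ranges must lie on one sequence),
#'   or a two-column matrix/data.frame of 0-based half-open `start`, `end`.
#' @return Union length in bp.
#' @export
#' @examples
#' unionLength(IRanges::IRanges(c(11, 51), c(60, 100)))  # [10,60)+[50,100)
unionLength <- function(x) {
  if (is.matrix(x) || is.data.frame(x))
    x <- IRanges(start = x[[1L]] + 1L, end = x[[2L]])
  if (is(x, "GRanges")) {
    if (length(unique(as.character(seqnames(x)))) > 1L)
      stop("unionLength expects intervals on a single sequence; ",
           "use reduce() per seqname for multi-sequence input")
    x <- ranges(x)
  }
  if (!is(x, "IRanges")) stop("unsupported interval representation")
  sum(width(reduce(x)))
}

#' Tile reference sequences into fixed-width windows
#'
#' @param ref_lengths Named vector of sequence lengths.
#' @param window_bp Window width; the last window of each sequence may be
#'   shorter.
#' @return A `GRanges` of windows, in sequence order.
#' @export
tileWindows <- function(ref_lengths, window_bp) {
  if (window_bp <= 0L) stop("window_bp must be positive")
  tiles <- tileGenome(seqlengths = ref_lengths, tilewidth = window_bp,
                      cut.last.tile.in.chrom = TRUE)
  if (is(tiles, "GRangesList")) tiles <- unlist(tiles)
  tiles
}

# Per-window overlap bp between `windows` and the (not necessarily reduced)
# ranges `gr`: clips gr to each window after reducing, so shared bases count
# once.
.windowOverlapBp <- function(windows, gr) {
  gr <- reduce(gr)
  hits <- findOverlaps(windows, gr)
  if (!length(hits)) return(integer(length(windows)))
  w <- width(pintersect(windows[queryHits(hits)], gr[subjectHits(hits)]))
  out <- integer(length(windows))
  agg <- tapply(w, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}
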