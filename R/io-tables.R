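# Tabular I/O: gene anchors, gene matches, marker hit tables (native TSV or
# BUSCO full-table layout), BED output for masks and windowed identity.

#' Read / write a gene anchor table
#'
#' Tab-separated with header: gene_id, contig_id, start, end, strand.
#' Coordinates are 0-based half-open (BED-like), as emitted by the usual
#' GFF-to-BED flattening of transcript placements.
#'
#' @param path File path.
#' @return `readAnchors()`: a data.frame with those five columns.
#' @export
readAnchors <- function(path) {
  if (!file.exists(path)) stop("anchor table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @param anchors A data.frame as returned by [readAnchors()].
#' @rdname readAnchors
#' @export
writeAnchors <- function(anchors, path) {
  write.table(anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene match table
#'
#' Two tab-separated columns `gene_a`, `gene_b`: a one-to-one pairing of
#' gene ids (e.g. reciprocal best hits) relating anchors on one contig to
#' anchors on another.
#'
#' @param path File path.
#' @return `readMatches()`: a data.frame with columns gene_a, gene_b.
#' @export
readMatches <- function(path) {
  if (!file.exists(path)) stop("match table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("match table must have columns gene_a, gene_b")
  df[c("gene_a", "gene_b")]
}

#' @param matches A data.frame as returned by [readMatches()].
#' @rdname readMatches
#' @export
writeMatches <- function(matches, path) {
  write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker hit table
#'
#' Native layout: tab-separated with header marker_id, contig_id, status
#' (complete / fragmented / missing), copies. A BUSCO full table
#' (comment-prefixed, columns Busco id / Status / Sequence / ...) is also
#' accepted: Complete and Duplicated rows are converted to per-contig copy
#' counts with status `complete`.
#'
#' @param path File path.
#' @return `readMarkers()`: a data.frame with columns marker_id, contig_id,
#'   status, copies.
#' @export
readMarkers <- function(path) {
  if (!file.exists(path)) stop("marker table not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) return(.readBuscoFullTable(path))
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("marker_id", "contig_id", "status", "copies")
  if (!all(need %in% names(df)))
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  bad <- xor(df$copies == 0L, df$status == "missing")
  if (any(bad))
    stop("marker table row ", which(bad)[1L],
         ": copies == 0 exactly for status 'missing'")
  df[need]
}

.readBuscoFullTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(marker_id = character(), contig_id = character(),
                      status = character(), copies = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  dt <- data.table(marker_id = vapply(f, `[`, "", 1L),
                   status = tolower(vapply(f, `[`, "", 2L)),
                   contig_id = vapply(f, function(x)
                     if (length(x) >= 3L) x[3L] else NA_character_, ""))
  # Duplicated = complete copy present more than once; count per contig.
  dt[status == "duplicated", status := "complete"]
  hit <- dt[status %in% c("complete", "fragmented") & !is.na(contig_id),
            .(copies = .N), by = .(marker_id, contig_id, status)]
  miss <- unique(dt[status == "missing",
                    .(marker_id, contig_id = NA_character_,
                      status = "missing", copies = 0L)])
  out <- rbindlist(list(hit, miss), use.names = TRUE)
  as.data.frame(out[, .(marker_id, contig_id, status, copies)])
}

#' @param markers A data.frame as returned by [readMarkers()] (native
#'   layout is written).
#' @rdname readMarkers
#' @export
writeMarkers <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genomic ranges as BED
#'
#' BED3, or BED4 with the value of `score_col` (e.g. window identity) in
#' the fourth column.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param score_col Optional mcols column for a fourth BED column.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(gr, path, score_col = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(score_col)) df$score <- mcols(gr)[[score_col]]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal TSV helpers for truth tables (header, tab-separated, no quotes).
.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
.readTsv <- function(path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
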