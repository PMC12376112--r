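# PAF reading/writing. PAF is the pairwise-mapping format emitted by
# minimap2 and friends: 12 mandatory columns, 0-based half-open coordinates,
# optional typed tags of which we consume cg:Z (CIGAR). No established R
# reader covers PAF, so the parser is written here against the format
# definition and validated by CIGAR/coordinate accounting.

.PAF_COLS <- c("query_id", "query_len", "query_start", "query_end", "strand",
               "target_id", "target_len", "target_start", "target_end",
               "n_match", "aln_len", "mapq", "cigar")

#' Read a PAF alignment file
#'
#' Coordinates stay in PAF's native 0-based half-open convention in the
#' returned table; conversion to 1-based `IRanges` happens where the
#' intervals are consumed. Records without a `cg:Z` tag carry `NA` in the
#' `cigar` column and are flagged `has_cigar = FALSE`: they remain usable
#' for coverage evidence but are excluded from variant extraction.
#'
#' For every record with a CIGAR, the query- and target-consumed CIGAR
#' lengths are checked against the coordinate spans; a mismatch is an
#' integrity error.
#'
#' @param path Path to a PAF file.
#' @return A data.frame with columns query_id, query_len, query_start,
#'   query_end, strand, target_id, target_len, target_start, target_end,
#'   n_match, aln_len, mapq, cigar, has_cigar.
#' @export
readPaf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.emptyPaf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed PAF line ", which(nf < 12L)[1L],
         ": fewer than 12 columns")
  cg <- vapply(fields, function(f) {
    tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(tag)) substring(tag[1L], 6L) else NA_character_
  }, character(1L))
  core <- t(vapply(fields, `[`, character(12L), 1:12))
  paf <- data.frame(
    query_id = core[, 1L], query_len = as.numeric(core[, 2L]),
    query_start = as.numeric(core[, 3L]), query_end = as.numeric(core[, 4L]),
    strand = core[, 5L],
    target_id = core[, 6L], target_len = as.numeric(core[, 7L]),
    target_start = as.numeric(core[, 8L]), target_end = as.numeric(core[, 9L]),
    n_match = as.numeric(core[, 10L]), aln_len = as.numeric(core[, 11L]),
    mapq = as.numeric(core[, 12L]),
    cigar = cg, has_cigar = !is.na(cg),
    stringsAsFactors = FALSE
  )
  num <- paf[c("query_len", "query_start", "query_end", "target_len",
               "target_start", "target_end", "n_match", "aln_len", "mapq")]
  if (anyNA(num))
    stop("malformed PAF line ", which(rowSums(is.na(num)) > 0)[1L],
         ": non-numeric coordinate field")
  if (!all(paf$strand %in% c("+", "-")))
    stop("malformed PAF line ", which(!paf$strand %in% c("+", "-"))[1L],
         ": strand must be + or -")
  .checkPafCigars(paf)
  paf
}

.emptyPaf <- function() {
  out <- data.frame(query_id = character(), query_len = numeric(),
                    query_start = numeric(), query_end = numeric(),
                    strand = character(), target_id = character(),
                    target_len = numeric(), target_start = numeric(),
                    target_end = numeric(), n_match = numeric(),
                    aln_len = numeric(), mapq = numeric(),
                    cigar = character(), has_cigar = logical(),
                    stringsAsFactors = FALSE)
  out
}

.checkPafCigars <- function(paf) {
  idx <- which(paf$has_cigar)
  for (i in idx) {
    sp <- cigarSpans(parseCigar(paf$cigar[i]))
    if (sp[["query"]] != paf$query_end[i] - paf$query_start[i] ||
        sp[["target"]] != paf$target_end[i] - paf$target_start[i])
      stop("PAF record ", i, " (", paf$query_id[i], " vs ",
           paf$target_id[i], "): CIGAR-consumed lengths (",
           sp[["query"]], "q/", sp[["target"]],
           "t) disagree with coordinate spans")
  }
  invisible(TRUE)
}

#' Write alignments as PAF
#'
#' @param paf A data.frame as returned by [readPaf()] (the `has_cigar`
#'   column is optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePaf <- function(paf, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  core <- paste(paf$query_id, fmt(paf$query_len), fmt(paf$query_start),
                fmt(paf$query_end), paf$strand, paf$target_id,
                fmt(paf$target_len), fmt(paf$target_start),
                fmt(paf$target_end), fmt(paf$n_match), fmt(paf$aln_len),
                fmt(paf$mapq), sep = "\t")
  has <- !is.na(paf$cigar) & nzchar(paf$cigar)
  core[has] <- paste0(core[has], "\tcg:Z:", paf$cigar[has])
  writeLines(core, path)
  invisible(path)
}
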