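# Variant container: a GRanges on reference (haplotype-1) coordinates with a
# fixed set of metadata columns. The reference span is the interval the
# variant masks in windowed identity: ref_len bases for substitutions and
# deletions, a single anchor base for insertions.

.VARIANT_MCOLS <- c("vclass", "subtype", "ref_len", "alt_len", "source")

#' Classify a variant by its reference/alternate lengths
#'
#' SNP: 1-bp substitution. Small INDEL: length difference > 0 and the longer
#' allele shorter than `pav_min` bp. PAV: longer allele at least `pav_min`
#' bp (default 50, the conventional small/structural boundary).
#'
#' @param ref_len,alt_len Integer vectors of allele lengths on reference and
#'   alternate haplotype.
#' @param pav_min PAV length floor in bp (default 50).
#' @return Character vector over `"SNP"`, `"INDEL"`, `"PAV"`.
#' @export
#' @examples
#' classifyVariant(c(1, 0, 0, 60), c(1, 10, 49, 0))
classifyVariant <- function(ref_len, alt_len, pav_min = 50L) {
  long <- pmax(ref_len, alt_len)
  ifelse(ref_len == 1L & alt_len == 1L, "SNP",
         ifelse(long >= pav_min, "PAV", "INDEL"))
}

#' Construct a validated variant GRanges
#'
#' Coordinates are 1-based closed (GRanges convention). A substitution or
#' deletion spans its `ref_len` reference bases; an insertion is anchored on
#' the single reference base before which the sequence is inserted, so every
#' variant occupies a non-empty reference interval.
#'
#' @param seq_id Reference sequence name(s).
#' @param start 1-based start of the reference span (for an insertion, the
#'   anchored base).
#' @param ref_len,alt_len Allele lengths in bp (insertion: ref_len 0;
#'   deletion: alt_len 0; substitution: both 1).
#' @param subtype `"substitution"`, `"insertion"` or `"deletion"`.
#' @param source Callset tag: `"wga"`, `"read"` or `"truth"`.
#' @param ref_seq,alt_seq Optional allele sequences.
#' @param seqlengths Optional named vector of reference lengths.
#' @param pav_min PAV length floor used for classification.
#' @return A `GRanges` with mcols vclass, subtype, ref_len, alt_len, source
#'   (and allele sequences when given).
#' @export
variantRanges <- function(seq_id, start, ref_len, alt_len, subtype, source,
                          ref_seq = NULL, alt_seq = NULL, seqlengths = NULL,
                          pav_min = 50L) {
  n <- length(start)
  stopifnot(length(ref_len) == n, length(alt_len) == n)
  subtype <- rep_len(subtype, n)
  source <- rep_len(source, n)
  bad <- (subtype == "substitution" & !(ref_len == alt_len)) |
    (subtype == "insertion" & ref_len != 0L) |
    (subtype == "deletion" & alt_len != 0L)
  if (any(bad))
    stop("inconsistent subtype/length combination at record ",
         which(bad)[1L])
  span <- ifelse(subtype == "insertion", 1L, ref_len)
  gr <- GRanges(seq_id, IRanges(start = start, width = span))
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  mcols(gr)$vclass <- classifyVariant(ref_len, alt_len, pav_min)
  mcols(gr)$subtype <- subtype
  mcols(gr)$ref_len <- as.integer(ref_len)
  mcols(gr)$alt_len <- as.integer(alt_len)
  mcols(gr)$source <- source
  if (!is.null(ref_seq)) mcols(gr)$ref_seq <- ref_seq
  if (!is.null(alt_seq)) mcols(gr)$alt_seq <- alt_seq
  validVariants(gr)
  sort(gr)
}

#' Check variant GRanges invariants
#'
#' @param gr A variant `GRanges`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validVariants <- function(gr) {
  miss <- setdiff(.VARIANT_MCOLS, names(mcols(gr)))
  if (length(miss))
    stop("variant GRanges lacks mcols: ", paste(miss, collapse = ", "))
  m <- mcols(gr)
  if (!all(m$vclass %in% c("SNP", "INDEL", "PAV")) ||
      !all(m$subtype %in% c("substitution", "insertion", "deletion")))
    stop("invalid vclass/subtype values")
  snp <- m$vclass == "SNP"
  if (!all(m$ref_len[snp] == 1L & m$alt_len[snp] == 1L))
    stop("SNP must have ref_len == alt_len == 1")
  ins <- m$subtype == "insertion"
  if (!all(width(gr)[ins] == 1L))
    stop("insertions must anchor exactly one reference base")
  if (!all(width(gr)[!ins] == m$ref_len[!ins]))
    stop("reference span must equal ref_len for substitutions/deletions")
  invisible(TRUE)
}

# Split a variant GRanges by class.
.byClass <- function(gr, cls) gr[mcols(gr)$vclass == cls]
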