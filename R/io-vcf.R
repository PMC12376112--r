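# VCF 4.2 boundary. Reading goes through VariantAnnotation::readVcf;
# writing is a small text emitter (the callsets are simple biallelic
# records, and round-trip through readVcf is covered by tests).
#
# Conventions at the boundary (standard VCF anchoring):
#   SNP        POS = variant base; REF/ALT single bases.
#   insertion  POS = base before the insertion point; symbolic <INS> with
#              SVTYPE=INS, SVLEN=+len (plus sequence alleles when known).
#   deletion   POS = base before the deleted span; SVTYPE=DEL, SVLEN=-len,
#              END = last deleted base.
# Internally an insertion anchors the reference base *after* the insertion
# point (POS+1) so that every variant has a non-empty reference span.

#' Write a variant callset as VCF 4.2
#'
#' @param gr A variant `GRanges` (see [variantRanges()]); seqlengths must be
#'   set (used for the contig header lines).
#' @param path Output path (plain text `.vcf`).
#' @param ref Optional `DNAStringSet` of the reference haplotype; when
#'   given, REF/ALT allele strings are emitted for SNPs and small INDELs,
#'   otherwise placeholder/symbolic alleles are used.
#' @return Invisibly, `path`.
#' @export
writeVariantVcf <- function(gr, path, ref = NULL) {
  sl <- seqlengths(gr)
  if (anyNA(sl)) stop("variant GRanges must carry seqlengths for VCF output")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=HaploDiverge",
    sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant class: SNP, INDEL or PAV\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length difference of ALT vs REF\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant on the reference\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (!length(gr)) { writeLines(hdr, path); return(invisible(path)) }

  m <- mcols(gr)
  chrom <- as.character(seqnames(gr))
  s <- start(gr)  # 1-based internal start
  hasSeq <- all(c("ref_seq", "alt_seq") %in% names(m))
  baseAt <- function(chr, pos) {
    if (!is.null(ref)) {
      ok <- pos >= 1L
      out <- rep("N", length(pos))
      if (any(ok))
        out[ok] <- unname(vapply(which(ok), function(i)
          as.character(subseq(ref[[chr[i]]], pos[i], pos[i])), character(1L)))
      out
    } else rep("N", length(pos))
  }

  pos <- integer(length(gr)); refA <- character(length(gr))
  altA <- character(length(gr)); info <- character(length(gr))

  snp <- m$subtype == "substitution"
  if (any(snp)) {
    pos[snp] <- s[snp]
    refA[snp] <- if (hasSeq) m$ref_seq[snp] else baseAt(chrom[snp], s[snp])
    altA[snp] <- if (hasSeq) m$alt_seq[snp] else "N"
    info[snp] <- "VT=SNP"
  }
  ins <- m$subtype == "insertion"
  if (any(ins)) {
    idx <- which(ins)
    anchor <- baseAt(chrom[idx], s[idx] - 1L)
    pos[idx] <- s[idx] - 1L
    refA[idx] <- anchor
    altA[idx] <- "<INS>"
    if (hasSeq && !is.null(ref)) {
      small <- m$vclass[idx] == "INDEL" & !is.na(m$alt_seq[idx])
      altA[idx[small]] <- paste0(anchor[small], m$alt_seq[idx[small]])
    }
    info[idx] <- sprintf("VT=%s;SVTYPE=INS;SVLEN=%d;END=%d",
                         m$vclass[idx], m$alt_len[idx], s[idx] - 1L)
  }
  del <- m$subtype == "deletion"
  if (any(del)) {
    pos[del] <- s[del] - 1L
    refA[del] <- baseAt(chrom[del], s[del] - 1L)
    altA[del] <- "<DEL>"
    info[del] <- sprintf("VT=%s;SVTYPE=DEL;SVLEN=%d;END=%d",
                         m$vclass[del], -m$ref_len[del],
                         s[del] + m$ref_len[del] - 1L)
  }
  body <- paste(chrom, pos, ".", refA, altA, ".", ".", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant callset from VCF
#'
#' Understands both the records this package writes (INFO key `VT`) and
#' generic biallelic VCFs: classes are then derived from REF/ALT lengths,
#' or from `SVTYPE`/`SVLEN`/`END` for symbolic alleles. Coordinates are
#' converted to the internal anchoring (insertions anchored on the base
#' after the insertion point).
#'
#' @param path Path to a VCF file.
#' @param source Source tag to stamp on the records (`"wga"`, `"read"`,
#'   `"truth"`).
#' @param pav_min PAV length floor used for classification (bp).
#' @return A variant `GRanges` (see [variantRanges()]).
#' @export
readVariantVcf <- function(path, source = "read", pav_min = 50L) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  sl <- seqlengths(rr)
  if (!n)
    return(variantRanges(character(), integer(), integer(), integer(),
                         character(), character(), seqlengths = sl,
                         pav_min = pav_min))
  refA <- as.character(rr$REF)
  altA <- as.character(rr$ALT)
  pos <- start(rr)
  symbolic <- grepl("^<", altA)

  svlen <- rep(NA_integer_, n)
  if ("SVLEN" %in% names(info)) {
    v <- info$SVLEN
    if (is.list(v) || is(v, "List"))
      v <- vapply(v, function(z) if (length(z)) as.integer(z[[1L]]) else NA_integer_,
                  integer(1L))
    svlen <- as.integer(v)
  }
  svtype <- rep(NA_character_, n)
  if ("SVTYPE" %in% names(info)) svtype <- as.character(info$SVTYPE)

  ref_len <- nchar(refA); alt_len <- nchar(altA)
  subtype <- character(n); istart <- integer(n)
  rl <- integer(n); al <- integer(n)
  rseq <- rep(NA_character_, n); aseq <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (symbolic[i]) {
      if (is.na(svtype[i]) || is.na(svlen[i]))
        stop("symbolic ALT without SVTYPE/SVLEN at record ", i)
      if (svtype[i] == "INS") {
        subtype[i] <- "insertion"; istart[i] <- pos[i] + 1L
        rl[i] <- 0L; al[i] <- abs(svlen[i])
      } else if (svtype[i] == "DEL") {
        subtype[i] <- "deletion"; istart[i] <- pos[i] + 1L
        rl[i] <- abs(svlen[i]); al[i] <- 0L
      } else stop("unsupported SVTYPE ", svtype[i], " at record ", i)
    } else if (ref_len[i] == 1L && alt_len[i] == 1L) {
      subtype[i] <- "substitution"; istart[i] <- pos[i]
      rl[i] <- 1L; al[i] <- 1L
      rseq[i] <- refA[i]; aseq[i] <- altA[i]
    } else if (ref_len[i] < alt_len[i] && ref_len[i] == 1L) {
      subtype[i] <- "insertion"; istart[i] <- pos[i] + 1L
      rl[i] <- 0L; al[i] <- alt_len[i] - 1L
      aseq[i] <- substring(altA[i], 2L)
    } else if (alt_len[i] < ref_len[i] && alt_len[i] == 1L) {
      subtype[i] <- "deletion"; istart[i] <- pos[i] + 1L
      rl[i] <- ref_len[i] - 1L; al[i] <- 0L
      rseq[i] <- substring(refA[i], 2L)
    } else {
      stop("unsupported complex allele at record ", i,
           " (REF ", refA[i], ", ALT ", altA[i], ")")
    }
  }
  variantRanges(as.character(seqnames(rr)), istart, rl, al, subtype,
                source, ref_seq = rseq, alt_seq = aseq,
                seqlengths = sl, pav_min = pav_min)
}
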