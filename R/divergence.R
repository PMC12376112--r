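# Inter-haplotype divergence: extract variants from whole-genome-alignment
# CIGARs, intersect with a read-based callset under the concordance rules
# (exact start for SNPs/INDELs; overlap-or-10-bp-slack for PAVs), filter
# gap-containing PAVs, and compute per-window sequence identity:
#
#   identity = (W - common-variant bp - gap bp - unaligned bp) / W
#
# with all masked categories counted once on a per-base union, W the window
# width (100 kb by default; the last window of a sequence may be shorter).

#' Extract variants from alignment CIGARs
#'
#' Walks `=`/`X`/`I`/`D` CIGAR runs on reference (target) coordinates.
#' An `X` run of length k yields k SNPs; `I`/`D` runs shorter than
#' `pav_min_bp` yield small INDELs, longer runs yield PAVs. `M` is rejected
#' as ambiguous. The unaligned track is the complement of all
#' target-aligned intervals on each reference sequence.
#'
#' Allele sequences are captured when both `ref` and `query` sequences are
#' supplied and the record is on the `+` strand.
#'
#' @param paf Alignment table from [readPaf()]; records without CIGAR are
#'   skipped with a message.
#' @param ref_lengths Named vector of reference (target) sequence lengths.
#' @param ref,query Optional `DNAStringSet`s for allele capture.
#' @param config A [DivergenceConfig-class].
#' @return A list with `variants` (variant `GRanges`, source `"wga"`) and
#'   `unaligned` (`GRanges` of reference intervals covered by no
#'   alignment).
#' @export
callVariantsFromAlignment <- function(paf, ref_lengths, ref = NULL,
                                      query = NULL,
                                      config = divergenceConfig()) {
  if (any(!paf$has_cigar))
    message(sum(!paf$has_cigar),
            " alignment record(s) without CIGAR skipped for variant ",
            "extraction (still usable for coverage)")
  paf <- paf[paf$has_cigar, , drop = FALSE]
  recs <- vector("list", nrow(paf))
  for (i in seq_len(nrow(paf))) {
    cig <- parseCigar(paf$cigar[i])
    if (any(!cig$op %in% c("=", "X", "I", "D")))
      stop("CIGAR op '", setdiff(cig$op, c("=", "X", "I", "D"))[1L],
           "' unsupported for variant extraction; generate =/X CIGARs ",
           "(e.g. minimap2 --eqx)")
    recs[[i]] <- .extractFromCigar(paf[i, ], cig, ref, query,
                                   config@pav_min_bp)
  }
  ev <- rbindlist(recs)
  sl <- ref_lengths[sort(names(ref_lengths))]
  variants <- if (nrow(ev)) variantRanges(
    ev$seq_id, ev$start, ev$ref_len, ev$alt_len, ev$subtype, "wga",
    ref_seq = ev$ref_seq, alt_seq = ev$alt_seq,
    seqlengths = sl, pav_min = config@pav_min_bp)
  else variantRanges(character(), integer(), integer(), integer(),
                     character(), character(), seqlengths = sl,
                     pav_min = config@pav_min_bp)
  aligned <- GRanges(paf$target_id,
                     IRanges(paf$target_start + 1L, paf$target_end),
                     seqlengths = sl)
  full <- GRanges(names(sl), IRanges(1L, unname(sl)), seqlengths = sl)
  unaligned <- GenomicRanges::setdiff(full, reduce(aligned))
  list(variants = variants, unaligned = unaligned)
}

# One PAF record -> data.table of variant fields (1-based internal starts).
.extractFromCigar <- function(rec, cig, ref, query, pav_min) {
  len <- cig$len; op <- cig$op
  tcons <- ifelse(op %in% c("=", "X", "D"), len, 0L)
  qcons <- ifelse(op %in% c("=", "X", "I"), len, 0L)
  t0 <- rec$target_start + cumsum(c(0L, tcons[-length(tcons)]))  # 0-based
  q0 <- rec$query_start + cumsum(c(0L, qcons[-length(qcons)]))
  alleles <- !is.null(ref) && !is.null(query) && rec$strand == "+"
  rs <- character(); as_ <- character()
  out <- list()

  ix <- which(op == "X")
  if (length(ix)) {
    n <- sum(len[ix])
    starts0 <- rep(t0[ix], len[ix]) + sequence(len[ix]) - 1L
    snp <- data.table(seq_id = rec$target_id, start = starts0 + 1L,
                      ref_len = 1L, alt_len = 1L, subtype = "substitution",
                      ref_seq = NA_character_, alt_seq = NA_character_)
    if (alleles) {
      qstarts0 <- rep(q0[ix], len[ix]) + sequence(len[ix]) - 1L
      snp$ref_seq <- .basesAt(ref[[rec$target_id]], starts0 + 1L)
      snp$alt_seq <- .basesAt(query[[rec$query_id]], qstarts0 + 1L)
    }
    out[[length(out) + 1L]] <- snp
  }
  ii <- which(op == "I")
  if (length(ii)) {
    insv <- data.table(seq_id = rec$target_id, start = t0[ii] + 1L,
                       ref_len = 0L, alt_len = len[ii],
                       subtype = "insertion",
                       ref_seq = NA_character_, alt_seq = NA_character_)
    if (alleles)
      insv$alt_seq <- vapply(seq_along(ii), function(k)
        as.character(subseq(query[[rec$query_id]], q0[ii[k]] + 1L,
                            q0[ii[k]] + len[ii[k]])), character(1L))
    out[[length(out) + 1L]] <- insv
  }
  id <- which(op == "D")
  if (length(id)) {
    delv <- data.table(seq_id = rec$target_id, start = t0[id] + 1L,
                       ref_len = len[id], alt_len = 0L,
                       subtype = "deletion",
                       ref_seq = NA_character_, alt_seq = NA_character_)
    if (alleles)
      delv$ref_seq <- vapply(seq_along(id), function(k)
        as.character(subseq(ref[[rec$target_id]], t0[id[k]] + 1L,
                            t0[id[k]] + len[id[k]])), character(1L))
    out[[length(out) + 1L]] <- delv
  }
  rbindlist(out)
}

.basesAt <- function(seq, pos1)
  as.character(Biostrings::extractAt(seq, IRanges(pos1, pos1)))

#' Find assembly gaps (N runs)
#'
#' @param seqs A `DNAStringSet` (uppercase-normalized internally).
#' @param config A [DivergenceConfig-class]; runs shorter than
#'   `min_gap_run` are ignored.
#' @return A `GRanges` of maximal N runs.
#' @export
findGaps <- function(seqs, config = divergenceConfig()) {
  sl <- setNames(Biostrings::width(seqs), names(seqs))
  hits <- vmatchPattern("N", DNAStringSet(toupper(seqs)))
  per <- lapply(seq_along(seqs), function(i) {
    r <- reduce(hits[[i]])
    r[width(r) >= config@min_gap_run]
  })
  gr <- GRanges(rep(names(seqs), lengths(per)),
                unlist(IRanges::IRangesList(per)), seqlengths = sl)
  unname(gr)
}

#' Match point variants (SNPs or small INDELs) between two callsets
#'
#' Two variants are common iff they are of the same class and share the
#' exact start position (same reference sequence). Allele agreement is not
#' required unless `strict = TRUE` (then REF/ALT sequences, where present
#' on both sides, must agree). The returned records are the
#' whole-genome-alignment copies, sorted.
#'
#' @param wga,read Variant `GRanges` callsets on the same reference.
#' @param vclass `"SNP"` or `"INDEL"`.
#' @param strict Require allele agreement when sequences are available.
#' @return The common variants as a sorted `GRanges` (wga copies).
#' @export
matchPointVariants <- function(wga, read, vclass = c("SNP", "INDEL"),
                               strict = FALSE) {
  vclass <- match.arg(vclass)
  a <- .byClass(wga, vclass); b <- .byClass(read, vclass)
  if (!length(a) || !length(b)) return(a[0])
  keyA <- paste0(seqnames(a), ":", start(a))
  keyB <- paste0(seqnames(b), ":", start(b))
  hit <- keyA %in% keyB
  if (strict) {
    mB <- match(keyA, keyB)
    sa <- mcols(a)$alt_seq; sb <- mcols(b)$alt_seq[mB]
    cmp <- !is.na(sa) & !is.na(sb)
    hit <- hit & (!cmp | sa == sb)
  }
  sort(a[hit])
}

#' Match PAVs between two callsets under the slack rule
#'
#' PAV a matches PAV b iff their reference spans overlap, or the start of
#' one lies within `pav_match_slack_bp` bp downstream of the end of the
#' other (both directions; the rule is symmetric). Each wga PAV is
#' reported at most once.
#'
#' @param wga,read Variant `GRanges` callsets.
#' @param config A [DivergenceConfig-class].
#' @return The common PAVs as a sorted `GRanges` (wga copies).
#' @export
matchPavs <- function(wga, read, config = divergenceConfig()) {
  a <- .byClass(wga, "PAV"); b <- .byClass(read, "PAV")
  if (!length(a) || !length(b)) return(a[0])
  hits <- findOverlaps(a, b, maxgap = config@pav_match_slack_bp)
  sort(a[unique(queryHits(hits))])
}

#' Remove PAVs whose span contains an assembly gap
#'
#' @param pavs PAV `GRanges`.
#' @param gaps Gap `GRanges` (from [findGaps()]).
#' @return The PAVs sharing no base with any gap.
#' @export
filterGapPavs <- function(pavs, gaps) {
  if (!length(pavs) || !length(gaps)) return(pavs)
  pavs[!overlapsAny(pavs, gaps)]
}

#' Intersect two callsets under the concordance rules
#'
#' Applies [matchPointVariants()] per point class, [matchPavs()] for PAVs,
#' then [filterGapPavs()].
#'
#' @param wga,read Variant `GRanges` callsets.
#' @param gaps Gap `GRanges` on the reference haplotype.
#' @param config A [DivergenceConfig-class].
#' @param strict Passed to [matchPointVariants()].
#' @return A [ConcordanceResult-class].
#' @export
concordantVariants <- function(wga, read, gaps = GRanges(),
                               config = divergenceConfig(),
                               strict = FALSE) {
  new("ConcordanceResult",
      snps = matchPointVariants(wga, read, "SNP", strict),
      indels = matchPointVariants(wga, read, "INDEL", strict),
      pavs = filterGapPavs(matchPavs(wga, read, config), gaps))
}

#' Windowed sequence identity between haplotypes
#'
#' Tiles each reference sequence into `window_bp` windows (the last window
#' of a sequence may be shorter) and computes, per window,
#' `identity = (W_eff - masked) / W_eff` where `masked` is the union of
#' common-variant reference spans, gap intervals and unaligned intervals
#' clipped to the window — bases in several categories count once.
#'
#' @param ref_lengths Named vector of reference sequence lengths.
#' @param variants Common-variant `GRanges` (reference spans mask;
#'   an insertion masks only its 1-bp anchor).
#' @param gaps,unaligned Mask `GRanges` on reference coordinates.
#' @param config A [DivergenceConfig-class].
#' @return A `GRanges` of windows with mcols variant_bp, gap_bp,
#'   unaligned_bp (each clipped per-category unions), masked_bp (the
#'   overall union) and identity in [0, 1].
#' @export
windowIdentity <- function(ref_lengths, variants, gaps = GRanges(),
                           unaligned = GRanges(),
                           config = divergenceConfig()) {
  win <- tileWindows(ref_lengths, config@window_bp)
  # strip mcols and harmonize seqlevels with the reference universe; a mask
  # on an unknown sequence is an input error surfaced here
  toGr <- function(g) {
    gr <- GRanges(as.character(seqnames(g)), ranges(g))
    seqlevels(gr) <- seqlevels(win)
    gr
  }
  vg <- toGr(variants); gg <- toGr(gaps); ug <- toGr(unaligned)
  mcols(win)$variant_bp <- .windowOverlapBp(win, vg)
  mcols(win)$gap_bp <- .windowOverlapBp(win, gg)
  mcols(win)$unaligned_bp <- .windowOverlapBp(win, ug)
  mcols(win)$masked_bp <- .windowOverlapBp(win, c(vg, gg, ug))
  w_eff <- width(win)
  mcols(win)$identity <- pmin(1, pmax(0, (w_eff - mcols(win)$masked_bp) /
                                       w_eff))
  win
}

#' Run the full divergence pipeline on files
#'
#' Calls variants from the whole-genome alignment, optionally intersects
#' them with a read-based callset, filters gap-containing PAVs, and writes
#' the window-identity track. With no read callset the WGA calls are used
#' directly (gap-PAV filtering still applies).
#'
#' @param ref_fa Reference haplotype FASTA (identity axis).
#' @param paf_path Whole-genome alignment PAF with `=`/`X` CIGARs.
#' @param query_fa Optional query haplotype FASTA (allele capture).
#' @param read_vcf Optional read-based callset VCF.
#' @param wga_vcf Optional precomputed WGA callset VCF (bypasses CIGAR
#'   extraction; the unaligned track is still computed from the PAF).
#' @param config A [DivergenceConfig-class].
#' @param out_dir Output directory, or `NULL` to skip writing. Writes
#'   `common_variants.vcf`, `gaps.bed`, `unaligned.bed`,
#'   `window_identity.bed` (BED4: identity) and `window_identity.tsv`
#'   (per-category masked bp).
#' @return A list with `variants` (the common set used), `windows`,
#'   `gaps`, `unaligned`, and `concordance` (`NULL` without a read
#'   callset).
#' @export
runDivergence <- function(ref_fa, paf_path, query_fa = NULL,
                          read_vcf = NULL, wga_vcf = NULL,
                          config = divergenceConfig(), out_dir = NULL) {
  ref <- readDNAStringSet(ref_fa)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref_lengths <- setNames(Biostrings::width(ref), names(ref))
  query <- if (!is.null(query_fa)) {
    q <- readDNAStringSet(query_fa); names(q) <- sub("\\s.*$", "", names(q)); q
  }
  paf <- readPaf(paf_path)
  wga <- callVariantsFromAlignment(paf, ref_lengths, ref = ref,
                                   query = query, config = config)
  wgaVars <- if (!is.null(wga_vcf))
    readVariantVcf(wga_vcf, source = "wga", pav_min = config@pav_min_bp)
  else wga$variants
  gaps <- findGaps(ref, config)
  conc <- NULL
  if (!is.null(read_vcf)) {
    readVars <- readVariantVcf(read_vcf, source = "read",
                               pav_min = config@pav_min_bp)
    conc <- concordantVariants(wgaVars, readVars, gaps, config)
    used <- sort(c(commonSnps(conc), commonIndels(conc), commonPavs(conc)))
  } else {
    used <- sort(c(.byClass(wgaVars, "SNP"), .byClass(wgaVars, "INDEL"),
                   filterGapPavs(.byClass(wgaVars, "PAV"), gaps)))
  }
  win <- windowIdentity(ref_lengths, used, gaps, wga$unaligned, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sl <- ref_lengths
    u <- used
    seqlevels(u) <- names(sl); seqlengths(u) <- sl
    writeVariantVcf(u, file.path(out_dir, "common_variants.vcf"), ref = ref)
    writeBed(gaps, file.path(out_dir, "gaps.bed"))
    writeBed(wga$unaligned, file.path(out_dir, "unaligned.bed"))
    writeBed(win, file.path(out_dir, "window_identity.bed"),
             score_col = "identity")
    .writeTsv(as.data.frame(win), file.path(out_dir, "window_identity.tsv"))
  }
  list(variants = used, windows = win, gaps = gaps,
       unaligned = wga$unaligned, concordance = conc)
}
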