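# Truth-labelled heterozygous diploid simulator. Haplotype 2 is derived
# from a random haplotype 1 by planting non-overlapping substitutions,
# small INDELs and large PAVs; the planted set IS the truth callset, and
# the simulator also emits the derived artefacts every downstream stage
# consumes: primary contigs tiling h1, redundant haplotigs sampled from h2,
# gene anchors and marker hits on allelic pairs, exact all-by-all PAF
# alignments with CIGARs, and two noisy variant callsets.
#
# One global seed feeds named substreams (genome, mutate, fragment, genes,
# paf, callsets) so changing one stage's parameters does not perturb
# another stage's draws.

.substreamSeed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h * 4721 + 1) %%
               (.Machine$integer.max - 1))
}

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(L)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, L, replace = TRUE)])

# Chromosome lengths: near-equal partition of genome_bp.
.chromLengths <- function(params) {
  n <- params@n_chroms
  base <- floor(params@genome_bp / n)
  lens <- rep(base, n)
  lens[1L] <- lens[1L] + params@genome_bp - base * n
  setNames(as.integer(lens), paste0("chr", seq_len(n)))
}

# ---- event placement ------------------------------------------------------

# Place `widths` non-overlapping event spans on a sequence of length L,
# avoiding `margin` bp at both ends and any already-occupied base.
# Rejection sampling in vectorized rounds; returns 1-based starts in input
# order and the updated occupancy.
.placeEvents <- function(L, widths, occupied, margin = 200L,
                         maxRounds = 200L) {
  n <- length(widths)
  starts <- integer(n)
  pending <- seq_len(n)
  if (any(L - 2L * margin - widths + 1L < 1L))
    stop("simulation error: events do not fit the sequence; ",
         "lower the rates or event lengths")
  for (round in seq_len(maxRounds)) {
    if (!length(pending)) break
    w <- widths[pending]
    cum <- c(0L, cumsum(occupied))
    cand <- margin + 1L + floor(runif(length(w)) * (L - 2L * margin - w + 1))
    free <- (cum[cand + w] - cum[cand]) == 0L
    ir <- IRanges(cand, width = w)
    hits <- findOverlaps(ir, ir)
    clash <- unique(queryHits(hits)[queryHits(hits) > subjectHits(hits)])
    ok <- free
    ok[clash] <- FALSE
    if (any(ok)) {
      acc <- pending[ok]
      starts[acc] <- cand[ok]
      occupied[rep(cand[ok], w[ok]) + sequence(w[ok]) - 1L] <- TRUE
      pending <- pending[!ok]
    }
  }
  if (length(pending))
    stop("simulation error: could not place ", length(pending),
         " events after ", maxRounds, " rounds; lower the rates")
  list(starts = starts, occupied = occupied)
}

# Occupied bases of an event table on one chromosome (1-based starts `s`).
# Blocking width: ref span for substitutions, anchor base for insertions;
# deletions block one extra spacer base so no event starts flush after a
# deletion end — adjacent deletions would otherwise fuse into a single
# CIGAR run and stop being two distinct variants.
.blockWidth <- function(ev)
  ifelse(ev$subtype == "deletion", ev$ref_len + 1L, 1L)

.occupancyFromEvents <- function(L, ev) {
  occ <- logical(L)
  if (nrow(ev)) {
    w <- .blockWidth(ev)
    occ[rep(ev$s, w) + sequence(w) - 1L] <- TRUE
  }
  occ
}

# ---- mutate ---------------------------------------------------------------

#' Derive haplotype 2 by planting variants on haplotype 1
#'
#' Plants non-overlapping substitutions (at `snp_rate` per bp), small
#' INDELs and large PAVs (per-bp event rates; lengths uniform in the
#' configured ranges, insertion/deletion equiprobable). Event counts are
#' binomial draws per chromosome; rejection sampling re-places rejected
#' events so realized counts equal the draws. Deterministic under the seed.
#'
#' @param h1 Haplotype 1 as a `DNAStringSet`.
#' @param params A [SimParams-class].
#' @return A list with `h2` (`DNAStringSet`, names suffixed `_h2`),
#'   `truth` (variant `GRanges` on h1 coordinates, source `"truth"`, with
#'   allele sequences), and `events` (internal per-chromosome table).
#' @export
mutateHaplotype <- function(h1, params) {
  set.seed(.substreamSeed(params@seed, "mutate"))
  evs <- list()
  for (chr in names(h1)) {
    L <- Biostrings::width(h1)[match(chr, names(h1))]
    seqc <- as.character(h1[[chr]])
    n_pav <- rbinom(1L, L, params@pav_rate)
    n_ind <- rbinom(1L, L, params@indel_rate)
    n_snp <- rbinom(1L, L, params@snp_rate)

    pav_len <- sample(params@pav_len_range[1L]:params@pav_len_range[2L],
                      n_pav, replace = TRUE)
    pav_del <- runif(n_pav) < 0.5
    ind_len <- sample(params@indel_len_range[1L]:params@indel_len_range[2L],
                      n_ind, replace = TRUE)
    ind_del <- runif(n_ind) < 0.5

    subtype <- c(ifelse(pav_del, "deletion", "insertion"),
                 ifelse(ind_del, "deletion", "insertion"),
                 rep("substitution", n_snp))
    ref_len <- c(ifelse(pav_del, pav_len, 0L),
                 ifelse(ind_del, ind_len, 0L), rep(1L, n_snp))
    alt_len <- c(ifelse(pav_del, 0L, pav_len),
                 ifelse(ind_del, 0L, ind_len), rep(1L, n_snp))
    block <- ifelse(subtype == "deletion", as.integer(ref_len) + 1L, 1L)

    # place wide events first (PAVs, then INDELs, then SNPs): narrow events
    # pepper the sequence and would otherwise starve wide spans
    grp <- rep(1:3, c(n_pav, n_ind, n_snp))
    starts <- integer(length(block))
    occ <- logical(L)
    for (g in 1:3) {
      sel <- grp == g
      if (!any(sel)) next
      pl <- .placeEvents(L, block[sel], occ)
      starts[sel] <- pl$starts
      occ <- pl$occupied
    }
    ev <- data.table(seq_id = chr, s = starts, subtype = subtype,
                     ref_len = as.integer(ref_len),
                     alt_len = as.integer(alt_len))
    setorder(ev, s)
    # allele sequences
    ev[, ref_seq := NA_character_]
    ev[, alt_seq := NA_character_]
    del <- ev$subtype == "deletion"
    if (any(del))
      ev$ref_seq[del] <- substring(seqc, ev$s[del],
                                   ev$s[del] + ev$ref_len[del] - 1L)
    ins <- ev$subtype == "insertion"
    if (any(ins))
      ev$alt_seq[ins] <- vapply(ev$alt_len[ins], .randSeq, character(1L))
    sub <- ev$subtype == "substitution"
    if (any(sub)) {
      refb <- substring(seqc, ev$s[sub], ev$s[sub])
      ri <- match(refb, .BASES)
      off <- sample.int(3L, length(refb), replace = TRUE)
      ev$ref_seq[sub] <- refb
      ev$alt_seq[sub] <- .BASES[((ri - 1L + off) %% 4L) + 1L]
    }
    evs[[chr]] <- ev
  }
  events <- rbindlist(evs)
  h2 <- .applyEvents(h1, events)
  truth <- .eventsToVariants(events, setNames(Biostrings::width(h1),
                                              names(h1)),
                             params@pav_len_range[1L])
  list(h2 = h2, truth = truth, events = events)
}

# Apply a sorted event table to h1, producing h2.
.applyEvents <- function(h1, events) {
  out <- character(length(h1))
  for (i in seq_along(h1)) {
    chr <- names(h1)[i]
    seqc <- as.character(h1[[i]])
    ev <- events[events$seq_id == chr, ]
    if (!nrow(ev)) { out[i] <- seqc; next }
    cons <- ifelse(ev$subtype == "deletion", ev$ref_len,
                   ifelse(ev$subtype == "substitution", 1L, 0L))
    L <- nchar(seqc)
    keep_start <- c(1L, ev$s + cons)
    keep_end <- c(ev$s - 1L, L)
    alt <- ifelse(ev$subtype == "deletion", "",
                  ifelse(is.na(ev$alt_seq), "", ev$alt_seq))
    n <- nrow(ev)
    pieces <- character(2L * n + 1L)
    pieces[seq(1L, 2L * n + 1L, by = 2L)] <- substring(seqc, keep_start,
                                                       keep_end)
    pieces[seq(2L, 2L * n, by = 2L)] <- alt
    out[i] <- paste(pieces, collapse = "")
  }
  h2 <- DNAStringSet(out)
  names(h2) <- paste0(names(h1), "_h2")
  h2
}

.eventsToVariants <- function(events, seqlengths, pav_min) {
  variantRanges(events$seq_id, events$s, events$ref_len, events$alt_len,
                events$subtype, "truth",
                ref_seq = events$ref_seq, alt_seq = events$alt_seq,
                seqlengths = seqlengths, pav_min = pav_min)
}

#' Reconstruct haplotype 2 from haplotype 1 and a truth callset
#'
#' The constructive inverse of [mutateHaplotype()]: applying the planted
#' variants to haplotype 1 must reproduce haplotype 2 exactly.
#'
#' @param h1 Haplotype 1 `DNAStringSet`.
#' @param truth A variant `GRanges` with `ref_seq`/`alt_seq` mcols.
#' @return A `DNAStringSet` (names suffixed `_h2`).
#' @export
applyVariants <- function(h1, truth) {
  m <- mcols(truth)
  events <- data.table(seq_id = as.character(seqnames(truth)),
                       s = start(truth), subtype = m$subtype,
                       ref_len = m$ref_len, alt_len = m$alt_len,
                       ref_seq = m$ref_seq, alt_seq = m$alt_seq)
  setorder(events, seq_id, s)
  .applyEvents(h1, events)
}

# h1 -> h2 coordinate shift: positions p (1-based, outside deleted spans)
# map to p + cumulative indel delta of all events entirely left of p.
.h1ToH2Map <- function(ev) {
  if (!nrow(ev)) return(function(p) p)
  thr <- ifelse(ev$subtype == "insertion", ev$s,
                ev$s + ifelse(ev$subtype == "deletion", ev$ref_len, 1L))
  delta <- ev$alt_len - ifelse(ev$subtype == "substitution", 1L,
                               ifelse(ev$subtype == "deletion",
                                      ev$ref_len, 0L))
  # substitutions have delta 0; keep only shifting events
  keep <- delta != 0L
  thr <- thr[keep]; delta <- delta[keep]
  o <- order(thr)
  thr <- thr[o]; cd <- cumsum(delta[o])
  function(p) {
    i <- findInterval(p, thr)
    p + ifelse(i > 0L, cd[pmax(i, 1L)], 0L)
  }
}

# Snap a 1-based boundary position b to the nearest position with
# occupied[b-1] and occupied[b] both free (no event span crosses or starts
# at the cut).
.snapFree <- function(b, occupied, lo, hi) {
  L <- length(occupied)
  isFree <- function(x) x > lo && x < hi && !occupied[x - 1L] && !occupied[x]
  if (isFree(b)) return(b)
  for (d in seq_len(L)) {
    if (isFree(b - d)) return(b - d)
    if (isFree(b + d)) return(b + d)
  }
  stop("simulation error: no event-free breakpoint available")
}

# ---- CIGAR from planted events -------------------------------------------

# Exact CIGAR of the h2-vs-h1 alignment over the h1 span [a, b] (1-based,
# both boundaries event-free). Returns list(cigar, n_match, aln_len,
# qlen, tlen).
.cigarFromEvents <- function(ev, a, b) {
  ev <- ev[ev$s >= a & ev$s <= b, , drop = FALSE]
  cons <- ifelse(ev$subtype == "deletion", ev$ref_len,
                 ifelse(ev$subtype == "substitution", 1L, 0L))
  n <- nrow(ev)
  op <- character(3L * n + 1L); len <- integer(3L * n + 1L)
  cursor <- a
  k <- 0L
  for (i in seq_len(n)) {
    mrun <- ev$s[i] - cursor
    k <- k + 1L; op[k] <- "="; len[k] <- mrun
    k <- k + 1L
    if (ev$subtype[i] == "substitution") { op[k] <- "X"; len[k] <- 1L }
    else if (ev$subtype[i] == "deletion") { op[k] <- "D"; len[k] <- ev$ref_len[i] }
    else { op[k] <- "I"; len[k] <- ev$alt_len[i] }
    cursor <- ev$s[i] + cons[i]
  }
  k <- k + 1L; op[k] <- "="; len[k] <- b - cursor + 1L
  op <- op[seq_len(k)]; len <- len[seq_len(k)]
  list(cigar = buildCigar(len, op),
       n_match = sum(len[op == "="]),
       aln_len = sum(len),
       qlen = sum(len[op %in% c("=", "X", "I")]),
       tlen = sum(len[op %in% c("=", "X", "D")]))
}

# ---- full scene -----------------------------------------------------------

#' Simulate a truth-labelled heterozygous diploid dataset
#'
#' Generates a random haplotype 1, derives haplotype 2 via
#' [mutateHaplotype()], tiles haplotype 1 into primary contigs, samples
#' strictly-shorter redundant haplotigs from haplotype 2 (each overlapping
#' exactly one primary), plants collinear gene anchors and single-copy
#' complete markers on each allelic pair, emits exact PAF alignments
#' (haplotig-vs-primary and whole-haplotype) with `=`/`X` CIGARs, and
#' produces two noisy callsets via [emitNoisyCallsets()].
#'
#' @param params A [SimParams-class].
#' @return A [DiploidSim-class].
#' @export
simulateDiploid <- function(params = simParams()) {
  set.seed(.substreamSeed(params@seed, "genome"))
  lens <- .chromLengths(params)
  h1 <- DNAStringSet(vapply(lens, .randSeq, character(1L)))
  names(h1) <- names(lens)

  mut <- mutateHaplotype(h1, params)
  h2 <- mut$h2
  events <- mut$events

  frag <- .fragmentWithRedundancy(h1, h2, events, params)
  gm <- .plantGenesAndMarkers(frag$labels, events, params)
  paf <- .emitPaf(frag$labels, events, params,
                  setNames(Biostrings::width(frag$contigs),
                           names(frag$contigs)))
  hap_paf <- .emitHapPaf(h1, h2, events)
  cs <- emitNoisyCallsets(mut$truth, params)

  new("DiploidSim", h1 = h1, h2 = h2, contigs = frag$contigs,
      truth = mut$truth, labels = frag$labels, anchors = gm$anchors,
      matches = gm$matches, markers = gm$markers,
      alignments = paf, hap_alignments = hap_paf,
      callset_wga = cs$wga, callset_read = cs$read, params = params)
}

# Tile h1 into primaries; sample haplotigs from h2, each a strictly
# shorter sub-interval of one primary's allelic region.
.fragmentWithRedundancy <- function(h1, h2, events, params) {
  set.seed(.substreamSeed(params@seed, "fragment"))
  lens <- setNames(Biostrings::width(h1), names(h1))
  # primaries per chromosome, proportional with largest remainder
  share <- lens / sum(lens) * params@n_primary_contigs
  k <- floor(share)
  k[k < 1] <- 1
  while (sum(k) < params@n_primary_contigs)
    k[which.max(share - k)] <- k[which.max(share - k)] + 1L
  while (sum(k) > params@n_primary_contigs)
    k[which.max(k)] <- k[which.max(k)] - 1L

  labels <- list(); contigs <- character(); p_i <- 0L
  for (chr in names(h1)) {
    L <- lens[[chr]]
    ev <- events[events$seq_id == chr, ]
    occ <- .occupancyFromEvents(L, ev)
    nseg <- k[[chr]]
    step <- L / nseg
    cuts <- if (nseg > 1L)
      vapply(seq_len(nseg - 1L), function(j) {
        b <- round(j * step + runif(1L, -0.1, 0.1) * step)
        .snapFree(as.integer(b), occ, lo = 1L, hi = L)
      }, integer(1L))
    else integer()
    bounds <- c(1L, sort(cuts), L + 1L)
    for (j in seq_len(nseg)) {
      p_i <- p_i + 1L
      id <- sprintf("p%03d", p_i)
      s <- bounds[j]; e <- bounds[j + 1L] - 1L
      contigs[id] <- substring(as.character(h1[[chr]]), s, e)
      labels[[id]] <- data.frame(
        contig_id = id, label = "primary", partner_id = NA_character_,
        seq_id = chr, h1_start0 = s - 1L, h1_end0 = e,
        h2_start0 = NA_integer_, h2_end0 = NA_integer_, inverted = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL

  if (params@n_haplotigs > 0L) {
    plen <- labels$h1_end0 - labels$h1_start0
    if (max(params@haplotig_len_range) >= min(plen))
      stop("haplotig_len_range must stay below the shortest primary contig (",
           min(plen), " bp)")
    partners <- sample(labels$contig_id, params@n_haplotigs)
    maps <- lapply(names(h1), function(chr)
      .h1ToH2Map(events[events$seq_id == chr, ]))
    names(maps) <- names(h1)
    occs <- lapply(names(h1), function(chr)
      .occupancyFromEvents(lens[[chr]],
                           events[events$seq_id == chr, ]))
    names(occs) <- names(h1)
    inverted <- runif(params@n_haplotigs) < 0.2
    hap_rows <- list()
    for (i in seq_len(params@n_haplotigs)) {
      pid <- partners[i]
      prow <- labels[labels$contig_id == pid, ]
      chr <- prow$seq_id
      ps <- prow$h1_start0 + 1L; pe <- prow$h1_end0  # 1-based closed
      occ <- occs[[chr]]; mp <- maps[[chr]]
      hl <- sample(params@haplotig_len_range[1L]:params@haplotig_len_range[2L], 1L)
      hl <- min(hl, pe - ps - 400L)  # keep strictly inside
      off <- sample.int(pe - ps + 1L - hl, 1L) - 1L
      a <- .snapFree(ps + off, occ, lo = ps, hi = pe)
      b <- .snapFree(a + hl, occ, lo = a + 100L, hi = pe)
      # h2 span of [a, b) : boundaries are event-free so the map is exact
      h2a <- mp(a); h2b <- mp(b)
      id <- sprintf("h%03d", i)
      hseq <- substring(as.character(h2[[paste0(chr, "_h2")]]), h2a, h2b - 1L)
      stopifnot(nchar(hseq) < prow$h1_end0 - prow$h1_start0)
      contigs[id] <- hseq
      hap_rows[[id]] <- data.frame(
        contig_id = id, label = "haplotig", partner_id = pid,
        seq_id = chr, h1_start0 = a - 1L, h1_end0 = b - 1L,
        h2_start0 = h2a - 1L, h2_end0 = h2b - 1L, inverted = inverted[i],
        stringsAsFactors = FALSE)
    }
    labels <- rbind(labels, do.call(rbind, hap_rows))
    rownames(labels) <- NULL
  }
  dss <- DNAStringSet(contigs)
  list(contigs = dss, labels = labels)
}

# Plant collinear gene anchors on each primary and copy those falling
# inside a haplotig's source interval onto it (same order, or inverted for
# inverted haplotigs); plant shared single-copy complete markers per pair.
.plantGenesAndMarkers <- function(labels, events, params) {
  set.seed(.substreamSeed(params@seed, "genes"))
  gene_w <- 300L
  prim <- labels[labels$label == "primary", ]
  haps <- labels[labels$label == "haplotig", ]
  anchors <- list(); matches <- list(); markers <- list()
  for (j in seq_len(nrow(prim))) {
    p <- prim[j, ]
    plen <- p$h1_end0 - p$h1_start0
    ng <- params@n_genes
    if (ng == 0L) next
    if (plen < (gene_w + 10L) * ng)
      stop("n_genes too large for primary contig length ", plen)
    slot <- plen / (ng + 1L)
    gs <- round(seq_len(ng) * slot + runif(ng, -0.25, 0.25) * slot)
    gs <- pmin(pmax(gs, 1L), plen - gene_w - 1L)
    gs <- as.integer(sort(gs))
    # keep anchors strictly ordered even after jitter
    gs <- gs + cumsum(c(0L, pmax(0L, diff(gs) == 0L)))
    ids <- sprintf("g_%s_%02d", p$contig_id, seq_len(ng))
    anchors[[p$contig_id]] <- data.frame(
      gene_id = ids, contig_id = p$contig_id, start = gs,
      end = gs + gene_w, strand = "+", stringsAsFactors = FALSE)
  }
  for (j in seq_len(nrow(haps))) {
    h <- haps[j, ]
    pa <- anchors[[h$partner_id]]
    if (is.null(pa)) next
    prow <- prim[prim$contig_id == h$partner_id, ]
    abs_start <- prow$h1_start0 + pa$start   # 0-based chrom coords
    abs_end <- prow$h1_start0 + pa$end
    inside <- abs_start >= h$h1_start0 & abs_end <= h$h1_end0
    if (!any(inside)) next
    ev <- events[events$seq_id == h$seq_id, ]
    mp <- .h1ToH2Map(ev)
    hlen <- h$h2_end0 - h$h2_start0
    loc_start <- mp(abs_start[inside] + 1L) - 1L - h$h2_start0
    loc_end <- mp(abs_end[inside] + 1L) - 1L - h$h2_start0
    strand <- "+"
    if (h$inverted) {
      tmp <- hlen - loc_end
      loc_end <- hlen - loc_start
      loc_start <- tmp
      strand <- "-"
    }
    ids_p <- pa$gene_id[inside]
    ids_h <- paste0(ids_p, "_h")
    anchors[[h$contig_id]] <- data.frame(
      gene_id = ids_h, contig_id = h$contig_id,
      start = as.integer(loc_start), end = as.integer(loc_end),
      strand = strand, stringsAsFactors = FALSE)
    matches[[h$contig_id]] <- data.frame(gene_a = ids_p, gene_b = ids_h,
                                         stringsAsFactors = FALSE)
    if (params@n_markers > 0L) {
      mk <- sprintf("mk_%s_%02d", h$contig_id, seq_len(params@n_markers))
      markers[[h$contig_id]] <- data.frame(
        marker_id = rep(mk, 2L),
        contig_id = rep(c(h$partner_id, h$contig_id),
                        each = params@n_markers),
        status = "complete", copies = 1L, stringsAsFactors = FALSE)
    }
  }
  # one unpaired single-copy marker per primary (background completeness)
  markers[["__solo"]] <- data.frame(
    marker_id = sprintf("mk_solo_%s", prim$contig_id),
    contig_id = prim$contig_id, status = "complete", copies = 1L,
    stringsAsFactors = FALSE)
  anchors <- do.call(rbind, c(anchors, list(NULL)))
  matches <- do.call(rbind, c(matches, list(NULL)))
  markers <- do.call(rbind, c(markers, list(NULL)))
  if (is.null(anchors))
    anchors <- data.frame(gene_id = character(), contig_id = character(),
                          start = integer(), end = integer(),
                          strand = character())
  if (is.null(matches))
    matches <- data.frame(gene_a = character(), gene_b = character())
  rownames(anchors) <- NULL
  # anchor dropout on haplotig copies (noisy scene)
  if (params@anchor_dropout > 0 && nrow(matches)) {
    set.seed(.substreamSeed(params@seed, "noise"))
    drop <- runif(nrow(matches)) < params@anchor_dropout
    dropped <- matches$gene_b[drop]
    matches <- matches[!drop, , drop = FALSE]
    anchors <- anchors[!(anchors$gene_id %in% dropped), , drop = FALSE]
  }
  rownames(matches) <- NULL; rownames(markers) <- NULL
  list(anchors = anchors, matches = matches, markers = markers)
}

# Exact haplotig-vs-primary PAF records (query = haplotig on h2, target =
# partner primary on h1), optionally trimmed by aln_trim_frac.
.emitPaf <- function(labels, events, params, contig_lens) {
  haps <- labels[labels$label == "haplotig", ]
  if (!nrow(haps)) return(.emptyPaf())
  prim <- labels[labels$label == "primary", ]
  chroms <- unique(haps$seq_id)
  chromLen <- vapply(chroms, function(chr)
    max(labels$h1_end0[labels$seq_id == chr]), numeric(1L))
  occs <- lapply(chroms, function(chr)
    .occupancyFromEvents(as.integer(chromLen[[chr]]),
                         events[events$seq_id == chr, ]))
  names(occs) <- chroms
  maps <- lapply(chroms, function(chr)
    .h1ToH2Map(events[events$seq_id == chr, ]))
  names(maps) <- chroms
  rows <- list()
  for (j in seq_len(nrow(haps))) {
    h <- haps[j, ]
    prow <- prim[prim$contig_id == h$partner_id, ]
    ev <- events[events$seq_id == h$seq_id, ]
    occ <- occs[[h$seq_id]]
    mp <- maps[[h$seq_id]]
    a <- h$h1_start0 + 1L; b <- h$h1_end0   # 1-based closed h1 span
    if (params@aln_trim_frac > 0) {
      trim <- floor((b - a + 1L) * params@aln_trim_frac / 2)
      a <- .snapFree(a + trim, occ, lo = h$h1_start0, hi = b)
      b <- .snapFree(b - trim, occ, lo = a + 100L, hi = h$h1_end0 + 1L) - 1L
    }
    cg <- .cigarFromEvents(ev, a, b)
    qs <- mp(a) - 1L - h$h2_start0          # 0-based on haplotig
    qe <- mp(b + 1L) - 1L - h$h2_start0
    stopifnot(qe - qs == cg$qlen)
    rows[[j]] <- data.frame(
      query_id = h$contig_id, query_len = contig_lens[[h$contig_id]],
      query_start = qs, query_end = qe, strand = "+",
      target_id = h$partner_id, target_len = contig_lens[[h$partner_id]],
      target_start = a - 1L - prow$h1_start0,
      target_end = b - prow$h1_start0,
      n_match = cg$n_match, aln_len = cg$aln_len, mapq = 60,
      cigar = cg$cigar, has_cigar = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Whole-haplotype h2-vs-h1 alignment, one record per chromosome.
.emitHapPaf <- function(h1, h2, events) {
  rows <- lapply(seq_along(h1), function(i) {
    chr <- names(h1)[i]
    L1 <- Biostrings::width(h1)[i]
    L2 <- Biostrings::width(h2)[i]
    ev <- events[events$seq_id == chr, ]
    cg <- .cigarFromEvents(ev, 1L, L1)
    stopifnot(cg$qlen == L2, cg$tlen == L1)
    data.frame(
      query_id = paste0(chr, "_h2"), query_len = L2, query_start = 0L,
      query_end = L2, strand = "+", target_id = chr, target_len = L1,
      target_start = 0L, target_end = L1, n_match = cg$n_match,
      aln_len = cg$aln_len, mapq = 60, cigar = cg$cigar,
      has_cigar = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emit two noisy callsets from a truth set
#'
#' Each callset is the truth minus independent Bernoulli(`callset_fnr`)
#' dropouts. In the read callset, PAV positions are additionally shifted
#' by a uniform jitter in `[-pav_jitter_bp, +pav_jitter_bp]` (length
#' preserved), emulating imprecise breakpoints of read-based SV callers.
#'
#' @param truth A variant `GRanges` (source `"truth"`).
#' @param params A [SimParams-class].
#' @return A list with `wga` and `read` variant `GRanges`.
#' @export
emitNoisyCallsets <- function(truth, params) {
  set.seed(.substreamSeed(params@seed, "callsets"))
  n <- length(truth)
  keep_w <- runif(n) >= params@callset_fnr
  keep_r <- runif(n) >= params@callset_fnr
  wga <- truth[keep_w]
  if (length(wga)) mcols(wga)$source <- "wga"
  rd <- truth[keep_r]
  if (length(rd)) mcols(rd)$source <- "read"
  if (params@pav_jitter_bp > 0L && length(rd)) {
    pav <- which(mcols(rd)$vclass == "PAV")
    if (length(pav)) {
      d <- sample(seq(-params@pav_jitter_bp, params@pav_jitter_bp),
                  length(pav), replace = TRUE)
      rd[pav] <- IRanges::shift(rd[pav], d)
    }
  }
  list(wga = sort(wga), read = sort(rd))
}

#' Truth masked bases per identity window
#'
#' The per-window union length of planted variant reference spans — the
#' quantity windowed identity must recover exactly when both callsets
#' equal the truth and no sequence is unaligned.
#'
#' @param sim A [DiploidSim-class].
#' @param window_bp Window width (default 100,000).
#' @return A `GRanges` of windows with mcol `masked_bp`.
#' @export
truthWindowMasked <- function(sim, window_bp = 100000L) {
  lens <- setNames(Biostrings::width(sim@h1), names(sim@h1))
  win <- tileWindows(lens, window_bp)
  gr <- GRanges(as.character(seqnames(sim@truth)), ranges(sim@truth))
  seqlevels(gr) <- seqlevels(win)
  mcols(win)$masked_bp <- .windowOverlapBp(win, gr)
  win
}

#' Write all simulator outputs to a directory
#'
#' Emits `h1.fa`, `h2.fa`, `contigs.fa`, `truth_variants.tsv`,
#' `labels.tsv`, `anchors.tsv`, `matches.tsv`, `markers.tsv`,
#' `callset_wga.vcf`, `callset_read.vcf`, `contigs.paf`,
#' `haplotypes.paf` and `params.yaml`. Identical parameters (including
#' the seed) give byte-identical files.
#'
#' @param sim A [DiploidSim-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSimOutputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(sim@h1, file.path(dir, "h1.fa"))
  writeXStringSet(sim@h2, file.path(dir, "h2.fa"))
  writeXStringSet(sim@contigs, file.path(dir, "contigs.fa"))
  tv <- as.data.frame(sim@truth)
  .writeTsv(tv, file.path(dir, "truth_variants.tsv"))
  .writeTsv(sim@labels, file.path(dir, "labels.tsv"))
  writeAnchors(sim@anchors, file.path(dir, "anchors.tsv"))
  writeMatches(sim@matches, file.path(dir, "matches.tsv"))
  writeMarkers(sim@markers, file.path(dir, "markers.tsv"))
  writeVariantVcf(sim@callset_wga, file.path(dir, "callset_wga.vcf"),
                  ref = sim@h1)
  writeVariantVcf(sim@callset_read, file.path(dir, "callset_read.vcf"),
                  ref = sim@h1)
  writePaf(sim@alignments, file.path(dir, "contigs.paf"))
  writePaf(sim@hap_alignments, file.path(dir, "haplotypes.paf"))
  p <- sim@params
  yaml::write_yaml(list(
    genome_bp = p@genome_bp, n_chroms = p@n_chroms, snp_rate = p@snp_rate,
    indel_rate = p@indel_rate, pav_rate = p@pav_rate,
    indel_len_range = p@indel_len_range, pav_len_range = p@pav_len_range,
    n_genes = p@n_genes, n_markers = p@n_markers,
    n_primary_contigs = p@n_primary_contigs, n_haplotigs = p@n_haplotigs,
    haplotig_len_range = p@haplotig_len_range, callset_fnr = p@callset_fnr,
    pav_jitter_bp = p@pav_jitter_bp, anchor_dropout = p@anchor_dropout,
    aln_trim_frac = p@aln_trim_frac, seed = p@seed),
    file.path(dir, "params.yaml"))
  invisible(dir)
}
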