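# Haplotig purging: pair allelic contigs on three evidence channels
# (all-by-all alignment coverage, micro-synteny collinear blocks, shared
# single-copy complete markers) and purge the shorter contig of each
# qualifying pair. A contig is a haplotig of a longer contig if it fulfils
# ANY one of:
#   (1) alignment coverage of the shorter contig  > 70%
#   (2) a collinear block of                      >= 5 shared genes
#   (3) shared single-copy complete markers       >= 1
# Thresholds live in PurgeConfig.

# Orient a pair so that `short` is the purgeable side: strictly shorter, or
# lexicographically larger id on equal length (tie, logged upstream).
.orientPair <- function(a, b, lengths) {
  la <- lengths[a]; lb <- lengths[b]
  swap <- la > lb | (la == lb & a < b)
  list(short = ifelse(swap, b, a), long = ifelse(swap, a, b),
       tie = la == lb)
}

#' Alignment coverage of the shorter contig of each aligned pair
#'
#' For every ordered pair (shorter, longer) with at least one alignment,
#' coverage is the union length of the shorter contig's aligned intervals
#' (to that longer contig) divided by the shorter contig's length.
#' Self-alignments are ignored; alignments below `min_mapq` are dropped.
#'
#' @param paf Alignment table from [readPaf()] (CIGARs not required).
#' @param lengths Named vector of contig lengths.
#' @param config A [PurgeConfig-class].
#' @return A data.frame with columns short_id, long_id, coverage.
#' @export
computePairCoverage <- function(paf, lengths, config = purgeConfig()) {
  unknown <- setdiff(unique(c(paf$query_id, paf$target_id)), names(lengths))
  if (length(unknown))
    stop("alignment references unknown contig(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  paf <- paf[paf$query_id != paf$target_id & paf$mapq >= config@min_mapq, ,
             drop = FALSE]
  if (!nrow(paf))
    return(data.frame(short_id = character(), long_id = character(),
                      coverage = numeric()))
  ori <- .orientPair(paf$query_id, paf$target_id, lengths)
  shortIsQuery <- ori$short == paf$query_id
  dt <- data.table(
    short_id = ori$short, long_id = ori$long,
    s = ifelse(shortIsQuery, paf$query_start, paf$target_start),
    e = ifelse(shortIsQuery, paf$query_end, paf$target_end))
  cov <- dt[, .(coverage = sum(width(reduce(IRanges(s + 1L, e)))) /
                  lengths[[short_id[1L]]]),
            by = .(short_id, long_id)]
  as.data.frame(cov)
}

# Longest chain of matched anchors monotone in both rank orders, with
# consecutive rank gaps <= maxgap on both contigs. dir = +1 (same
# orientation) or -1 (inverted). O(n^2) DP with traceback.
.bestChain <- function(ra, rb, maxgap, dir) {
  n <- length(ra)
  if (!n) return(list(size = 0L, idx = integer()))
  o <- order(ra)
  ra_s <- ra[o]; rb_s <- dir * rb[o]
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra_s[i] - ra_s[j] <= maxgap &&
          rb_s[i] > rb_s[j] && rb_s[i] - rb_s[j] <= maxgap &&
          best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  k <- which.max(best)
  idx <- integer()
  while (!is.na(k)) { idx <- c(k, idx); k <- prev[k] }
  list(size = max(best), idx = o[idx])
}

#' Detect collinear gene blocks between two contigs
#'
#' Given the anchors of two contigs and a one-to-one gene-id pairing,
#' returns the best chain of matched anchors per orientation: anchor ranks
#' strictly increasing on contig a and strictly increasing (same
#' orientation) or strictly decreasing (inverted) on contig b, with
#' consecutive rank gaps of at most `max_anchor_gap` on both contigs.
#'
#' @param anchors_a,anchors_b Anchor tables (see [readAnchors()]) of one
#'   contig each.
#' @param matches Data.frame gene_a (on a), gene_b (on b); must be
#'   one-to-one.
#' @param config A [PurgeConfig-class] (uses `max_anchor_gap`).
#' @return A list of blocks, each a list with elements `orientation`
#'   ("same"/"inverted"), `size`, and `anchor_pairs` (data.frame gene_a,
#'   gene_b, rank_a, rank_b). Empty input gives an empty list.
#' @export
detectCollinearBlocks <- function(anchors_a, anchors_b, matches,
                                  config = purgeConfig()) {
  ra <- .anchorRanks(anchors_a)
  rb <- .anchorRanks(anchors_b)
  m <- matches[matches$gene_a %in% names(ra) &
                 matches$gene_b %in% names(rb), , drop = FALSE]
  if (!nrow(m)) return(list())
  if (anyDuplicated(m$gene_a) || anyDuplicated(m$gene_b))
    stop("gene matches must be one-to-one (apply best-hit reduction first)")
  ka <- unname(ra[m$gene_a]); kb <- unname(rb[m$gene_b])
  blocks <- list()
  for (dir in c(1L, -1L)) {
    ch <- .bestChain(ka, kb, config@max_anchor_gap, dir)
    if (ch$size >= 1L) {
      blocks[[length(blocks) + 1L]] <- list(
        orientation = if (dir > 0L) "same" else "inverted",
        size = ch$size,
        anchor_pairs = data.frame(gene_a = m$gene_a[ch$idx],
                                  gene_b = m$gene_b[ch$idx],
                                  rank_a = ka[ch$idx], rank_b = kb[ch$idx]))
    }
  }
  blocks
}

# Rank anchors along one contig by start coordinate; duplicate start
# positions would make ranks ambiguous and are an integrity error.
.anchorRanks <- function(anchors) {
  if (!nrow(anchors)) return(setNames(integer(), character()))
  if (length(unique(anchors$contig_id)) > 1L)
    stop("anchor table spans multiple contigs; subset per contig first")
  if (anyDuplicated(anchors$start))
    stop("duplicate anchor start on contig ", anchors$contig_id[1L],
         ": ranks would be ambiguous")
  setNames(rank(anchors$start), anchors$gene_id)
}

#' Best collinear-block size for every contig pair
#'
#' Runs [detectCollinearBlocks()] over all contig pairs connected by the
#' match table.
#'
#' @param anchors Full anchor table (all contigs).
#' @param matches One-to-one gene-id pairing.
#' @param config A [PurgeConfig-class].
#' @return A data.frame with columns contig_a, contig_b, collinear_genes,
#'   orientation (of the best chain).
#' @export
collinearGenesPerPair <- function(anchors, matches,
                                  config = purgeConfig()) {
  empty <- data.frame(contig_a = character(), contig_b = character(),
                      collinear_genes = integer(), orientation = character())
  if (!nrow(anchors) || !nrow(matches)) return(empty)
  contigOf <- setNames(anchors$contig_id, anchors$gene_id)
  m <- matches[matches$gene_a %in% names(contigOf) &
                 matches$gene_b %in% names(contigOf), , drop = FALSE]
  if (!nrow(m)) return(empty)
  m$ca <- unname(contigOf[m$gene_a]); m$cb <- unname(contigOf[m$gene_b])
  m <- m[m$ca != m$cb, , drop = FALSE]
  if (!nrow(m)) return(empty)
  byContig <- split(anchors, anchors$contig_id)
  out <- lapply(split(m, paste(m$ca, m$cb, sep = "\r")), function(g) {
    blocks <- detectCollinearBlocks(byContig[[g$ca[1L]]],
                                    byContig[[g$cb[1L]]],
                                    g[c("gene_a", "gene_b")], config)
    if (!length(blocks)) return(NULL)
    sizes <- vapply(blocks, `[[`, integer(1L), "size")
    best <- which.max(sizes)
    data.frame(contig_a = g$ca[1L], contig_b = g$cb[1L],
               collinear_genes = sizes[best],
               orientation = blocks[[best]]$orientation)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count shared single-copy complete markers per contig pair
#'
#' A marker links two contigs iff its status is `complete` and it occurs
#' exactly once on each of the two contigs. Single-copy is judged per
#' contig: a marker duplicated genome-wide but present once on each member
#' of an allelic pair is precisely the signal sought.
#'
#' @param markers Marker table (see [readMarkers()]).
#' @return A data.frame with columns contig_a, contig_b (unordered pair,
#'   a < b), shared_markers.
#' @export
sharedSingleCopyMarkers <- function(markers) {
  dt <- as.data.table(markers)[status == "complete" & copies == 1L]
  if (!nrow(dt))
    return(data.frame(contig_a = character(), contig_b = character(),
                      shared_markers = integer()))
  pairs <- dt[, if (.N >= 2L) {
    cs <- sort(contig_id)
    idx <- combn(length(cs), 2L)
    .(contig_a = cs[idx[1L, ]], contig_b = cs[idx[2L, ]])
  }, by = marker_id]
  if (!nrow(pairs))
    return(data.frame(contig_a = character(), contig_b = character(),
                      shared_markers = integer()))
  as.data.frame(pairs[, .(shared_markers = .N), by = .(contig_a, contig_b)])
}

#' Assemble per-pair evidence from the three channels
#'
#' Orients every pair as (shorter, longer) — equal lengths break
#' lexicographically and are logged as ties — and outer-joins coverage,
#' collinear genes, and shared markers, filling absences with zero.
#'
#' @param coverage Output of [computePairCoverage()].
#' @param collinear Output of [collinearGenesPerPair()].
#' @param markers_shared Output of [sharedSingleCopyMarkers()].
#' @param lengths Named vector of contig lengths.
#' @return A list with `evidence` (data.frame short_id, long_id, coverage,
#'   collinear_genes, shared_markers) and `ties` (character vector of
#'   logged equal-length pairs).
#' @export
buildPairEvidence <- function(coverage, collinear, markers_shared, lengths) {
  ties <- character()
  orient <- function(a, b, val, col) {
    if (!length(a)) {
      dt <- data.table(short_id = character(), long_id = character(),
                       V = numeric())
      return(setnames(dt, "V", col))
    }
    o <- .orientPair(a, b, lengths)
    if (any(o$tie))
      ties <<- c(ties, paste(o$short[o$tie], o$long[o$tie], sep = "~"))
    dt <- data.table(short_id = o$short, long_id = o$long, V = val)
    # a pair can surface in both orders upstream; keep the strongest value
    dt <- dt[, .(V = max(V)), by = .(short_id, long_id)]
    setnames(dt, "V", col)
  }
  cov <- orient(coverage$short_id, coverage$long_id, coverage$coverage,
                "coverage")
  col <- orient(collinear$contig_a, collinear$contig_b,
                as.numeric(collinear$collinear_genes), "collinear_genes")
  mar <- orient(markers_shared$contig_a, markers_shared$contig_b,
                as.numeric(markers_shared$shared_markers), "shared_markers")
  ev <- Reduce(function(x, y) merge(x, y, by = c("short_id", "long_id"),
                                    all = TRUE),
               list(cov, col, mar))
  for (cc in c("coverage", "collinear_genes", "shared_markers"))
    ev[is.na(get(cc)), (cc) := 0]
  list(evidence = as.data.frame(ev), ties = unique(ties))
}

#' Classify contigs as primaries or haplotigs
#'
#' Processes contigs in decreasing length order. A contig is labelled a
#' haplotig if any longer contig qualifies on at least one criterion
#' (coverage strict `>`, gene and marker counts inclusive `>=`). The
#' recorded partner is the best qualifying longer contig: most criteria
#' triggered, then highest coverage, then most collinear genes, then
#' lexicographically smallest id. A contig that was itself purged remains
#' eligible as a recorded partner of even shorter contigs (the whole chain
#' is removed; the output stays a pure partition).
#'
#' @param evidence Evidence table from [buildPairEvidence()] (the
#'   `evidence` element).
#' @param lengths Named vector of contig lengths (defines the full contig
#'   universe; contigs without evidence become primaries).
#' @param config A [PurgeConfig-class].
#' @param ties Optional tie log to carry into the result.
#' @return A [PurgeResult-class].
#' @export
classifyHaplotigs <- function(evidence, lengths, config = purgeConfig(),
                              ties = character()) {
  ev <- as.data.table(evidence)
  if (nrow(ev)) {
    unknown <- setdiff(unique(c(ev$short_id, ev$long_id)), names(lengths))
    if (length(unknown))
      stop("evidence references unknown contig(s): ",
           paste(head(unknown, 3L), collapse = ", "))
    trig_cov <- ev$coverage > config@min_coverage
    trig_syn <- ev$collinear_genes >= config@min_collinear_genes
    trig_mar <- ev$shared_markers >= config@min_shared_markers
    ev[, `:=`(t_cov = trig_cov, t_syn = trig_syn, t_mar = trig_mar,
              n_criteria = trig_cov + trig_syn + trig_mar)]
    ev <- ev[n_criteria > 0L]
  }
  ids <- names(lengths)[order(-lengths, names(lengths))]
  dec <- data.frame(contig_id = ids, label = "primary",
                    partner_id = NA_character_, triggered_criteria = "",
                    coverage = 0, collinear_genes = 0L, shared_markers = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(ev)) {
    setorder(ev, short_id, -n_criteria, -coverage, -collinear_genes,
             long_id)
    best <- ev[!duplicated(short_id)]
    i <- match(best$short_id, dec$contig_id)
    dec$label[i] <- "haplotig"
    dec$partner_id[i] <- best$long_id
    dec$triggered_criteria[i] <- apply(
      cbind(best$t_cov, best$t_syn, best$t_mar), 1L,
      function(x) paste(c("coverage", "synteny", "marker")[x],
                        collapse = ","))
    dec$coverage[i] <- best$coverage
    dec$collinear_genes[i] <- as.integer(best$collinear_genes)
    dec$shared_markers[i] <- as.integer(best$shared_markers)
  }
  new("PurgeResult", decisions = dec,
      evidence = as.data.frame(evidence), config = config, ties = ties)
}

#' Partition an assembly into primary and haplotig sets
#'
#' @param contigs A `DNAStringSet` of all input contigs.
#' @param result A [PurgeResult-class] with one decision per contig.
#' @return A list with `primary` and `haplotigs` (`DNAStringSet`s whose
#'   total width equals the input) and `report` (one row per contig:
#'   decision plus evidence values and contig length).
#' @export
purgeAssembly <- function(contigs, result) {
  dec <- decisions(result)
  if (!setequal(names(contigs), dec$contig_id) ||
      length(contigs) != nrow(dec))
    stop("decisions must cover each input contig exactly once")
  report <- dec
  report$length <- width(contigs)[match(dec$contig_id, names(contigs))]
  keep <- dec$contig_id[dec$label == "primary"]
  drop <- dec$contig_id[dec$label == "haplotig"]
  list(primary = contigs[keep], haplotigs = contigs[drop], report = report)
}

#' Run the full purge pipeline on files
#'
#' Reads contigs, alignments and evidence tables, computes the three
#' channels, classifies, and (optionally) writes `primary.fa`,
#' `haplotigs.fa` and `purge_report.tsv` into `out_dir`.
#'
#' @param contigs_fa Contig FASTA path.
#' @param paf All-by-all PAF path.
#' @param anchors_tsv,matches_tsv Gene anchor and match tables (optional:
#'   `NULL` disables the synteny channel).
#' @param markers_tsv Marker table (optional: `NULL` disables the marker
#'   channel).
#' @param config A [PurgeConfig-class].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return The [PurgeResult-class], invisibly when writing.
#' @export
runPurge <- function(contigs_fa, paf, anchors_tsv = NULL,
                     matches_tsv = NULL, markers_tsv = NULL,
                     config = purgeConfig(), out_dir = NULL) {
  contigs <- readDNAStringSet(contigs_fa)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  lengths <- setNames(width(contigs), names(contigs))
  aln <- readPaf(paf)
  cov <- computePairCoverage(aln, lengths, config)
  col <- if (!is.null(anchors_tsv) && !is.null(matches_tsv))
    collinearGenesPerPair(readAnchors(anchors_tsv),
                          readMatches(matches_tsv), config)
  else data.frame(contig_a = character(), contig_b = character(),
                  collinear_genes = integer(), orientation = character())
  mar <- if (!is.null(markers_tsv)) sharedSingleCopyMarkers(readMarkers(markers_tsv))
  else data.frame(contig_a = character(), contig_b = character(),
                  shared_markers = integer())
  pe <- buildPairEvidence(cov, col, mar, lengths)
  res <- classifyHaplotigs(pe$evidence, lengths, config, ties = pe$ties)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    parts <- purgeAssembly(contigs, res)
    writeXStringSet(parts$primary, file.path(out_dir, "primary.fa"))
    writeXStringSet(parts$haplotigs, file.path(out_dir, "haplotigs.fa"))
    .writeTsv(parts$report, file.path(out_dir, "purge_report.tsv"))
    return(invisible(res))
  }
  res
}
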