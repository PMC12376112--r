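suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
})

# Small standard scene used across unit tests: 600 kb, 2 chromosomes,
# 8 primaries, 5 haplotigs. Cached per seed within a test run.
smallSimParams <- function(seed = 7L, ...) {
  simParams(genome_bp = 6e5, n_chroms = 2L, n_primary_contigs = 8L,
            n_haplotigs = 5L, haplotig_len_range = c(30000L, 50000L),
            n_genes = 20L, seed = seed, ...)
}

.simCache <- new.env(parent = emptyenv())
smallSim <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateDiploid(smallSimParams(seed))
  .simCache[[key]]
}

# Default 5-Mb study scene (simParams() defaults), cached per seed/noise.
defaultSim <- function(seed = 1L, ...) {
  key <- paste("d", seed, paste(c(...), collapse = "_"), sep = "_")
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateDiploid(simParams(seed = seed, ...))
  .simCache[[key]]
}

contigLengths <- function(sim)
  setNames(width(assemblyContigs(sim)), names(assemblyContigs(sim)))

refLengths <- function(sim)
  setNames(width(haplotype1(sim)), names(haplotype1(sim)))

# ---- independent oracles --------------------------------------------------

# Per-base membership union length over 0-based half-open intervals.
oracleUnionLength <- function(starts0, ends0) {
  if (!length(starts0)) return(0L)
  hi <- max(ends0)
  member <- logical(hi)
  for (i in seq_along(starts0))
    if (ends0[i] > starts0[i])
      member[(starts0[i] + 1L):ends0[i]] <- TRUE
  sum(member)
}

# Longest common chain of matched anchors, monotone in both rank orders
# (either orientation) with consecutive gaps <= maxgap, by adjacency-matrix
# fixpoint relaxation — mechanically independent of the package's
# sequential DP.
oracleChainSize <- function(ra, rb, maxgap) {
  n <- length(ra)
  if (!n) return(0L)
  best <- 0L
  for (dir in c(1L, -1L)) {
    rb2 <- dir * rb
    dA <- outer(ra, ra, function(a, b) b - a)   # dA[i, j] = ra[j] - ra[i]
    dB <- outer(rb2, rb2, function(a, b) b - a)
    E <- dA > 0 & dA <= maxgap & dB > 0 & dB <= maxgap
    len <- rep(1L, n)
    repeat {
      nxt <- vapply(seq_len(n), function(j) {
        pred <- len[E[, j]]
        if (length(pred)) max(1L, 1L + max(pred)) else 1L
      }, integer(1L))
      if (identical(nxt, len)) break
      len <- nxt
    }
    best <- max(best, max(len))
  }
  best
}

# Per-window masked bp by per-base painting of 1-based closed ranges.
oracleWindowMasked <- function(L, win_start, win_end, mask_start, mask_end) {
  member <- logical(L)
  for (i in seq_along(mask_start))
    member[mask_start[i]:mask_end[i]] <- TRUE
  vapply(seq_along(win_start), function(j)
    sum(member[win_start[j]:win_end[j]]), integer(1L))
}

# Haplotig-recovery precision/recall/F1 of a PurgeResult against truth.
purgeScores <- function(res, labels) {
  truth_h <- labels$contig_id[labels$label == "haplotig"]
  called_h <- haplotigIds(res)
  tp <- length(intersect(called_h, truth_h))
  prec <- if (length(called_h)) tp / length(called_h) else 1
  rec <- if (length(truth_h)) tp / length(truth_h) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

# Full purge pipeline on in-memory simulator output.
purgeSim <- function(sim, config = purgeConfig()) {
  lens <- contigLengths(sim)
  cov <- computePairCoverage(contigAlignments(sim), lens, config)
  col <- collinearGenesPerPair(geneAnchors(sim), geneMatches(sim), config)
  mar <- sharedSingleCopyMarkers(markerHits(sim))
  pe <- buildPairEvidence(cov, col, mar, lens)
  classifyHaplotigs(pe$evidence, lens, config, ties = pe$ties)
}
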