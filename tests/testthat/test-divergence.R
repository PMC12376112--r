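.pafRec <- function(cigar, tstart = 100, tid = "chr1", qid = "q1",
                    tlen = 100000, qlen = 100000) {
  cig <- parseCigar(cigar)
  sp <- cigarSpans(cig)
  data.frame(query_id = qid, query_len = qlen, query_start = 0,
             query_end = sp[["query"]], strand = "+", target_id = tid,
             target_len = tlen, target_start = tstart,
             target_end = tstart + sp[["target"]],
             n_match = sum(cig$len[cig$op == "="]), aln_len = sum(cig$len),
             mapq = 60, cigar = cigar, has_cigar = TRUE)
}

.mkVar <- function(start, ref_len, alt_len, subtype, seq_id = "chr1",
                   source = "read")
  variantRanges(seq_id, as.integer(start), as.integer(ref_len),
                as.integer(alt_len), subtype, source)

test_that("CIGAR variant extraction places SNPs, INDELs and PAVs", {
  rl <- c(chr1 = 100000L)
  # 5=1X4= at target start 100 (0-based): one SNP at 0-based 105
  out <- callVariantsFromAlignment(.pafRec("5=1X4="), rl)
  v <- out$variants
  expect_equal(length(v), 1)
  expect_equal(start(v), 106)  # 1-based
  expect_equal(mcols(v)$vclass, "SNP")
  # X run of length 3 decomposes into 3 per-base SNPs
  v3 <- callVariantsFromAlignment(.pafRec("5=3X4="), rl)$variants
  expect_equal(length(v3), 3)
  expect_equal(start(v3), c(106, 107, 108))
  # 100=60D100= -> one PAV deletion of ref_len 60
  vd <- callVariantsFromAlignment(.pafRec("100=60D100="), rl)$variants
  expect_equal(mcols(vd)$vclass, "PAV")
  expect_equal(mcols(vd)$subtype, "deletion")
  expect_equal(mcols(vd)$ref_len, 60L)
  expect_equal(start(vd), 201)
  expect_equal(width(vd), 60)
  # 100=10I100= -> one INDEL insertion of alt_len 10, 1-bp anchor
  vi <- callVariantsFromAlignment(.pafRec("100=10I100="), rl)$variants
  expect_equal(mcols(vi)$vclass, "INDEL")
  expect_equal(mcols(vi)$subtype, "insertion")
  expect_equal(mcols(vi)$alt_len, 10L)
  expect_equal(width(vi), 1)
  # 50-bp boundary: 49 -> INDEL, 50 -> PAV
  expect_equal(mcols(callVariantsFromAlignment(
    .pafRec("10=49D10="), rl)$variants)$vclass, "INDEL")
  expect_equal(mcols(callVariantsFromAlignment(
    .pafRec("10=50D10="), rl)$variants)$vclass, "PAV")
  # M is rejected as ambiguous
  expect_error(callVariantsFromAlignment(.pafRec("100M"), rl), "eqx")
})

test_that("unaligned track is the complement of target-aligned intervals", {
  rl <- c(chr1 = 1000L)
  out <- callVariantsFromAlignment(.pafRec("200=", tstart = 100,
                                           tlen = 1000), rl)
  ua <- out$unaligned
  expect_equal(start(ua), c(1, 301))
  expect_equal(end(ua), c(100, 1000))
  expect_equal(sum(width(ua)), 800)
})

test_that("findGaps reports maximal N runs", {
  seqs <- DNAStringSet(c(s1 = "ACGTNNNACG", s2 = "ACGT", s3 = "NNN"))
  g <- findGaps(seqs)
  expect_equal(as.character(seqnames(g)), c("s1", "s3"))
  expect_equal(start(g), c(5, 1))  # 0-based (4,7) and (0,3)
  expect_equal(end(g), c(7, 3))
  g2 <- findGaps(seqs, divergenceConfig(min_gap_run = 4L))
  expect_equal(length(g2), 0)
})

test_that("point variants match on exact start position only", {
  a <- .mkVar(106, 1, 1, "substitution", source = "wga")
  b_same <- .mkVar(106, 1, 1, "substitution")
  b_off <- .mkVar(107, 1, 1, "substitution")
  expect_equal(length(matchPointVariants(a, b_same, "SNP")), 1)
  expect_equal(length(matchPointVariants(a, b_off, "SNP")), 0)
  expect_equal(length(matchPointVariants(a, b_same[0], "SNP")), 0)
  # classes do not cross-match: INDEL at same start is not a SNP match
  ind <- .mkVar(106, 0, 5, "insertion")
  expect_equal(length(matchPointVariants(a, ind, "SNP")), 0)
  # source of the output is the wga copy
  m <- matchPointVariants(a, b_same, "SNP")
  expect_equal(mcols(m)$source, "wga")
})

test_that("PAV matching follows overlap-or-10-bp-downstream slack", {
  cfg <- divergenceConfig()
  pav <- function(s0, e0, source = "read")
    .mkVar(s0 + 1, e0 - s0, 0, "deletion", source = source)
  a <- pav(100, 200, source = "wga")
  expect_equal(length(matchPavs(a, pav(150, 260), cfg)), 1)  # overlap
  expect_equal(length(matchPavs(a, pav(208, 300), cfg)), 1)  # gap 8
  expect_equal(length(matchPavs(a, pav(210, 300), cfg)), 1)  # gap 10
  expect_equal(length(matchPavs(a, pav(211, 300), cfg)), 0)  # gap 11
  # slack applies in both directions
  expect_equal(length(matchPavs(pav(208, 300, "wga"), pav(100, 200), cfg)),
               1)
  # symmetric matched-pair set under argument swap
  set.seed(21)
  s_a <- sort(sample(0:5000, 8)) * 3L
  s_b <- s_a + sample(-60:60, 8, replace = TRUE)
  A <- .mkVar(s_a + 1, rep(80L, 8), rep(0L, 8), "deletion", source = "wga")
  B <- .mkVar(s_b + 1, rep(80L, 8), rep(0L, 8), "deletion", source = "read")
  ab <- matchPavs(A, B, cfg)
  ba <- matchPavs(B, A, cfg)
  # the set of matched (A,B) pairs is the same; check via counts and the
  # matched coordinates on each side
  hits_ab <- findOverlaps(A, B, maxgap = cfg@pav_match_slack_bp)
  hits_ba <- findOverlaps(B, A, maxgap = cfg@pav_match_slack_bp)
  expect_equal(sort(paste(queryHits(hits_ab), subjectHits(hits_ab))),
               sort(paste(subjectHits(hits_ba), queryHits(hits_ba))))
  expect_equal(length(ab), length(unique(queryHits(hits_ab))))
  expect_equal(length(ba), length(unique(queryHits(hits_ba))))
})

test_that("gap-containing PAVs are filtered, abutting gaps are kept", {
  pav <- .mkVar(101, 100, 0, "deletion", source = "wga")  # [100,200) 0-based
  gapIn <- GRanges("chr1", IRanges(151, 160))    # inside
  gapOut <- GRanges("chr1", IRanges(301, 310))   # elsewhere
  gapAbut <- GRanges("chr1", IRanges(201, 210))  # abuts at 200 (0-based)
  expect_equal(length(filterGapPavs(pav, gapIn)), 0)
  expect_equal(length(filterGapPavs(pav, gapOut)), 1)
  expect_equal(length(filterGapPavs(pav, gapAbut)), 1)
  # single shared base removes
  gap1 <- GRanges("chr1", IRanges(200, 200))
  expect_equal(length(filterGapPavs(pav, gap1)), 0)
})

test_that("window identity is a clamped union-mask fraction", {
  rl <- c(chr1 = 200000L)
  cfg <- divergenceConfig()
  # no masks -> identity 1
  w0 <- windowIdentity(rl, .mkVar(1, 1, 1, "substitution")[0],
                       config = cfg)
  expect_equal(mcols(w0)$identity, c(1, 1))
  # 70,000 masked bp in a 100-kb window -> 0.30
  del <- .mkVar(1001, 70000, 0, "deletion", source = "wga")
  w1 <- windowIdentity(rl, del, config = cfg)
  expect_equal(mcols(w1)$identity[1], 0.30)
  # variant inside unaligned: union masks 5,000 not 6,000
  v <- .mkVar(1001, 1000, 0, "deletion", source = "wga")
  ua <- GRanges("chr1", IRanges(501, 5500))
  w2 <- windowIdentity(rl, v, unaligned = ua, config = cfg)
  expect_equal(mcols(w2)$masked_bp[1], 5000)
  expect_equal(mcols(w2)$variant_bp[1], 1000)
  expect_equal(mcols(w2)$unaligned_bp[1], 5000)
  expect_equal(mcols(w2)$identity[1], (100000 - 5000) / 100000)
  # identity bounded in [0,1] even with saturating masks
  big <- GRanges("chr1", IRanges(1, 200000))
  w3 <- windowIdentity(rl, del, unaligned = big, config = cfg)
  expect_true(all(mcols(w3)$identity >= 0 & mcols(w3)$identity <= 1))
  expect_equal(mcols(w3)$identity, c(0, 0))
})

test_that("per-window masked bp matches the per-base oracle", {
  set.seed(31)
  rl <- c(chr1 = 60000L)
  cfg <- divergenceConfig(window_bp = 10000L)
  for (rep in 1:20) {
    nv <- sample(5:30, 1)
    s <- sample(1:59000, nv)
    w <- sample(1:400, nv, replace = TRUE)
    e <- pmin(s + w - 1L, 60000L)
    vg <- GRanges("chr1", IRanges(s, e))
    ng <- sample(0:3, 1)
    gaps <- if (ng) GRanges("chr1", IRanges(sample(1:55000, ng),
                                            width = 500)) else GRanges()
    win <- windowIdentity(rl, vg, gaps = gaps, config = cfg)
    ms <- c(start(vg), start(gaps))
    me <- pmin(c(end(vg), end(gaps)), 60000L)
    expect_equal(mcols(win)$masked_bp,
                 oracleWindowMasked(60000L, start(win), end(win), ms, me))
  }
})

test_that("divergence on exact haplotype alignments recovers truth exactly", {
  sim <- smallSim()
  rl <- refLengths(sim)
  out <- callVariantsFromAlignment(haplotypeAlignments(sim), rl)
  tv <- truthVariants(sim)
  ex <- out$variants
  expect_equal(length(out$unaligned), 0)
  expect_equal(length(ex), length(tv))
  expect_equal(start(ex), start(tv))
  expect_equal(as.character(seqnames(ex)), as.character(seqnames(tv)))
  expect_equal(mcols(ex)$vclass, mcols(tv)$vclass)
  expect_equal(mcols(ex)$subtype, mcols(tv)$subtype)
  expect_equal(mcols(ex)$ref_len, mcols(tv)$ref_len)
  expect_equal(mcols(ex)$alt_len, mcols(tv)$alt_len)
  # identity equals 1 - truth_masked/W_eff exactly
  win <- windowIdentity(rl, ex, config = divergenceConfig())
  tm <- truthWindowMasked(sim, 100000L)
  expect_equal(mcols(win)$identity,
               1 - mcols(tm)$masked_bp / width(tm))
})

test_that("allele capture reads REF/ALT bases from the sequences", {
  sim <- smallSim()
  rl <- refLengths(sim)
  out <- callVariantsFromAlignment(haplotypeAlignments(sim), rl,
                                   ref = haplotype1(sim),
                                   query = setNames(haplotype2(sim),
                                                    names(haplotype2(sim))))
  tv <- truthVariants(sim)
  snp <- mcols(out$variants)$vclass == "SNP"
  expect_equal(mcols(out$variants)$ref_seq[snp], mcols(tv)$ref_seq[snp])
  expect_equal(mcols(out$variants)$alt_seq[snp], mcols(tv)$alt_seq[snp])
})
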