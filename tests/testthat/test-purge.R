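test_that("pair coverage follows union-of-intervals over the shorter contig", {
  lens <- c(A = 5000, B = 1000)
  mkPaf <- function(qs, qe) data.frame(
    query_id = "B", query_len = 1000, query_start = qs, query_end = qe,
    strand = "+", target_id = "A", target_len = 5000,
    target_start = qs + 100, target_end = qe + 100,
    n_match = qe - qs, aln_len = qe - qs, mapq = 60,
    cigar = NA_character_, has_cigar = FALSE)
  # one alignment covering [0,710) of a 1000-bp contig: 0.71 > 0.70
  cov <- computePairCoverage(mkPaf(0, 710), lens)
  expect_equal(cov$coverage, 0.71)
  expect_equal(cov$short_id, "B")
  expect_equal(cov$long_id, "A")
  # overlapping intervals [0,400) + [300,800): union 800 -> 0.80
  paf2 <- rbind(mkPaf(0, 400), mkPaf(300, 800))
  expect_equal(computePairCoverage(paf2, lens)$coverage, 0.80)
  # no alignments between a pair -> pair absent (coverage 0 downstream)
  expect_equal(nrow(computePairCoverage(mkPaf(0, 710)[0, ], lens)), 0)
  # unknown contig -> integrity error
  expect_error(computePairCoverage(
    within(mkPaf(0, 100), target_id <- "Z"), lens), "unknown")
})

test_that("pair coverage matches the per-base oracle on random instances", {
  set.seed(11)
  lens <- c(long = 20000, short = 3000)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    qs <- sample(0:2900, n, replace = TRUE)
    qe <- pmin(3000, qs + sample(50:800, n, replace = TRUE))
    paf <- data.frame(
      query_id = "short", query_len = 3000, query_start = qs,
      query_end = qe, strand = "+", target_id = "long", target_len = 20000,
      target_start = qs, target_end = qe, n_match = qe - qs,
      aln_len = qe - qs, mapq = 60, cigar = NA_character_,
      has_cigar = FALSE)
    got <- computePairCoverage(paf, lens)$coverage
    expect_equal(got, oracleUnionLength(qs, qe) / 3000)
  }
})

.anchorsFor <- function(contig, ids, starts)
  data.frame(gene_id = ids, contig_id = contig, start = starts,
             end = starts + 100L, strand = "+")

test_that("collinear chaining handles identity, short, and shuffled orders", {
  cfg <- purgeConfig()
  # 6 shared genes in identical order -> one chain of 6, same orientation
  a <- .anchorsFor("A", paste0("g", 1:6), seq(0, 5000, by = 1000))
  b <- .anchorsFor("B", paste0("h", 1:6), seq(0, 5000, by = 1000))
  m <- data.frame(gene_a = paste0("g", 1:6), gene_b = paste0("h", 1:6))
  blocks <- detectCollinearBlocks(a, b, m, cfg)
  sizes <- vapply(blocks, `[[`, integer(1), "size")
  ori <- vapply(blocks, `[[`, character(1), "orientation")
  expect_equal(max(sizes), 6)
  expect_equal(ori[which.max(sizes)], "same")
  # 4 shared genes: no block reaching the 5-gene criterion
  blocks4 <- detectCollinearBlocks(a[1:4, ], b[1:4, ], m[1:4, ], cfg)
  expect_lt(max(vapply(blocks4, `[[`, integer(1), "size")),
            cfg@min_collinear_genes)
  # b ranks (2,1,3,5,4) against a (1,2,3,4,5): best same-orientation chain 3
  b5 <- .anchorsFor("B", paste0("h", 1:5),
                    c(2, 1, 3, 5, 4) * 1000L)
  m5 <- data.frame(gene_a = paste0("g", 1:5), gene_b = paste0("h", 1:5))
  blocks5 <- detectCollinearBlocks(a[1:5, ], b5, m5, cfg)
  same5 <- Filter(function(x) x$orientation == "same", blocks5)
  expect_equal(max(vapply(same5, `[[`, integer(1), "size")), 3)
  # fully reversed order chains as inverted
  brev <- .anchorsFor("B", paste0("h", 1:6), seq(5000, 0, by = -1000))
  blocksr <- detectCollinearBlocks(a, brev, m, cfg)
  sizes_r <- vapply(blocksr, `[[`, integer(1), "size")
  expect_equal(max(sizes_r), 6)
  expect_equal(vapply(blocksr, `[[`, character(1),
                      "orientation")[which.max(sizes_r)], "inverted")
  # duplicate anchor start is an integrity error
  adup <- .anchorsFor("A", c("g1", "g2"), c(100L, 100L))
  expect_error(detectCollinearBlocks(adup, b, m, cfg), "ambiguous")
})

test_that("chain size equals the relaxation oracle on random permutations", {
  set.seed(101)
  cfg <- purgeConfig()
  for (rep in 1:200) {
    n <- sample(2:15, 1)
    ra <- sample(n)
    rb <- sample(n)
    a <- .anchorsFor("A", paste0("g", 1:n), ra * 10L)
    b <- .anchorsFor("B", paste0("h", 1:n), rb * 10L)
    m <- data.frame(gene_a = paste0("g", 1:n), gene_b = paste0("h", 1:n))
    blocks <- detectCollinearBlocks(a, b, m, cfg)
    got <- max(vapply(blocks, `[[`, integer(1), "size"))
    expect_equal(got, oracleChainSize(ra, rb, cfg@max_anchor_gap),
                 info = paste("n =", n, "rep =", rep))
  }
})

test_that("shared single-copy markers require complete x1 on both contigs", {
  mk <- data.frame(
    marker_id = c("m1", "m1", "m2", "m2", "m3", "m3", "m3", "m4"),
    contig_id = c("A", "B", "A", "B", "A", "A", "B", "A"),
    status = c("complete", "complete", "complete", "fragmented",
               "complete", "complete", "complete", "complete"),
    copies = c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L))
  # m1: complete x1 on both -> counts; m2: fragmented on B -> no;
  # m3: 2 copies on A -> no; m4: one contig only -> no
  out <- sharedSingleCopyMarkers(mk)
  expect_equal(nrow(out), 1)
  expect_equal(out$shared_markers, 1L)
  expect_setequal(c(out$contig_a, out$contig_b), c("A", "B"))
})

test_that("classification triggers per criterion and picks best partner", {
  lens <- c(A = 10000, B = 5000, C = 2000)
  mkEv <- function(short, long, cov = 0, genes = 0, mks = 0)
    data.frame(short_id = short, long_id = long, coverage = cov,
               collinear_genes = genes, shared_markers = mks)
  cfg <- purgeConfig()
  # coverage criterion alone
  r1 <- classifyHaplotigs(mkEv("B", "A", cov = 0.80), lens, cfg)
  d1 <- decisions(r1)
  expect_equal(d1$label[d1$contig_id == "B"], "haplotig")
  expect_equal(d1$partner_id[d1$contig_id == "B"], "A")
  expect_equal(d1$triggered_criteria[d1$contig_id == "B"], "coverage")
  # coverage at exactly the threshold does not trigger (strict >)
  r1b <- classifyHaplotigs(mkEv("B", "A", cov = 0.70), lens, cfg)
  expect_equal(decisions(r1b)$label[2], "primary")
  # synteny criterion alone (coverage below threshold)
  r2 <- classifyHaplotigs(mkEv("B", "A", cov = 0.50, genes = 5), lens, cfg)
  expect_equal(decisions(r2)$triggered_criteria[
    decisions(r2)$contig_id == "B"], "synteny")
  # marker criterion alone, inclusive >= 1
  r3 <- classifyHaplotigs(mkEv("B", "A", mks = 1), lens, cfg)
  expect_equal(decisions(r3)$triggered_criteria[
    decisions(r3)$contig_id == "B"], "marker")
  # chain: C -> B and B -> A; all purged, partners recorded even though B
  # is itself purged
  ev <- rbind(mkEv("B", "A", cov = 0.9), mkEv("C", "B", cov = 0.9))
  r4 <- classifyHaplotigs(ev, lens, cfg)
  d4 <- decisions(r4)
  expect_equal(d4$label, c("primary", "haplotig", "haplotig"))
  expect_equal(d4$partner_id[d4$contig_id == "C"], "B")
  # best-partner ordering: most criteria, then coverage
  ev2 <- rbind(mkEv("C", "A", cov = 0.95),
               mkEv("C", "B", cov = 0.80, genes = 6))
  d5 <- decisions(classifyHaplotigs(ev2, lens, cfg))
  expect_equal(d5$partner_id[d5$contig_id == "C"], "B")  # 2 criteria beat 1
})

test_that("purge recovers simulated truth labels perfectly without noise", {
  sim <- smallSim()
  res <- purgeSim(sim)
  sc <- purgeScores(res, truthLabels(sim))
  expect_equal(unname(sc["precision"]), 1.0)
  expect_equal(unname(sc["recall"]), 1.0)
})

test_that("purgeAssembly conserves every base and reports every contig", {
  sim <- smallSim()
  res <- purgeSim(sim)
  parts <- purgeAssembly(assemblyContigs(sim), res)
  expect_equal(sum(width(parts$primary)) + sum(width(parts$haplotigs)),
               sum(width(assemblyContigs(sim))))
  expect_equal(nrow(parts$report), length(assemblyContigs(sim)))
  expect_setequal(c(names(parts$primary), names(parts$haplotigs)),
                  names(assemblyContigs(sim)))
  # all-primary decisions: haplotig set empty, primary == input
  lens <- contigLengths(sim)
  allp <- classifyHaplotigs(
    data.frame(short_id = character(), long_id = character(),
               coverage = numeric(), collinear_genes = numeric(),
               shared_markers = numeric()), lens)
  parts0 <- purgeAssembly(assemblyContigs(sim), allp)
  expect_equal(length(parts0$haplotigs), 0)
  expect_equal(length(parts0$primary), length(assemblyContigs(sim)))
})

test_that("raising min_coverage never enlarges the purged set", {
  sim <- smallSim()
  purged <- lapply(c(0.5, 0.7, 0.9), function(mc) {
    # isolate the coverage channel so the threshold actually binds
    lens <- contigLengths(sim)
    cov <- computePairCoverage(contigAlignments(sim), lens)
    pe <- buildPairEvidence(cov,
      data.frame(contig_a = character(), contig_b = character(),
                 collinear_genes = integer(), orientation = character()),
      data.frame(contig_a = character(), contig_b = character(),
                 shared_markers = integer()), lens)
    haplotigIds(classifyHaplotigs(pe$evidence, lens,
                                  purgeConfig(min_coverage = mc)))
  })
  expect_true(all(purged[[2]] %in% purged[[1]]))
  expect_true(all(purged[[3]] %in% purged[[2]]))
})

test_that("decisions are invariant to input row order", {
  sim <- smallSim()
  lens <- contigLengths(sim)
  paf <- contigAlignments(sim)
  set.seed(5)
  paf2 <- paf[sample(nrow(paf)), ]
  cov1 <- computePairCoverage(paf, lens)
  cov2 <- computePairCoverage(paf2, lens)
  col <- collinearGenesPerPair(geneAnchors(sim), geneMatches(sim))
  mar <- sharedSingleCopyMarkers(markerHits(sim))
  d1 <- decisions(classifyHaplotigs(
    buildPairEvidence(cov1, col, mar, lens)$evidence, lens))
  d2 <- decisions(classifyHaplotigs(
    buildPairEvidence(cov2, col, mar, lens)$evidence, lens))
  expect_equal(d1, d2)
})

test_that("equal-length pairs break lexicographically and are logged", {
  lens <- c(aa = 1000, bb = 1000)
  cov <- data.frame(short_id = "bb", long_id = "aa", coverage = 0.9)
  pe <- buildPairEvidence(cov,
    data.frame(contig_a = character(), contig_b = character(),
               collinear_genes = integer(), orientation = character()),
    data.frame(contig_a = character(), contig_b = character(),
               shared_markers = integer()), lens)
  expect_equal(pe$ties, "bb~aa")
  d <- decisions(classifyHaplotigs(pe$evidence, lens, ties = pe$ties))
  expect_equal(d$label[d$contig_id == "bb"], "haplotig")
  expect_equal(d$label[d$contig_id == "aa"], "primary")
})
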