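# Central S4 classes. All genomic coordinates inside the package live in
# GRanges/IRanges (1-based, closed), the standard Bioconductor convention;
# 0-based formats (PAF, BED) and VCF anchoring conventions are converted at
# the I/O boundary.

#' Configuration for haplotig purging
#'
#' Holds the evidence thresholds of the three-channel purge procedure:
#' alignment coverage of the shorter contig (strict `>`), collinear genes in
#' the best micro-synteny chain (`>=`), and shared single-copy complete
#' markers (`>=`).
#'
#' @slot min_coverage Coverage fraction threshold, strict (default 0.70).
#' @slot min_collinear_genes Minimum genes in one collinear block (default 5).
#' @slot min_shared_markers Minimum shared single-copy complete markers
#'   (default 1).
#' @slot max_anchor_gap Maximum rank gap between consecutive chained anchors,
#'   on either contig (default 10).
#' @slot min_mapq Alignments below this MAPQ are ignored for coverage
#'   (default 0, i.e. no filter).
#' @exportClass PurgeConfig
setClass("PurgeConfig", representation(
  min_coverage = "numeric",
  min_collinear_genes = "integer",
  min_shared_markers = "integer",
  max_anchor_gap = "integer",
  min_mapq = "integer"
))

setValidity("PurgeConfig", function(object) {
  msg <- character()
  if (!(object@min_coverage > 0 && object@min_coverage <= 1))
    msg <- c(msg, "min_coverage must be in (0, 1]")
  if (object@min_collinear_genes < 1L)
    msg <- c(msg, "min_collinear_genes must be >= 1")
  if (object@min_shared_markers < 1L)
    msg <- c(msg, "min_shared_markers must be >= 1")
  if (object@max_anchor_gap < 1L)
    msg <- c(msg, "max_anchor_gap must be >= 1")
  if (object@min_mapq < 0L)
    msg <- c(msg, "min_mapq must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param min_coverage,min_collinear_genes,min_shared_markers,max_anchor_gap,min_mapq
#'   See slot documentation.
#' @return A `PurgeConfig` object.
#' @rdname PurgeConfig-class
#' @export
purgeConfig <- function(min_coverage = 0.70, min_collinear_genes = 5L,
                        min_shared_markers = 1L, max_anchor_gap = 10L,
                        min_mapq = 0L) {
  new("PurgeConfig",
      min_coverage = as.numeric(min_coverage),
      min_collinear_genes = as.integer(min_collinear_genes),
      min_shared_markers = as.integer(min_shared_markers),
      max_anchor_gap = as.integer(max_anchor_gap),
      min_mapq = as.integer(min_mapq))
}

setMethod("show", "PurgeConfig", function(object) {
  cat("PurgeConfig: coverage >", object@min_coverage,
      "| collinear genes >=", object@min_collinear_genes,
      "| shared markers >=", object@min_shared_markers,
      "| max anchor gap", object@max_anchor_gap, "\n")
})

#' Configuration for inter-haplotype divergence
#'
#' @slot window_bp Window width for sequence identity (default 100,000 bp).
#' @slot pav_min_bp Minimum length of a presence/absence variant; shorter
#'   insertions/deletions are small INDELs (default 50 bp).
#' @slot pav_match_slack_bp Two PAVs are concordant if they overlap or if one
#'   starts within this many bp downstream of the other's end (default 10).
#' @slot min_gap_run Minimum N-run length reported as an assembly gap
#'   (default 1).
#' @exportClass DivergenceConfig
setClass("DivergenceConfig", representation(
  window_bp = "integer",
  pav_min_bp = "integer",
  pav_match_slack_bp = "integer",
  min_gap_run = "integer"
))

setValidity("DivergenceConfig", function(object) {
  if (any(c(object@window_bp, object@pav_min_bp,
            object@pav_match_slack_bp, object@min_gap_run) < 1L))
    "all DivergenceConfig fields must be positive" else TRUE
})

#' @param window_bp,pav_min_bp,pav_match_slack_bp,min_gap_run See slot
#'   documentation.
#' @return A `DivergenceConfig` object.
#' @rdname DivergenceConfig-class
#' @export
divergenceConfig <- function(window_bp = 100000L, pav_min_bp = 50L,
                             pav_match_slack_bp = 10L, min_gap_run = 1L) {
  new("DivergenceConfig",
      window_bp = as.integer(window_bp),
      pav_min_bp = as.integer(pav_min_bp),
      pav_match_slack_bp = as.integer(pav_match_slack_bp),
      min_gap_run = as.integer(min_gap_run))
}

setMethod("show", "DivergenceConfig", function(object) {
  cat("DivergenceConfig: window", object@window_bp, "bp | PAV >=",
      object@pav_min_bp, "bp | slack", object@pav_match_slack_bp,
      "bp | gap run >=", object@min_gap_run, "\n")
})

#' Parameters of the heterozygous diploid simulator
#'
#' The defaults describe the standard simulated scene: a 5-Mb two-chromosome
#' haplotype mutated at a 3.43% SNP rate (three to four SNPs per 100 bp, the
#' heterozygosity level of highly heterozygous forage grasses), with small
#' INDELs (< 50 bp) and large PAVs (>= 50 bp) at rates reproducing roughly
#' 12:1 and 42:1 SNP:INDEL and SNP:PAV count ratios; fragmented into 40
#' primary contigs plus 25 redundant haplotigs.
#'
#' @slot genome_bp Total haplotype-1 length in bp.
#' @slot n_chroms Number of chromosomes.
#' @slot snp_rate Per-bp substitution rate between haplotypes.
#' @slot indel_rate Per-bp small-INDEL event rate.
#' @slot pav_rate Per-bp large-PAV event rate.
#' @slot indel_len_range Small INDEL length range (bp, max < pav_min).
#' @slot pav_len_range PAV length range (bp, min >= 50).
#' @slot n_genes Gene anchors planted per primary contig.
#' @slot n_markers Single-copy complete markers planted per
#'   primary/haplotig pair.
#' @slot n_primary_contigs Number of primary contigs tiling haplotype 1.
#' @slot n_haplotigs Number of redundant haplotigs drawn from haplotype 2.
#' @slot haplotig_len_range Haplotig length range (bp); must stay below the
#'   shortest primary contig.
#' @slot callset_fnr Per-variant false-negative rate of each emitted callset.
#' @slot pav_jitter_bp Maximum uniform start perturbation of read-callset
#'   PAVs.
#' @slot anchor_dropout Per-anchor dropout probability for haplotig gene
#'   copies (noisy scene).
#' @slot aln_trim_frac Fraction of each haplotig alignment trimmed away
#'   (split between both ends; noisy scene).
#' @slot seed Integer seed; fully determines all outputs.
#' @exportClass SimParams
setClass("SimParams", representation(
  genome_bp = "numeric",
  n_chroms = "integer",
  snp_rate = "numeric",
  indel_rate = "numeric",
  pav_rate = "numeric",
  indel_len_range = "integer",
  pav_len_range = "integer",
  n_genes = "integer",
  n_markers = "integer",
  n_primary_contigs = "integer",
  n_haplotigs = "integer",
  haplotig_len_range = "integer",
  callset_fnr = "numeric",
  pav_jitter_bp = "integer",
  anchor_dropout = "numeric",
  aln_trim_frac = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  rates <- c(object@snp_rate, object@indel_rate, object@pav_rate,
             object@callset_fnr, object@anchor_dropout, object@aln_trim_frac)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "all rates must be in [0, 1]")
  if (object@genome_bp < 1000)
    msg <- c(msg, "genome_bp must be >= 1000")
  if (object@n_chroms < 1L || object@n_chroms > object@n_primary_contigs)
    msg <- c(msg, "need 1 <= n_chroms <= n_primary_contigs")
  if (object@pav_len_range[1] < 50L)
    msg <- c(msg, "pav_len_range minimum must be >= 50 bp")
  if (object@indel_len_range[1] < 1L || object@indel_len_range[2] >= 50L)
    msg <- c(msg, "indel_len_range must lie in [1, 49] bp")
  if (diff(object@pav_len_range) < 0 || diff(object@indel_len_range) < 0 ||
      diff(object@haplotig_len_range) < 0)
    msg <- c(msg, "length ranges must be (min, max) with min <= max")
  if (object@n_haplotigs > object@n_primary_contigs)
    msg <- c(msg, "n_haplotigs cannot exceed n_primary_contigs")
  if (object@pav_jitter_bp < 0L)
    msg <- c(msg, "pav_jitter_bp must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param genome_bp,n_chroms,snp_rate,indel_rate,pav_rate,indel_len_range,pav_len_range,n_genes,n_markers,n_primary_contigs,n_haplotigs,haplotig_len_range,callset_fnr,pav_jitter_bp,anchor_dropout,aln_trim_frac,seed
#'   See slot documentation.
#' @return A `SimParams` object.
#' @rdname SimParams-class
#' @export
simParams <- function(genome_bp = 5e6, n_chroms = 2L, snp_rate = 0.0343,
                      indel_rate = 0.00283, pav_rate = 0.00082,
                      indel_len_range = c(1L, 49L),
                      pav_len_range = c(50L, 500L),
                      n_genes = 30L, n_markers = 3L,
                      n_primary_contigs = 40L, n_haplotigs = 25L,
                      haplotig_len_range = c(40000L, 100000L),
                      callset_fnr = 0, pav_jitter_bp = 0L,
                      anchor_dropout = 0, aln_trim_frac = 0, seed = 1L) {
  new("SimParams",
      genome_bp = as.numeric(genome_bp), n_chroms = as.integer(n_chroms),
      snp_rate = snp_rate, indel_rate = indel_rate, pav_rate = pav_rate,
      indel_len_range = as.integer(indel_len_range),
      pav_len_range = as.integer(pav_len_range),
      n_genes = as.integer(n_genes), n_markers = as.integer(n_markers),
      n_primary_contigs = as.integer(n_primary_contigs),
      n_haplotigs = as.integer(n_haplotigs),
      haplotig_len_range = as.integer(haplotig_len_range),
      callset_fnr = callset_fnr, pav_jitter_bp = as.integer(pav_jitter_bp),
      anchor_dropout = anchor_dropout, aln_trim_frac = aln_trim_frac,
      seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", format(object@genome_bp, big.mark = ","), "bp in",
      object@n_chroms, "chromosomes | rates snp", object@snp_rate,
      "indel", object@indel_rate, "pav", object@pav_rate, "\n  ",
      object@n_primary_contigs, "primaries +", object@n_haplotigs,
      "haplotigs | fnr", object@callset_fnr, "| seed", object@seed, "\n")
})

#' A simulated heterozygous diploid dataset with truth labels
#'
#' Produced by [simulateDiploid()]. Haplotype 2 is derived from haplotype 1
#' by planting non-overlapping substitutions, small INDELs and large PAVs;
#' applying `truth(x)` to haplotype 1 reconstructs haplotype 2 exactly.
#' Contigs tile haplotype 1 (primaries) with redundant haplotigs sampled
#' from haplotype 2, each overlapping exactly one primary.
#'
#' @slot h1,h2 The two haplotypes as `DNAStringSet`.
#' @slot contigs Assembly contigs (`DNAStringSet`): primaries + haplotigs.
#' @slot truth Planted variants as a `GRanges` on haplotype-1 coordinates
#'   (mcols: vclass, subtype, ref_len, alt_len, source = "truth",
#'   ref_seq, alt_seq).
#' @slot labels Truth labels: contig_id, label, partner_id, seq_id,
#'   h1_start/h1_end (0-based half-open source span on haplotype 1).
#' @slot anchors Gene anchor table (gene_id, contig_id, start, end, strand).
#' @slot matches Gene-id pairing between primary and haplotig copies.
#' @slot markers Marker hit table (marker_id, contig_id, status, copies).
#' @slot alignments All-by-all contig PAF records (data.frame).
#' @slot hap_alignments Whole-haplotype h2-vs-h1 PAF records (data.frame).
#' @slot callset_wga,callset_read The two noisy callsets (`GRanges`).
#' @slot params The `SimParams` used.
#' @exportClass DiploidSim
setClass("DiploidSim", representation(
  h1 = "DNAStringSet", h2 = "DNAStringSet", contigs = "DNAStringSet",
  truth = "GRanges", labels = "data.frame", anchors = "data.frame",
  matches = "data.frame", markers = "data.frame",
  alignments = "data.frame", hap_alignments = "data.frame",
  callset_wga = "GRanges", callset_read = "GRanges",
  params = "SimParams"
))

setMethod("show", "DiploidSim", function(object) {
  tab <- table(object@labels$label)
  cat("DiploidSim:", length(object@h1), "chromosomes,",
      format(sum(Biostrings::width(object@h1)), big.mark = ","), "bp (h1)\n",
      " contigs:", sum(tab["primary"], na.rm = TRUE), "primary,",
      sum(tab["haplotig"], na.rm = TRUE), "haplotig\n",
      " truth variants:", length(object@truth),
      sprintf("(%d SNP, %d INDEL, %d PAV)",
              sum(object@truth$vclass == "SNP"),
              sum(object@truth$vclass == "INDEL"),
              sum(object@truth$vclass == "PAV")), "\n",
      " seed:", object@params@seed, "\n")
})

#' Result of haplotig classification
#'
#' @slot decisions One row per contig: contig_id, label
#'   (primary/haplotig), partner_id (NA for primaries), triggered_criteria
#'   (comma-joined subset of coverage/synteny/marker), and the evidence
#'   values for the chosen partner.
#' @slot evidence All candidate pair evidence rows (short_id, long_id,
#'   coverage, collinear_genes, shared_markers).
#' @slot config The `PurgeConfig` used.
#' @slot ties Character vector of logged equal-length tie pairs.
#' @exportClass PurgeResult
setClass("PurgeResult", representation(
  decisions = "data.frame",
  evidence = "data.frame",
  config = "PurgeConfig",
  ties = "character"
))

setValidity("PurgeResult", function(object) {
  d <- object@decisions
  need <- c("contig_id", "label", "partner_id", "triggered_criteria")
  if (!all(need %in% names(d)))
    return("decisions must have contig_id, label, partner_id, triggered_criteria")
  hap <- d$label == "haplotig"
  if (any(hap & (is.na(d$partner_id) | d$triggered_criteria == "")))
    return("every haplotig needs a partner and at least one triggered criterion")
  if (any(!hap & !is.na(d$partner_id)))
    return("primary contigs must not carry a partner")
  if (anyDuplicated(d$contig_id))
    return("one decision per contig")
  TRUE
})

setMethod("show", "PurgeResult", function(object) {
  d <- object@decisions
  cat("PurgeResult:", nrow(d), "contigs |", sum(d$label == "haplotig"),
      "haplotigs purged,", sum(d$label == "primary"), "primaries kept\n")
  if (length(object@ties))
    cat("  equal-length ties:", length(object@ties), "\n")
})

#' Variants concordant between two callsets
#'
#' @slot snps,indels,pavs `GRanges` of common variants per class, carried on
#'   the whole-genome-alignment callset's coordinates.
#' @exportClass ConcordanceResult
setClass("ConcordanceResult", representation(
  snps = "GRanges", indels = "GRanges", pavs = "GRanges"
))

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult:", length(object@snps), "SNPs,",
      length(object@indels), "INDELs,", length(object@pavs), "PAVs\n")
})
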