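# Accessor generics for the central classes.

#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))
#' @export
setGeneric("pairEvidence", function(x) standardGeneric("pairEvidence"))
#' @export
setGeneric("haplotigIds", function(x) standardGeneric("haplotigIds"))
#' @export
setGeneric("primaryIds", function(x) standardGeneric("primaryIds"))
#' @export
setGeneric("truthVariants", function(x) standardGeneric("truthVariants"))
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @export
setGeneric("haplotype1", function(x) standardGeneric("haplotype1"))
#' @export
setGeneric("haplotype2", function(x) standardGeneric("haplotype2"))
#' @export
setGeneric("assemblyContigs", function(x) standardGeneric("assemblyContigs"))
#' @export
setGeneric("geneAnchors", function(x) standardGeneric("geneAnchors"))
#' @export
setGeneric("geneMatches", function(x) standardGeneric("geneMatches"))
#' @export
setGeneric("markerHits", function(x) standardGeneric("markerHits"))
#' @export
setGeneric("contigAlignments", function(x) standardGeneric("contigAlignments"))
#' @export
setGeneric("haplotypeAlignments",
           function(x) standardGeneric("haplotypeAlignments"))
#' @export
setGeneric("callset", function(x, which) standardGeneric("callset"))
#' @export
setGeneric("commonSnps", function(x) standardGeneric("commonSnps"))
#' @export
setGeneric("commonIndels", function(x) standardGeneric("commonIndels"))
#' @export
setGeneric("commonPavs", function(x) standardGeneric("commonPavs"))
#' @export
setGeneric("commonVariants", function(x) standardGeneric("commonVariants"))

#' Accessors for PurgeResult
#'
#' @param x A [PurgeResult-class] object.
#' @return `decisions()` the per-contig decision table; `pairEvidence()` the
#'   candidate pair evidence table; `haplotigIds()` / `primaryIds()` the ids
#'   carrying each label.
#' @name PurgeResult-accessors
#' @aliases decisions pairEvidence haplotigIds primaryIds
NULL

#' @rdname PurgeResult-accessors
#' @export
setMethod("decisions", "PurgeResult", function(x) x@decisions)
#' @rdname PurgeResult-accessors
#' @export
setMethod("pairEvidence", "PurgeResult", function(x) x@evidence)
#' @rdname PurgeResult-accessors
#' @export
setMethod("haplotigIds", "PurgeResult", function(x)
  x@decisions$contig_id[x@decisions$label == "haplotig"])
#' @rdname PurgeResult-accessors
#' @export
setMethod("primaryIds", "PurgeResult", function(x)
  x@decisions$contig_id[x@decisions$label == "primary"])

#' Accessors for DiploidSim
#'
#' @param x A [DiploidSim-class] object.
#' @param which For `callset()`, `"wga"` or `"read"`.
#' @return The corresponding slot: haplotypes and contigs as
#'   `DNAStringSet`, truth variants and callsets as `GRanges`, tables as
#'   data.frames.
#' @name DiploidSim-accessors
#' @aliases truthVariants truthLabels haplotype1 haplotype2 assemblyContigs
#'   geneAnchors geneMatches markerHits contigAlignments haplotypeAlignments
#'   callset
NULL

#' @rdname DiploidSim-accessors
#' @export
setMethod("truthVariants", "DiploidSim", function(x) x@truth)
#' @rdname DiploidSim-accessors
#' @export
setMethod("truthLabels", "DiploidSim", function(x) x@labels)
#' @rdname DiploidSim-accessors
#' @export
setMethod("haplotype1", "DiploidSim", function(x) x@h1)
#' @rdname DiploidSim-accessors
#' @export
setMethod("haplotype2", "DiploidSim", function(x) x@h2)
#' @rdname DiploidSim-accessors
#' @export
setMethod("assemblyContigs", "DiploidSim", function(x) x@contigs)
#' @rdname DiploidSim-accessors
#' @export
setMethod("geneAnchors", "DiploidSim", function(x) x@anchors)
#' @rdname DiploidSim-accessors
#' @export
setMethod("geneMatches", "DiploidSim", function(x) x@matches)
#' @rdname DiploidSim-accessors
#' @export
setMethod("markerHits", "DiploidSim", function(x) x@markers)
#' @rdname DiploidSim-accessors
#' @export
setMethod("contigAlignments", "DiploidSim", function(x) x@alignments)
#' @rdname DiploidSim-accessors
#' @export
setMethod("haplotypeAlignments", "DiploidSim", function(x) x@hap_alignments)
#' @rdname DiploidSim-accessors
#' @export
setMethod("callset", "DiploidSim", function(x, which = c("wga", "read")) {
  which <- match.arg(which)
  if (which == "wga") x@callset_wga else x@callset_read
})

#' Accessors for ConcordanceResult
#'
#' @param x A [ConcordanceResult-class] object.
#' @return Per-class `GRanges` of common variants; `commonVariants()`
#'   concatenates all three classes, sorted.
#' @name ConcordanceResult-accessors
#' @aliases commonSnps commonIndels commonPavs commonVariants
NULL

#' @rdname ConcordanceResult-accessors
#' @export
setMethod("commonSnps", "ConcordanceResult", function(x) x@snps)
#' @rdname ConcordanceResult-accessors
#' @export
setMethod("commonIndels", "ConcordanceResult", function(x) x@indels)
#' @rdname ConcordanceResult-accessors
#' @export
setMethod("commonPavs", "ConcordanceResult", function(x) x@pavs)
#' @rdname ConcordanceResult-accessors
#' @export
setMethod("commonVariants", "ConcordanceResult", function(x)
  sort(c(x@snps, x@indels, x@pavs)))
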