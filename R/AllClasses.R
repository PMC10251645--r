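#' @import methods
#' @importFrom S4Vectors Rle runValue runLength mcols mcols<- DataFrame
#' @importFrom IRanges IRanges RleList Views viewSums reduce
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#' @importFrom stats median p.adjust pnorm quantile rnbinom rpois rlnorm runif
#'   sd var wilcox.test rbinom lm coef predict setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Gene models: strand-aware gene and transcript structure
#'
#' Container for the gene/transcript annotation driving all window and exon
#' quantification: per-transcript exon intervals, transcription-direction
#' anchors (TSS and poly(A) site) and per-gene metadata including the
#' selected principal isoform.
#'
#' @slot exons A [GenomicRanges::GRangesList] named by transcript id; each
#'   element holds the transcript's exons sorted by genomic coordinate with
#'   an `exon_rank` metadata column giving the ordinal along the transcript
#'   in transcription direction.
#' @slot transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `tss`, `tes`, `n_exons`. `tss`/`tes` are
#'   transcription-direction anchors: on `+` the TSS is the lowest
#'   coordinate, on `-` the highest, so `tss > tes` on minus-strand
#'   transcripts.
#' @slot genes `data.frame` with columns `gene_id`, `gene_name`, `biotype`,
#'   `principal` (`NA` until [selectPrincipalIsoforms()] has run, or when no
#'   isoform passed the expression filter).
#'
#' @seealso [readGeneAnnotation()], [selectPrincipalIsoforms()],
#'   [filterProteinCodingSet()], [exonUnion()]
#' @export
setClass("GeneModels",
  representation(
    exons = "GRangesList",
    transcripts = "data.frame",
    genes = "data.frame"
  )
)

setValidity("GeneModels", function(object) {
  tx <- object@transcripts
  need <- c("transcript_id", "gene_id", "chrom", "strand", "tss", "tes", "n_exons")
  if (!all(need %in% names(tx))) {
    return(paste("transcripts table must have columns:", paste(need, collapse = ", ")))
  }
  if (!identical(names(object@exons), tx$transcript_id)) {
    return("exons names must match transcripts$transcript_id in order")
  }
  if (!all(tx$n_exons == lengths(object@exons))) {
    return("n_exons must equal the number of exon intervals per transcript")
  }
  plus <- tx$strand == "+"
  if (any(tx$tss[plus] >= tx$tes[plus])) {
    return("plus-strand transcripts must have tss < tes")
  }
  if (any(tx$tss[!plus] <= tx$tes[!plus])) {
    return("minus-strand transcripts must have tss > tes")
  }
  gn <- object@genes
  if (!all(c("gene_id", "biotype", "principal") %in% names(gn))) {
    return("genes table must have columns gene_id, biotype, principal")
  }
  if (!all(tx$gene_id %in% gn$gene_id)) {
    return("every transcript's gene_id must appear in the genes table")
  }
  TRUE
})

#' Strand-specific per-base signal track
#'
#' Per-chromosome run-length-encoded signal values, kept at single-base
#' resolution so that interval quantification weights partial bins exactly.
#' Binned tracks (e.g. 10-bp RPKM coverage) store the bin value replicated
#' across the bases of the bin.
#'
#' @slot fwd,rev [S4Vectors::RleList] of per-base values, one element per
#'   chromosome. For unstranded tracks all signal lives in `fwd` and
#'   `stranded` is `FALSE`.
#' @slot binSize Integer, the bin width the values were computed at (1 for
#'   per-base tracks).
#' @slot normalization `"raw"` or `"RPKM"`.
#' @slot stranded Logical.
#'
#' @seealso [coverageTrack()], [quantifyInterval()], [exportBedGraph()]
#' @export
setClass("SignalTrack",
  representation(
    fwd = "RleList",
    rev = "RleList",
    binSize = "integer",
    normalization = "character",
    stranded = "logical"
  )
)

setValidity("SignalTrack", function(object) {
  if (length(object@binSize) != 1L || object@binSize < 1L) {
    return("binSize must be a single integer >= 1")
  }
  if (!object@normalization %in% c("raw", "RPKM")) {
    return("normalization must be 'raw' or 'RPKM'")
  }
  if (object@stranded && !identical(names(object@fwd), names(object@rev))) {
    return("stranded tracks need matching chromosome sets on both strands")
  }
  TRUE
})

#' Scale-regions metagene profile
#'
#' Regions-by-bins matrix of signal values where every gene body has been
#' linearly rescaled to a common number of bins, flanked by fixed-width
#' upstream and downstream windows, all read TSS to TES left to right.
#'
#' @slot matrix Numeric matrix, one row per retained region; `NA` marks bins
#'   falling outside chromosome bounds.
#' @slot upstreamBins,bodyBins,downstreamBins Integer bin layout.
#' @slot binSize Integer, bases per flank bin.
#' @slot nRegionsExcluded Number of regions dropped by the max-threshold
#'   filter.
#'
#' @seealso [scaleRegionsMatrix()], [meanProfile()], [ratioProfile()]
#' @export
setClass("MetaProfile",
  representation(
    matrix = "matrix",
    upstreamBins = "integer",
    bodyBins = "integer",
    downstreamBins = "integer",
    binSize = "integer",
    nRegionsExcluded = "integer"
  )
)

setValidity("MetaProfile", function(object) {
  total <- object@upstreamBins + object@bodyBins + object@downstreamBins
  if (ncol(object@matrix) != total) {
    return("matrix column count must equal upstreamBins + bodyBins + downstreamBins")
  }
  TRUE
})

#' Differential fraction-enrichment results
#'
#' Per-gene output of the negative-binomial Wald test comparing two sample
#' groups (e.g. nucleoplasm vs chromatin exonic counts), plus the enrichment
#' category once thresholds have been applied.
#'
#' @slot results `data.frame` with columns `gene_id`, `baseMean`, `log2FC`
#'   (group B over group A), `p`, `padj`, `category`, `lowConfidence`.
#' @slot excluded Gene ids dropped before testing (all-zero counts).
#' @slot groupA,groupB Labels of the compared groups.
#' @slot lfcThreshold,alpha Classification thresholds (`NA` before
#'   [classifyFractionEnrichment()] has been applied).
#'
#' @seealso [differentialEnrichment()], [classifyFractionEnrichment()]
#' @export
setClass("EnrichmentResult",
  representation(
    results = "data.frame",
    excluded = "character",
    groupA = "character",
    groupB = "character",
    lfcThreshold = "numeric",
    alpha = "numeric"
  )
)

setValidity("EnrichmentResult", function(object) {
  need <- c("gene_id", "baseMean", "log2FC", "p", "padj", "category", "lowConfidence")
  if (!all(need %in% names(object@results))) {
    return(paste("results must have columns:", paste(need, collapse = ", ")))
  }
  padj <- object@results$padj
  if (any(padj < 0 | padj > 1, na.rm = TRUE)) {
    return("padj must lie in [0, 1]")
  }
  TRUE
})

#' Expression-matched gene subsets
#'
#' Result of iterative random subsampling that draws same-size (or
#' same-fraction) gene subsets from each enrichment category so that the
#' matching covariate no longer differs significantly between any pair.
#'
#' @slot subsets Named list of gene-id character vectors, one per category.
#' @slot pvalues Symmetric matrix of pairwise two-sided Wilcoxon rank-sum
#'   p-values on the covariate, for the returned subsets.
#' @slot nIterationsUsed Iterations evaluated before returning.
#' @slot seed The seed that reproduces the draw.
#' @slot success `TRUE` iff the minimum pairwise p-value exceeds `alpha`.
#' @slot mode `"n"` (fixed size) or `"fraction"`.
#' @slot alpha Significance level defining "no significant difference".
#'
#' @seealso [iterativeSubsampleMatch()]
#' @export
setClass("MatchedSubsets",
  representation(
    subsets = "list",
    pvalues = "matrix",
    nIterationsUsed = "integer",
    seed = "integer",
    success = "logical",
    mode = "character",
    alpha = "numeric"
  )
)

setValidity("MatchedSubsets", function(object) {
  if (object@mode == "n" && length(unique(lengths(object@subsets))) > 1L) {
    return("fixed-size mode requires all subsets to have the same size")
  }
  TRUE
})
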