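#' @describeIn GeneModels-accessors Transcript table (`transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tss`, `tes`, `n_exons`).
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))

#' @describeIn GeneModels-accessors Gene table (`gene_id`, `gene_name`,
#'   `biotype`, `principal`).
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @describeIn GeneModels-accessors Per-transcript exon `GRangesList`.
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))

#' @describeIn GeneModels-accessors Merged (disjoint) exon intervals per
#'   gene as a `GRangesList`. Uses the principal isoform's exons when one
#'   has been selected for the gene, otherwise the union over all isoforms.
#' @export
setGeneric("exonUnion", function(x, ...) standardGeneric("exonUnion"))

#' Accessors for GeneModels
#'
#' @param x A [GeneModels] object.
#' @param ... Unused.
#' @name GeneModels-accessors
#' @aliases transcriptTable geneTable exonsByTranscript exonUnion
NULL

#' @rdname GeneModels-accessors
#' @export
setMethod("transcriptTable", "GeneModels", function(x) x@transcripts)

#' @rdname GeneModels-accessors
#' @export
setMethod("geneTable", "GeneModels", function(x) x@genes)

#' @rdname GeneModels-accessors
#' @export
setMethod("exonsByTranscript", "GeneModels", function(x) x@exons)

#' @rdname GeneModels-accessors
#' @export
setMethod("exonUnion", "GeneModels", function(x, ...) {
  tx <- x@transcripts
  gn <- x@genes
  use_tx <- ifelse(is.na(gn$principal), NA_character_, gn$principal)
  per_gene <- lapply(seq_len(nrow(gn)), function(i) {
    ids <- if (is.na(use_tx[i])) {
      tx$transcript_id[tx$gene_id == gn$gene_id[i]]
    } else {
      use_tx[i]
    }
    reduce(unlist(x@exons[ids], use.names = FALSE))
  })
  names(per_gene) <- gn$gene_id
  GRangesList(per_gene)
})

setMethod("length", "GeneModels", function(x) nrow(x@genes))

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", nrow(object@genes), "genes and",
      nrow(object@transcripts), "transcripts\n")
  cat("  principal isoform selected for",
      sum(!is.na(object@genes$principal)), "genes\n")
  bt <- table(object@genes$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = ", "), "\n")
})

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack (", object@normalization, ", bin size ", object@binSize,
      if (object@stranded) ", stranded" else ", unstranded", ")\n", sep = "")
  cat("  chromosomes:", paste(names(object@fwd), collapse = ", "), "\n")
})

#' @describeIn MetaProfile-accessors Per-bin mean over regions, ignoring
#'   missing values.
#' @export
setGeneric("meanProfile", function(x) standardGeneric("meanProfile"))

#' Accessors for MetaProfile
#'
#' @param x A [MetaProfile].
#' @name MetaProfile-accessors
#' @aliases meanProfile profileMatrix
NULL

#' @rdname MetaProfile-accessors
#' @export
setMethod("meanProfile", "MetaProfile", function(x) {
  colMeans(x@matrix, na.rm = TRUE)
})

#' @describeIn MetaProfile-accessors Regions-by-bins matrix.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname MetaProfile-accessors
#' @export
setMethod("profileMatrix", "MetaProfile", function(x) x@matrix)

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile:", nrow(object@matrix), "regions x",
      ncol(object@matrix), "bins",
      sprintf("(%d upstream + %d body + %d downstream, %d bp flank bins)\n",
              object@upstreamBins, object@bodyBins, object@downstreamBins,
              object@binSize))
  cat("  regions excluded by max-threshold:", object@nRegionsExcluded, "\n")
})

#' @describeIn EnrichmentResult-accessors Per-gene results as a `data.frame`.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' Accessors for EnrichmentResult
#'
#' @param x An [EnrichmentResult].
#' @name EnrichmentResult-accessors
#' @aliases enrichmentTable excludedGenes
NULL

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@results)

#' @describeIn EnrichmentResult-accessors Gene ids excluded before testing.
#' @export
setGeneric("excludedGenes", function(x) standardGeneric("excludedGenes"))

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("excludedGenes", "EnrichmentResult", function(x) x@excluded)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", object@groupB, "vs", object@groupA,
      sprintf("(%d genes tested, %d excluded)\n",
              nrow(object@results), length(object@excluded)))
  if (!is.na(object@alpha)) {
    cat("  thresholds: |log2FC| >", object@lfcThreshold,
        "& padj <", object@alpha, "\n")
    print(table(object@results$category))
  } else {
    cat("  not yet classified; run classifyFractionEnrichment()\n")
  }
})

#' @describeIn MatchedSubsets-accessors Named list of matched gene-id sets.
#' @export
setGeneric("matchedSets", function(x) standardGeneric("matchedSets"))

#' Accessors for MatchedSubsets
#'
#' @param x A [MatchedSubsets].
#' @name MatchedSubsets-accessors
#' @aliases matchedSets matchingPvalues
NULL

#' @rdname MatchedSubsets-accessors
#' @export
setMethod("matchedSets", "MatchedSubsets", function(x) x@subsets)

#' @describeIn MatchedSubsets-accessors Pairwise Wilcoxon p-value matrix on
#'   the matching covariate.
#' @export
setGeneric("matchingPvalues", function(x) standardGeneric("matchingPvalues"))

#' @rdname MatchedSubsets-accessors
#' @export
setMethod("matchingPvalues", "MatchedSubsets", function(x) x@pvalues)

setMethod("show", "MatchedSubsets", function(object) {
  cat("MatchedSubsets (", object@mode, " mode): ",
      paste(names(object@subsets), lengths(object@subsets),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  min pairwise Wilcoxon p:",
      signif(min(object@pvalues[upper.tri(object@pvalues)]), 3),
      "| success:", object@success,
      "| iterations:", object@nIterationsUsed, "\n")
})
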