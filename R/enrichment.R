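#' Count read pairs on exon unions
#'
#' A pair is counted for a gene iff at least one aligned block overlaps the
#' gene's merged exon intervals on the matching transcription strand; each
#' pair is counted at most once per gene. In split-aware mode the gapped
#' (junction) structure of the alignment is respected, so a pair whose gap
#' merely spans an exon contributes nothing to that exon; otherwise each
#' mate's full reference span is used.
#'
#' @param pairs A `GAlignmentPairs` (see [readAlignments()]).
#' @param models A [GeneModels]; counting uses [exonUnion()].
#' @param strandSpecific Require the pair's transcription strand to match
#'   the gene strand.
#' @param splitAware Use gapped aligned blocks rather than full spans.
#' @param layout Library layout; see [transcriptionStrand()].
#' @return Named integer vector of counts, one per gene in `models`.
#' @export
countExonic <- function(pairs, models, strandSpecific = TRUE,
                        splitAware = TRUE, layout = "dUTP") {
  eu <- exonUnion(models)
  gene_strand <- vapply(seq_along(eu), function(i) {
    as.character(strand(eu[[i]]))[1]
  }, character(1))
  blocks <- if (splitAware) {
    GenomicAlignments::grglist(pairs)
  } else {
    grA <- GenomicRanges::granges(GenomicAlignments::first(pairs))
    grB <- GenomicRanges::granges(GenomicAlignments::last(pairs))
    S4Vectors::split(c(grA, grB), rep(seq_along(pairs), 2L))
  }
  ov <- GenomicRanges::findOverlaps(blocks, eu, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (strandSpecific) {
    ts <- as.character(transcriptionStrand(pairs, layout))
    keep <- ts[qh] == gene_strand[sh]
    qh <- qh[keep]
    sh <- sh[keep]
  }
  hit <- unique(data.frame(pair = qh, gene = sh))
  cnt <- tabulate(hit$gene, nbins = length(eu))
  stats::setNames(as.integer(cnt), names(eu))
}

#' Median-of-ratios size factors
#'
#' For each sample the factor is the median, over genes positive in every
#' sample, of the gene's count divided by its geometric mean across
#' samples. Identical samples get identical factors; a uniform doubling of
#' one sample doubles its factor.
#'
#' @param counts Genes x samples integer matrix.
#' @return Named numeric vector of per-sample factors.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    stop("no gene has positive counts in every sample; ",
         "consider a pseudo-reference normalization")
  }
  k <- counts[allpos, , drop = FALSE]
  loggeo <- rowMeans(log(k))
  apply(k, 2, function(col) exp(median(log(col) - loggeo)))
}

# coerce count input + group spec into a matrix and two column-index sets
.resolve_groups <- function(counts, groupA, groupB) {
  if (is(counts, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(counts)
    m <- SummarizedExperiment::assay(counts, "counts")
    pick <- function(g) {
      if (is.character(g) && length(g) == 1L && "fraction" %in% names(cd) &&
          g %in% cd$fraction) {
        return(which(cd$fraction == g))
      }
      if (is.character(g)) return(match(g, colnames(m)))
      g
    }
    list(m = as.matrix(m), A = pick(groupA), B = pick(groupB),
         labA = if (is.character(groupA) && length(groupA) == 1L) groupA else "groupA",
         labB = if (is.character(groupB) && length(groupB) == 1L) groupB else "groupB")
  } else {
    m <- as.matrix(counts)
    idx <- function(g) if (is.character(g)) match(g, colnames(m)) else g
    list(m = m, A = idx(groupA), B = idx(groupB),
         labA = "groupA", labB = "groupB")
  }
}

#' Negative-binomial Wald test for differential fraction enrichment
#'
#' A self-contained NB Wald test on exonic counts. Per gene: counts are
#' normalized by median-of-ratios size factors; the reported fold change is
#' `log2((mB + 0.5) / (mA + 0.5))` on normalized group means (pseudocount
#' 0.5 tames zeros); the NB dispersion `alpha` (variance `mu + alpha*mu^2`)
#' is estimated by method-of-moments from the pooled within-group variance,
#' then shrunk 50/50 toward a log-linear mean-dispersion trend fitted
#' across genes; the Wald statistic uses a delta-method standard error of
#' the log fold change and a two-sided normal p-value; BH adjustment is
#' applied over all tested genes. Genes with zero counts in every used
#' sample are excluded and reported.
#'
#' @param counts Genes x samples matrix, or a `SummarizedExperiment` with a
#'   `counts` assay and a `fraction` colData column.
#' @param groupA,groupB Column indices/names, or (for a
#'   SummarizedExperiment) a fraction label. The fold change is B over A.
#' @param lowCountFloor Genes with `baseMean` below this are flagged
#'   low-confidence (default 10).
#' @return An [EnrichmentResult] (not yet classified; see
#'   [classifyFractionEnrichment()]).
#' @export
differentialEnrichment <- function(counts, groupA, groupB,
                                   lowCountFloor = 10) {
  g <- .resolve_groups(counts, groupA, groupB)
  m <- g$m[, c(g$A, g$B), drop = FALSE]
  iA <- seq_along(g$A)
  iB <- length(g$A) + seq_along(g$B)
  if (length(iA) < 2L || length(iB) < 2L) {
    stop("need >= 2 replicates per group for dispersion estimation")
  }
  nonzero <- rowSums(m) > 0
  excluded <- rownames(m)[!nonzero]
  if (length(excluded)) {
    message(length(excluded), " all-zero gene(s) excluded from testing")
  }
  m <- m[nonzero, , drop = FALSE]
  sf <- sizeFactorsMedianRatio(m)
  q <- sweep(m, 2, sf, "/")
  nA <- length(iA)
  nB <- length(iB)
  mA <- rowMeans(q[, iA, drop = FALSE])
  mB <- rowMeans(q[, iB, drop = FALSE])
  baseMean <- rowMeans(q)
  lfc <- log2((mB + 0.5) / (mA + 0.5))

  varA <- apply(q[, iA, drop = FALSE], 1, var)
  varB <- apply(q[, iB, drop = FALSE], 1, var)
  var_w <- ((nA - 1) * varA + (nB - 1) * varB) / (nA + nB - 2)
  mean_w <- (nA * mA + nB * mB) / (nA + nB)
  disp_mom <- pmax(0, (var_w - mean_w) / mean_w^2)

  # log-linear mean-dispersion trend, fitted on binned means of the raw
  # moment estimates (binning before the log keeps the fit unbiased for
  # E[dispersion | mean]; the per-gene estimates are zero-truncated and
  # log-skewed, so fitting them directly would bias the trend downward)
  nbin <- max(2L, min(20L, floor(length(disp_mom) / 50)))
  bins <- cut(log(mean_w), nbin)
  bin_disp <- tapply(disp_mom, bins, mean)
  bin_mean <- tapply(log(mean_w), bins, mean)
  fit_ok <- is.finite(bin_disp) & bin_disp > 0 & is.finite(bin_mean)
  disp_trend <- if (sum(fit_ok) >= 3L) {
    fit <- lm(bin_disp[fit_ok] ~ bin_mean[fit_ok],
              weights = as.vector(table(bins))[fit_ok])
    pmax(1e-8, coef(fit)[1] + coef(fit)[2] * log(mean_w))
  } else {
    rep(max(mean(disp_mom), 1e-8), length(disp_mom))
  }
  disp <- 0.5 * disp_mom + 0.5 * disp_trend

  # delta-method variance of log2 of the shifted group means
  inv_sf_A <- sum(1 / sf[iA])
  inv_sf_B <- sum(1 / sf[iB])
  varMeanA <- (mA * inv_sf_A / nA^2) + disp * mA^2 / nA
  varMeanB <- (mB * inv_sf_B / nB^2) + disp * mB^2 / nB
  se2 <- (varMeanA / (mA + 0.5)^2 + varMeanB / (mB + 0.5)^2) / log(2)^2
  se <- sqrt(se2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = "BH")

  res <- data.frame(
    gene_id = rownames(m),
    baseMean = baseMean,
    log2FC = lfc,
    p = p,
    padj = padj,
    category = NA_character_,
    lowConfidence = baseMean < lowCountFloor,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  new("EnrichmentResult", results = res, excluded = excluded,
      groupA = g$labA, groupB = g$labB,
      lfcThreshold = NA_real_, alpha = NA_real_)
}

#' Classify genes by fraction enrichment
#'
#' Applies the classification thresholds to a tested [EnrichmentResult]:
#' `log2FC > lfcThreshold` with `padj < alpha` is nucleoplasm-enriched,
#' `log2FC < -lfcThreshold` with `padj < alpha` is chromatin-enriched, and
#' everything else is non-enriched. The three categories partition the
#' tested gene set.
#'
#' @param x An [EnrichmentResult] from [differentialEnrichment()] with
#'   nucleoplasm as group B and chromatin as group A.
#' @param lfcThreshold Fold-change threshold on the log2 scale (default 1).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return `x` with the `category` column filled and thresholds recorded.
#' @export
classifyFractionEnrichment <- function(x, lfcThreshold = 1, alpha = 0.05) {
  stopifnot(is(x, "EnrichmentResult"))
  r <- x@results
  cat_ <- rep("non-enriched", nrow(r))
  sig <- !is.na(r$padj) & r$padj < alpha
  cat_[sig & r$log2FC > lfcThreshold] <- "nucleoplasm-enriched"
  cat_[sig & r$log2FC < -lfcThreshold] <- "chromatin-enriched"
  x@results$category <- cat_
  x@lfcThreshold <- lfcThreshold
  x@alpha <- alpha
  validObject(x)
  x
}

#' Chromatin-association index
#'
#' Log2 enrichment of chromatin RNA-seq over nascent (POINT-seq-like)
#' exonic counts: high values indicate transcripts retained on chromatin
#' after synthesis. Internally reuses [differentialEnrichment()] with
#' nascent as the reference group, so the index is the `log2FC` column and
#' `baseMean` supports an MA-style scatter.
#'
#' @param counts As in [differentialEnrichment()].
#' @param chromatin,nascent Group specifications (fraction labels, column
#'   names or indices).
#' @param ... Passed to [differentialEnrichment()].
#' @return An [EnrichmentResult] whose `log2FC` is the association index.
#' @export
chromatinAssociationIndex <- function(counts, chromatin = "chromatin",
                                      nascent = "nascent", ...) {
  differentialEnrichment(counts, groupA = nascent, groupB = chromatin, ...)
}
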