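#' Classify alignment records as spliced or unspliced
#'
#' A record is spliced iff its alignment contains a reference gap (an `N`
#' CIGAR operation, i.e. at least two aligned blocks separated by a
#' skipped region). Insertions and deletions alone do not qualify.
#'
#' @param x A `GAlignments`, a `GAlignmentPairs` (classified per mate), or
#'   a character vector of CIGAR strings.
#' @return Logical vector (for pairs: `TRUE` if either mate is spliced).
#' @export
classifySpliced <- function(x) {
  if (is.character(x)) {
    return(grepl("N", x, fixed = TRUE))
  }
  if (is(x, "GAlignmentPairs")) {
    return(GenomicAlignments::njunc(GenomicAlignments::first(x)) > 0L |
           GenomicAlignments::njunc(GenomicAlignments::last(x)) > 0L)
  }
  GenomicAlignments::njunc(x) > 0L
}

#' Per-transcript co-transcriptional splicing-efficiency index
#'
#' For each multi-exon transcript, counts the read pairs overlapping the
#' transcript span (split-aware, strand-matched, each pair at most once per
#' transcript), classifies each pair as spliced (either mate's CIGAR
#' contains an `N` gap) or unspliced, and reports the raw splicing index
#' `se_raw = n_spliced / n_total` together with its exon-normalized form
#' `se_norm = se_raw / n_exons` (optionally `/ (n_exons - 1)`, the junction
#' count). Pairs overlapping several queried transcripts count for each of
#' them.
#'
#' @param pairs A `GAlignmentPairs` of properly-paired records.
#' @param models A [GeneModels]; all transcripts with `n_exons >= 2` are
#'   scored.
#' @param minReads Transcripts with fewer than this many overlapping pairs
#'   are flagged unreliable (default 10).
#' @param strandSpecific Match the pair's transcription strand to the
#'   transcript strand.
#' @param normalizeBy `"exons"` (default) or `"junctions"` for the
#'   `se_norm` divisor.
#' @param layout Library layout; see [transcriptionStrand()].
#' @return `data.frame` with columns `transcript_id`, `gene_id`,
#'   `n_spliced`, `n_total`, `se_raw`, `se_norm`, `reliable`. Transcripts
#'   with no overlapping pairs get `NA` indices.
#' @export
transcriptSplicingIndex <- function(pairs, models, minReads = 10L,
                                    strandSpecific = TRUE,
                                    normalizeBy = c("exons", "junctions"),
                                    layout = "dUTP") {
  normalizeBy <- match.arg(normalizeBy)
  tx <- models@transcripts
  tx <- tx[tx$n_exons >= 2L, , drop = FALSE]
  if (nrow(tx) == 0L) stop("no multi-exon transcripts to score")
  span <- GRanges(tx$chrom,
                  IRanges(pmin(tx$tss, tx$tes), pmax(tx$tss, tx$tes)),
                  strand = tx$strand)
  blocks <- GenomicAlignments::grglist(pairs)
  ov <- GenomicRanges::findOverlaps(blocks, span, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (strandSpecific) {
    ts <- as.character(transcriptionStrand(pairs, layout))
    keep <- ts[qh] == tx$strand[sh]
    qh <- qh[keep]
    sh <- sh[keep]
  }
  hit <- unique(data.frame(pair = qh, tx = sh))
  spliced <- classifySpliced(pairs)
  n_total <- tabulate(hit$tx, nbins = nrow(tx))
  n_spliced <- tabulate(hit$tx[spliced[hit$pair]], nbins = nrow(tx))
  divisor <- if (normalizeBy == "exons") tx$n_exons else tx$n_exons - 1L
  se_raw <- ifelse(n_total > 0, n_spliced / n_total, NA_real_)
  data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    n_spliced = as.integer(n_spliced),
    n_total = as.integer(n_total),
    se_raw = se_raw,
    se_norm = se_raw / divisor,
    reliable = n_total >= minReads,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Compare a per-gene statistic between enrichment categories
#'
#' Convenience wrapper producing per-category summaries and all pairwise
#' two-sided Wilcoxon rank-sum p-values for a numeric statistic (splicing
#' index, RTI, ...) grouped by category.
#'
#' @param values Numeric vector.
#' @param category Character/factor vector of the same length.
#' @return A list with `medians` (named numeric) and `pvalues` (symmetric
#'   matrix of pairwise Wilcoxon p-values).
#' @export
compareByCategory <- function(values, category) {
  ok <- !is.na(values) & !is.na(category)
  values <- values[ok]
  category <- as.character(category)[ok]
  cats <- sort(unique(category))
  med <- vapply(cats, function(cc) median(values[category == cc]), numeric(1))
  pm <- matrix(NA_real_, length(cats), length(cats),
               dimnames = list(cats, cats))
  diag(pm) <- 1
  if (length(cats) >= 2L) {
    for (i in seq_len(length(cats) - 1L)) {
      for (j in (i + 1L):length(cats)) {
        pm[i, j] <- pm[j, i] <- wilcox.test(
          values[category == cats[i]], values[category == cats[j]],
          alternative = "two.sided", exact = FALSE)$p.value
      }
    }
  }
  list(medians = med, pvalues = pm)
}
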