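#' Cohort pseudocount for the read-through index
#'
#' The RTI pseudocount `c` is half of the smallest positive finite
#' gene-body/downstream signal ratio observed across the evaluated gene
#' set (the smallest-representable-ratio convention).
#'
#' @param ratios Numeric vector of GB/TES ratios (zeros, `NA` and infinite
#'   values are ignored).
#' @return The pseudocount, a single positive number.
#' @export
computePseudocount <- function(ratios) {
  pos <- ratios[!is.na(ratios) & is.finite(ratios) & ratios > 0]
  if (!length(pos)) stop("no positive finite ratio; pseudocount undefined")
  min(pos) / 2
}

#' Read-through index (RTI) per gene
#'
#' For each gene with a principal isoform, sums strand-specific signal over
#' the gene body (TSS to TES) and over a fixed window downstream of the
#' poly(A) site in transcription direction, then computes
#' `RTI = log2(GB/TES + c)` with the cohort pseudocount `c` from
#' [computePseudocount()]. Genes with downstream signal but an empty gene
#' body raise an error; genes with `TES = 0` and `GB > 0` have an infinite
#' ratio and are reported with `rti = NA` under the default policy. The
#' index is invariant to a global rescaling of the track, monotone
#' increasing in gene-body signal and decreasing in downstream signal.
#'
#' @param track A strand-specific [SignalTrack].
#' @param models A [GeneModels] with principal isoforms selected.
#' @param tesWindow Downstream window length in bases (default 2500).
#' @param excludeOverlapNeighbors Drop genes whose downstream window
#'   overlaps another gene body on the same strand (default `FALSE`).
#' @return `data.frame` with columns `gene_id`, `gb_signal`, `tes_signal`,
#'   `ratio`, `rti`; the pseudocount is attached as `attr(, "pseudocount")`.
#' @export
readthroughIndex <- function(track, models, tesWindow = 2500L,
                             excludeOverlapNeighbors = FALSE) {
  tt <- .principal_tx_table(models)
  if (nrow(tt) == 0L) stop("no genes with principal isoforms")
  body_start <- pmin(tt$tss, tt$tes)
  body_end <- pmax(tt$tss, tt$tes)
  if (any(body_end <= body_start)) stop("zero-length gene body")
  down_start <- ifelse(tt$strand == "+", tt$tes + 1L, tt$tes - tesWindow)
  down_end <- down_start + tesWindow - 1L

  if (excludeOverlapNeighbors) {
    bodies <- GRanges(tt$chrom, IRanges(body_start, body_end),
                      strand = tt$strand)
    downs <- GRanges(tt$chrom, IRanges(pmax(1L, down_start), down_end),
                     strand = tt$strand)
    ov <- GenomicRanges::findOverlaps(downs, bodies)
    bad <- unique(S4Vectors::queryHits(ov)[S4Vectors::queryHits(ov) !=
                                             S4Vectors::subjectHits(ov)])
    if (length(bad)) {
      message("excluding ", length(bad),
              " gene(s) whose downstream window overlaps a neighbour")
      keep <- setdiff(seq_len(nrow(tt)), bad)
      tt <- tt[keep, , drop = FALSE]
      body_start <- body_start[keep]
      body_end <- body_end[keep]
      down_start <- down_start[keep]
      down_end <- down_end[keep]
    }
  }

  gb <- tes <- numeric(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    gb[i] <- quantifyInterval(track, tt$chrom[i], body_start[i], body_end[i],
                              tt$strand[i])
    tes[i] <- quantifyInterval(track, tt$chrom[i], max(1L, down_start[i]),
                               down_end[i], tt$strand[i])
  }
  ratio <- ifelse(tes > 0, gb / tes, ifelse(gb > 0, Inf, NA_real_))
  has_pos <- any(!is.na(ratio) & is.finite(ratio) & ratio > 0)
  c_ <- if (has_pos) computePseudocount(ratio) else NA_real_
  rti <- if (has_pos) {
    ifelse(is.finite(ratio), log2(ratio + c_), NA_real_)
  } else rep(NA_real_, length(ratio))
  out <- data.frame(gene_id = tt$gene_id, gb_signal = gb, tes_signal = tes,
                    ratio = ratio, rti = rti,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pseudocount") <- c_
  out
}
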