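#' Simulation configuration for synthetic fractionation cohorts
#'
#' Bundles and validates all generator parameters. Every downstream
#' simulator is a pure function of `(config, seed)`.
#'
#' @param nGenes Number of genes.
#' @param proportions Named proportions over the three enrichment
#'   categories; must sum to 1. Allocation is deterministic (largest-floor,
#'   remainder in category order), so e.g. 300 genes at (1/3, 1/3, 1/3)
#'   give exactly 100 per category.
#' @param delta Magnitude `d` of the true nucleoplasm-vs-chromatin log2 fold
#'   change: nucleoplasm-enriched genes get `+d`, chromatin-enriched `-d`,
#'   non-enriched 0.
#' @param dispersion NB dispersion `alpha`; counts are drawn with variance
#'   `mean + alpha * mean^2` (`alpha = 0` means Poisson).
#' @param libSize Expected library depth per sample; fraction means are
#'   scaled so each column's expected sum equals `libSize`.
#' @param repsPerFraction Replicates per fraction.
#' @param readsPerGene Paired-end fragments per gene for simulated
#'   alignments.
#' @param junctionProb Probability `q` that a simulated fragment spans an
#'   exon-exon junction; with per-gene splicing probability `s` the expected
#'   raw splicing index is `q * s`.
#' @param readLength Aligned bases per mate.
#' @param exonCountRange Inclusive range the per-gene exon count is drawn
#'   uniformly from.
#' @param exonLength,intronLength Exon/intron sizes in bases.
#' @param geneSpacing Intergenic gap in bases (keeps flank and downstream
#'   windows of neighbouring genes disjoint).
#' @param meanLog,sdLog Log-normal parameters for the expected nascent
#'   expression `lam` (mean exonic fragments per library).
#' @param splicingProb Named per-category junction splicing probability `s`.
#'   Defaults encode the structure under study: chromatin-enriched
#'   transcripts splice worst, nucleoplasm-enriched best.
#' @param readthroughFraction Named per-category read-through fraction
#'   `rho` (per-base signal density past the poly(A) site relative to
#'   gene-body density). Defaults give chromatin-enriched genes the most
#'   read-through.
#' @param retention Named per-category chromatin-association multiplier
#'   (>= 1) applied to the chromatin-fraction mean.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 300L,
                             proportions = c("chromatin-enriched" = 1 / 3,
                                             "nucleoplasm-enriched" = 1 / 3,
                                             "non-enriched" = 1 / 3),
                             delta = 2,
                             dispersion = 0.05,
                             libSize = 1e6,
                             repsPerFraction = 3L,
                             readsPerGene = 1000L,
                             junctionProb = 1,
                             readLength = 50L,
                             exonCountRange = c(2L, 20L),
                             exonLength = 200L,
                             intronLength = 1000L,
                             geneSpacing = 10000L,
                             meanLog = log(200),
                             sdLog = 0.5,
                             splicingProb = c("chromatin-enriched" = 0.5,
                                              "nucleoplasm-enriched" = 0.9,
                                              "non-enriched" = 0.7),
                             readthroughFraction = c("chromatin-enriched" = 0.5,
                                                     "nucleoplasm-enriched" = 0.1,
                                                     "non-enriched" = 0.2),
                             retention = c("chromatin-enriched" = 1,
                                           "nucleoplasm-enriched" = 1,
                                           "non-enriched" = 1),
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (nGenes < 1L) stop("nGenes must be >= 1")
  cats <- c("chromatin-enriched", "nucleoplasm-enriched", "non-enriched")
  if (!setequal(names(proportions), cats)) {
    stop("proportions must be named over: ", paste(cats, collapse = ", "))
  }
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("proportions must be non-negative and sum to 1")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  for (nm in c("splicingProb", "readthroughFraction", "retention")) {
    v <- get(nm)
    if (!all(cats %in% names(v))) stop(nm, " must be named over all categories")
  }
  if (any(splicingProb < 0 | splicingProb > 1)) stop("splicingProb in [0,1]")
  if (any(readthroughFraction < 0 | readthroughFraction > 1)) {
    stop("readthroughFraction in [0,1]")
  }
  if (any(retention < 1)) stop("retention must be >= 1")
  cfg <- list(nGenes = as.integer(nGenes),
              proportions = proportions[cats], delta = delta,
              dispersion = dispersion, libSize = libSize,
              repsPerFraction = as.integer(repsPerFraction),
              readsPerGene = as.integer(readsPerGene),
              junctionProb = junctionProb, readLength = as.integer(readLength),
              exonCountRange = as.integer(exonCountRange),
              exonLength = as.integer(exonLength),
              intronLength = as.integer(intronLength),
              geneSpacing = as.integer(geneSpacing),
              meanLog = meanLog, sdLog = sdLog,
              splicingProb = splicingProb[cats],
              readthroughFraction = readthroughFraction[cats],
              retention = retention[cats],
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# deterministic category allocation: floors, remainder in category order
.allocate_categories <- function(n, proportions) {
  base <- floor(n * proportions)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * proportions - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  rep(names(proportions), times = base)
}

#' Simulate a gene cohort with known ground truth
#'
#' Lays out `nGenes` disjoint multi-exon genes on a synthetic chromosome
#' (alternating strands, spaced by `geneSpacing`), assigns each a category
#' and the per-gene simulation parameters, and returns both the
#' [GeneModels] and the ground-truth table used by all other simulators.
#'
#' @param config A [simulationConfig()].
#' @return A list with elements `models` ([GeneModels], one transcript per
#'   gene, principal pre-selected) and `truth` (`data.frame` with columns
#'   `gene_id`, `category`, `lam`, `delta`, `s`, `rho`, `retention`).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nGenes
  category <- .allocate_categories(n, config$proportions)
  delta <- ifelse(category == "nucleoplasm-enriched", config$delta,
                  ifelse(category == "chromatin-enriched", -config$delta, 0))
  truth <- data.frame(
    gene_id = sprintf("SGENE%04d", seq_len(n)),
    category = category,
    lam = rlnorm(n, meanlog = config$meanLog, sdlog = config$sdLog),
    delta = delta,
    s = unname(config$splicingProb[category]),
    rho = unname(config$readthroughFraction[category]),
    retention = unname(config$retention[category]),
    stringsAsFactors = FALSE
  )

  ex_choices <- seq(config$exonCountRange[1], config$exonCountRange[2])
  n_ex <- if (length(ex_choices) == 1L) rep(ex_choices, n) else
    sample(ex_choices, n, replace = TRUE)
  strand <- rep(c("+", "-"), length.out = n)
  gene_len <- n_ex * config$exonLength + (n_ex - 1L) * config$intronLength
  gstart <- config$geneSpacing +
    cumsum(c(0L, utils::head(gene_len + config$geneSpacing, -1L)))
  chrom <- "chrS1"
  chrom_len <- gstart[n] + gene_len[n] + config$geneSpacing

  tx_id <- sub("SGENE", "STX", truth$gene_id)
  # all exons in one vectorized GRanges, then split per transcript
  per_gene <- rep(seq_len(n), n_ex)
  within_gene <- sequence(n_ex)
  estarts <- gstart[per_gene] +
    (within_gene - 1L) * (config$exonLength + config$intronLength)
  ex_all <- GRanges(chrom, IRanges(estarts, width = config$exonLength),
                    strand = strand[per_gene])
  rank_ <- ifelse(strand[per_gene] == "-",
                  n_ex[per_gene] - within_gene + 1L, within_gene)
  mcols(ex_all)$exon_rank <- rank_
  exl <- S4Vectors::split(ex_all, factor(tx_id[per_gene], levels = tx_id))
  GenomeInfoDb::seqlengths(exl) <- stats::setNames(chrom_len, chrom)

  tx <- data.frame(
    transcript_id = tx_id,
    gene_id = truth$gene_id,
    chrom = chrom,
    strand = strand,
    tss = ifelse(strand == "+", gstart, gstart + gene_len - 1L),
    tes = ifelse(strand == "+", gstart + gene_len - 1L, gstart),
    n_exons = as.integer(n_ex),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- tx_id
  genes <- data.frame(
    gene_id = truth$gene_id,
    gene_name = truth$gene_id,
    biotype = "protein_coding",
    principal = tx_id,
    stringsAsFactors = FALSE
  )
  rownames(genes) <- genes$gene_id
  models <- new("GeneModels", exons = exl, transcripts = tx, genes = genes)
  list(models = models, truth = truth)
}

# expected (unscaled) per-fraction means implied by the generative model
.fraction_means <- function(truth) {
  cbind(chromatin = truth$lam * 2^(-truth$delta / 2) * truth$retention,
        nucleoplasm = truth$lam * 2^(truth$delta / 2),
        nascent = truth$lam)
}

#' Simulate fraction-specific exonic count matrices
#'
#' Draws negative-binomial exonic counts for chromatin, nucleoplasm and
#' nascent (POINT-seq-like) samples. Generative means per gene: chromatin
#' `lam * 2^(-delta/2) * retention`, nucleoplasm `lam * 2^(+delta/2)`,
#' nascent `lam`; each fraction's means are rescaled so the expected column
#' sum equals `libSize`. Variance is `mean + alpha * mean^2`.
#'
#' @param truth Ground-truth table from [simulateCohort()].
#' @param config The same [simulationConfig()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (genes x samples) and colData columns `fraction` and
#'   `replicate`.
#' @export
simulateFractionCounts <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  mu <- .fraction_means(truth)
  reps <- config$repsPerFraction
  cols <- expand.grid(replicate = seq_len(reps),
                      fraction = colnames(mu),
                      stringsAsFactors = FALSE)[, 2:1]
  counts <- matrix(0L, nrow = nrow(truth), ncol = nrow(cols),
                   dimnames = list(truth$gene_id,
                                   paste(cols$fraction, cols$replicate,
                                         sep = "_")))
  for (j in seq_len(nrow(cols))) {
    m <- mu[, cols$fraction[j]]
    m <- m * config$libSize / sum(m)
    counts[, j] <- if (config$dispersion > 0) {
      rnbinom(length(m), mu = m, size = 1 / config$dispersion)
    } else {
      rpois(length(m), m)
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(fraction = cols$fraction,
                        replicate = cols$replicate,
                        row.names = colnames(counts))
  )
}

#' Simulate paired-end alignments with controlled splicing evidence
#'
#' Writes a SAM file of properly-paired fragments per gene. Each fragment
#' spans an exon-exon junction with probability `junctionProb`; a
#' junction-spanning fragment is spliced (its gene-strand mate carries an
#' N gap in the CIGAR) with the gene's splicing probability `s`, and
#' otherwise aligns contiguously across the intron. Expected raw splicing
#' index per gene is therefore `junctionProb * s`. The library layout is
#' dUTP-style: mate 1 aligns opposite to the transcription strand, mate 2
#' on it. Output is byte-identical for a fixed seed.
#'
#' @param truth,models From [simulateCohort()].
#' @param config The [simulationConfig()] (uses `readsPerGene`,
#'   `junctionProb`, `readLength`, `seed`).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
simulateAlignments <- function(truth, models, config, path) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  readLen <- config$readLength
  q <- config$junctionProb
  tt <- .principal_tx_table(models)
  exl <- models@exons[tt$transcript_id]
  sl <- GenomeInfoDb::seqlengths(exl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ch in names(sl)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, sl[[ch]]), con)
  }
  seq1 <- strrep("A", readLen)
  for (i in seq_len(nrow(tt))) {
    g <- tt$gene_id[i]
    e <- exl[[i]]
    st <- tt$strand[i]
    n_ex <- length(e)
    s_g <- truth$s[truth$gene_id == g]
    nreads <- config$readsPerGene
    spans <- runif(nreads) < q & n_ex >= 2L
    spliced <- spans & runif(nreads) < s_g
    jx <- if (n_ex >= 2L) sample(n_ex - 1L, nreads, replace = TRUE) else
      rep(1L, nreads)
    ew <- width(e)
    # mate 1: contiguous within a random exon (opposite strand)
    ex1 <- sample(n_ex, nreads, replace = TRUE)
    pos1 <- as.integer(start(e)[ex1] +
      floor(runif(nreads) * (ew[ex1] - readLen + 1)))
    # mate 2: junction-anchored when the fragment spans one, else exonic
    a <- sample(10:(readLen - 10L), nreads, replace = TRUE)
    jend <- end(e)[jx]
    gap <- start(e)[pmin(jx + 1L, n_ex)] - jend - 1L
    pos2_exonic <- as.integer(start(e)[ex1] +
      floor(runif(nreads) * (ew[ex1] - readLen + 1)))
    pos2 <- as.integer(ifelse(spans, jend - a + 1L, pos2_exonic))
    cig2 <- ifelse(spliced, sprintf("%dM%dN%dM", a, gap, readLen - a),
                   sprintf("%dM", readLen))
    seq2 <- seq1
    if (st == "+") {
      f1 <- 83L; f2 <- 163L       # mate1 reverse, mate2 forward
    } else {
      f1 <- 99L; f2 <- 147L       # mate1 forward, mate2 reverse
    }
    tlen <- as.integer(pmax(pos1, pos2) - pmin(pos1, pos2) + readLen)
    qname <- sprintf("%s_R%05d", g, seq_len(nreads))
    l1 <- paste(qname, f1, tt$chrom[i], pos1, 255L,
                sprintf("%dM", readLen), "=", pos2, tlen, seq1, "*",
                sep = "\t")
    l2 <- paste(qname, f2, tt$chrom[i], pos2, 255L, cig2, "=", pos1,
                -tlen, seq2, "*", sep = "\t")
    lines <- character(2L * nreads)
    lines[c(TRUE, FALSE)] <- l1
    lines[c(FALSE, TRUE)] <- l2
    writeLines(lines, con)
  }
  invisible(path)
}

#' Simulate strand-specific nascent-transcription signal tracks
#'
#' Lays a flat per-base density `d_g = lam_g` over each gene body
#' (TSS..TES) on the gene's strand and `rho_g * d_g` over the
#' `downstreamWindow` bases past the poly(A) site (flat, or exponentially
#' decaying). Optional Poisson noise replaces each base's value by a
#' Poisson draw with that mean.
#'
#' @param truth,models From [simulateCohort()].
#' @param downstreamWindow Bases of read-through signal past the TES.
#' @param noise Add per-base Poisson noise.
#' @param decay `"flat"` or `"exponential"` (halving every quarter of the
#'   window) shape of the downstream signal.
#' @param seed Seed used only when `noise = TRUE`.
#' @return A strand-specific per-base [SignalTrack].
#' @export
simulateSignalTracks <- function(truth, models, downstreamWindow = 2500L,
                                 noise = FALSE, decay = c("flat", "exponential"),
                                 seed = 1L) {
  decay <- match.arg(decay)
  tt <- .principal_tx_table(models)
  tt <- tt[truth$gene_id, , drop = FALSE]
  sl <- GenomeInfoDb::seqlengths(models@exons)
  if (anyNA(sl)) stop("gene models must carry chromosome lengths")
  body <- GRanges(tt$chrom,
                  IRanges(pmin(tt$tss, tt$tes), pmax(tt$tss, tt$tes)),
                  strand = tt$strand)
  ov <- GenomicRanges::findOverlaps(body, drop.self = TRUE,
                                    drop.redundant = TRUE)
  if (length(ov) > 0 &&
      any(as.character(strand(body))[S4Vectors::queryHits(ov)] ==
          as.character(strand(body))[S4Vectors::subjectHits(ov)])) {
    stop("overlapping genes on the same strand are not supported")
  }
  down_start <- ifelse(tt$strand == "+", tt$tes + 1L,
                       tt$tes - downstreamWindow)
  down <- GRanges(tt$chrom,
                  IRanges(pmax(1L, down_start),
                          width = downstreamWindow),
                  strand = tt$strand)

  one_strand <- function(st) {
    sel <- which(tt$strand == st)
    gr <- c(GenomicRanges::granges(body[sel], use.mcols = FALSE),
            GenomicRanges::granges(down[sel], use.mcols = FALSE))
    GenomicRanges::strand(gr) <- "*"
    w <- c(truth$lam[sel], truth$rho[sel] * truth$lam[sel])
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    gr <- GenomicRanges::trim(gr)
    cov <- GenomicRanges::coverage(gr, weight = w)
    if (decay == "exponential") {
      # halve the downstream signal every quarter window along
      # transcription direction
      for (i in sel) {
        dw <- down[i]
        if (width(dw) == 0) next
        pos_in <- seq_len(width(dw))
        if (st == "-") pos_in <- rev(pos_in)
        ch <- as.character(seqnames(dw))
        v <- cov[[ch]]
        v[start(dw):end(dw)] <- truth$rho[i] * truth$lam[i] *
          2^(-(pos_in - 1) / (downstreamWindow / 4))
        cov[[ch]] <- v
      }
    }
    cov
  }
  fwd <- one_strand("+")
  rev_ <- one_strand("-")
  if (noise) {
    set.seed(seed)
    noisify <- function(rl) {
      out <- lapply(rl, function(v) {
        if (!any(runValue(v) > 0)) return(v)
        dv <- as.numeric(v)
        pos <- which(dv > 0)
        dv[pos] <- rpois(length(pos), dv[pos])
        Rle(dv)
      })
      rl2 <- RleList(out)
      names(rl2) <- names(rl)
      rl2
    }
    fwd <- noisify(fwd)
    rev_ <- noisify(rev_)
  }
  new("SignalTrack", fwd = fwd, rev = rev_, binSize = 1L,
      normalization = "raw", stranded = TRUE)
}

#' Write a ground-truth or generic table as TSV
#' @param x A data.frame.
#' @param path Output path.
#' @param header Optional character vector of `# `-prefixed provenance
#'   lines written before the column header.
#' @return `path`, invisibly.
#' @export
writeTableTSV <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTableTSV()]
#' @param path Input path.
#' @return A data.frame (provenance comment lines skipped).
#' @export
readTableTSV <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
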