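# stable small hash for provenance headers (FNV-1a over the deparsed config)
.config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.provenance <- function(config) {
  config$outputDir <- NULL
  c(paste0("FractionSeq ", as.character(packageVersion("FractionSeq"))),
    paste0("seed=", config$seed),
    paste0("config=", .config_hash(config)))
}

#' Pipeline configuration
#'
#' Validates paths and parameters for [runFractionationAnalysis()]. All
#' referenced files must exist at validation time; the seed is mandatory.
#'
#' @param annotation GTF path.
#' @param alignments SAM/BAM path (splicing evidence).
#' @param trackFwd,trackRev Strand-specific bedGraph paths (nascent
#'   signal for RTI and metagene profiles).
#' @param counts TSV of the fraction count matrix (genes x samples,
#'   columns named `<fraction>_<replicate>`).
#' @param expression Optional TSV of per-transcript TPM for principal
#'   isoform selection; without it, single-isoform genes take their only
#'   transcript and multi-isoform genes the lexicographically first.
#' @param truth Optional ground-truth TSV (carried through for recovery
#'   reports).
#' @param outputDir Output directory (created if missing).
#' @param lfcThreshold,alpha Classification thresholds.
#' @param minReads Reliability floor for the splicing index.
#' @param tesWindow RTI downstream window (bases).
#' @param matchMode,matchN,matchFrac Matching mode and size.
#' @param seed Mandatory integer seed.
#' @return Validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(annotation, alignments, trackFwd, trackRev,
                           counts, expression = NULL, truth = NULL,
                           outputDir, lfcThreshold = 1, alpha = 0.05,
                           minReads = 10L, tesWindow = 2500L,
                           matchMode = "fraction", matchN = 500L,
                           matchFrac = 0.10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  paths <- c(annotation = annotation, alignments = alignments,
             trackFwd = trackFwd, trackRev = trackRev, counts = counts)
  if (!is.null(expression)) paths <- c(paths, expression = expression)
  if (!is.null(truth)) paths <- c(paths, truth = truth)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths)) {
    stop("missing input file(s): ",
         paste(names(missing_paths), missing_paths, sep = "=", collapse = ", "))
  }
  cfg <- list(annotation = annotation, alignments = alignments,
              trackFwd = trackFwd, trackRev = trackRev, counts = counts,
              expression = expression, truth = truth, outputDir = outputDir,
              lfcThreshold = lfcThreshold, alpha = alpha,
              minReads = as.integer(minReads),
              tesWindow = as.integer(tesWindow), matchMode = matchMode,
              matchN = as.integer(matchN), matchFrac = matchFrac,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Write a synthetic dataset to disk
#'
#' Thin wrapper over the simulators: generates a cohort and writes the GTF
#' annotation, the fraction count matrix, the paired-end SAM alignments,
#' the strand-specific bedGraph tracks and the ground-truth table into
#' `dir`, in the exact formats [runFractionationAnalysis()] consumes.
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if missing).
#' @return Named list of the file paths written.
#' @export
simulateDataset <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$nGenes < 1L) stop("nGenes must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(config)
  se <- simulateFractionCounts(cohort$truth, config)
  track <- simulateSignalTracks(cohort$truth, cohort$models,
                                noise = FALSE, seed = config$seed + 3L)
  paths <- list(
    annotation = file.path(dir, "genes.gtf"),
    counts = file.path(dir, "counts.tsv"),
    alignments = file.path(dir, "alignments.sam"),
    trackFwd = file.path(dir, "signal.fwd.bedGraph"),
    trackRev = file.path(dir, "signal.rev.bedGraph"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  writeGeneAnnotation(cohort$models, paths$annotation)
  cm <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
  cm <- cbind(gene_id = rownames(cm), cm)
  writeTableTSV(cm, paths$counts, header = .provenance(config))
  simulateAlignments(cohort$truth, cohort$models, config, paths$alignments)
  exportBedGraph(track, file.path(dir, "signal"))
  writeTableTSV(cohort$truth, paths$truth, header = .provenance(config))
  paths
}

# counts TSV (gene_id + <fraction>_<rep> columns) -> SummarizedExperiment
.read_counts_se <- function(path) {
  tab <- readTableTSV(path)
  genes <- tab$gene_id
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(m) <- genes
  fraction <- sub("_[0-9]+$", "", colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = DataFrame(fraction = fraction,
                        replicate = as.integer(sub("^.*_", "", colnames(m))),
                        row.names = colnames(m)))
}

#' Run the full fractionation analysis
#'
#' Executes the analysis end-to-end from a validated [pipelineConfig()]:
#' annotation and principal-isoform selection; nucleoplasm-vs-chromatin
#' differential enrichment and category classification; chromatin-
#' association index (chromatin vs nascent); expression-matched subsets;
#' per-transcript splicing indices; read-through indices; metagene mean
#' profiles per category; and per-category group statistics (medians plus
#' pairwise Wilcoxon rank-sum tests) for the splicing index and the RTI.
#' All result tables are written as TSV with a provenance header into
#' `outputDir`; re-running the same config reproduces them byte for byte.
#'
#' @param config A [pipelineConfig()].
#' @return Invisible list with elements `models`, `enrichment`,
#'   `association`, `matched`, `splicing`, `rti`, `profiles`, `summary`
#'   and `paths`.
#' @export
runFractionationAnalysis <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  prov <- .provenance(config)

  models <- stage("annotate", {
    gm <- readGeneAnnotation(config$annotation)
    if (!is.null(config$expression)) {
      gm <- selectPrincipalIsoforms(gm, readExpressionTable(config$expression))
    } else {
      by_gene <- split(gm@transcripts$transcript_id, gm@transcripts$gene_id)
      pr <- vapply(by_gene, function(ids) sort(ids)[1], character(1))
      gm@genes$principal <- unname(pr[gm@genes$gene_id])
    }
    gm
  })

  se <- stage("counts", .read_counts_se(config$counts))

  enrichment <- stage("differential_enrichment", {
    res <- differentialEnrichment(se, groupA = "chromatin",
                                  groupB = "nucleoplasm")
    classifyFractionEnrichment(res, config$lfcThreshold, config$alpha)
  })

  association <- stage("chromatin_association",
                       chromatinAssociationIndex(se))

  er <- enrichmentTable(enrichment)
  norm <- sweep(SummarizedExperiment::assay(se, "counts"), 2,
                sizeFactorsMedianRatio(SummarizedExperiment::assay(se, "counts")),
                "/")
  chrom_cols <- SummarizedExperiment::colData(se)$fraction == "chromatin"
  covariate <- rowMeans(norm[, chrom_cols, drop = FALSE])[er$gene_id]

  matched <- stage("matching", {
    iterativeSubsampleMatch(
      data.frame(gene_id = er$gene_id, category = er$category,
                 covariate = covariate, stringsAsFactors = FALSE),
      mode = config$matchMode, n = config$matchN, frac = config$matchFrac,
      alpha = config$alpha, seed = config$seed)
  })

  pairs <- stage("read_alignments", readAlignments(config$alignments))
  splicing <- stage("splicing_index",
                    transcriptSplicingIndex(pairs, models,
                                            minReads = config$minReads))

  track <- stage("signal_tracks",
                 importBedGraph(config$trackFwd, config$trackRev))
  rti <- stage("readthrough_index",
               readthroughIndex(track, models, tesWindow = config$tesWindow))

  profiles <- stage("metagene", {
    cats <- sort(unique(er$category))
    lapply(stats::setNames(cats, cats), function(cc) {
      ids <- er$gene_id[er$category == cc]
      if (!length(ids)) return(NULL)
      scaleRegionsMatrix(track, subsetGenes(models, ids))
    })
  })

  summary <- stage("group_statistics", {
    g2c <- stats::setNames(er$category, er$gene_id)
    se_by <- compareByCategory(splicing$se_norm, g2c[splicing$gene_id])
    rti_by <- compareByCategory(rti$rti, g2c[rti$gene_id])
    list(se_norm = se_by, rti = rti_by)
  })

  out <- function(name) file.path(config$outputDir, name)
  writeTableTSV(er, out("enrichment.tsv"), header = prov)
  writeTableTSV(enrichmentTable(association), out("association.tsv"),
                header = prov)
  writeTableTSV(splicing, out("splicing_index.tsv"), header = prov)
  writeTableTSV(rti, out("readthrough_index.tsv"), header = prov)
  match_df <- data.frame(
    gene_id = unlist(matchedSets(matched), use.names = FALSE),
    category = rep(names(matchedSets(matched)),
                   lengths(matchedSets(matched))))
  writeTableTSV(match_df, out("matched_subsets.tsv"), header = prov)
  prof_df <- do.call(rbind, lapply(names(profiles), function(cc) {
    if (is.null(profiles[[cc]])) return(NULL)
    mp <- meanProfile(profiles[[cc]])
    data.frame(category = cc, bin = seq_along(mp), mean_signal = mp)
  }))
  writeTableTSV(prof_df, out("metagene_profiles.tsv"), header = prov)
  summ_df <- do.call(rbind, lapply(names(summary), function(stat) {
    s <- summary[[stat]]
    data.frame(statistic = stat,
               category = names(s$medians),
               median = unname(s$medians))
  }))
  writeTableTSV(summ_df, out("summary.tsv"), header = prov)

  invisible(list(models = models, enrichment = enrichment,
                 association = association, matched = matched,
                 splicing = splicing, rti = rti, profiles = profiles,
                 summary = summary,
                 paths = vapply(c("enrichment.tsv", "association.tsv",
                                  "splicing_index.tsv", "readthrough_index.tsv",
                                  "matched_subsets.tsv",
                                  "metagene_profiles.tsv", "summary.tsv"),
                                out, character(1))))
}
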