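#' Read a GTF gene annotation into GeneModels
#'
#' Parses a Gencode-dialect GTF and builds strand-aware transcript models.
#' Only `exon` features are used; per transcript the exons are sorted by
#' genomic coordinate and ranked in transcription direction. TSS and
#' poly(A)-site (TES) anchors follow the transcription-direction convention:
#' on the `+` strand the TSS is the transcript's lowest coordinate, on the
#' `-` strand its highest, so `tss > tes` for minus-strand transcripts.
#'
#' @param path Path to a GTF file (9 tab-separated columns, attributes with
#'   `gene_id` and `transcript_id`).
#' @return A [GeneModels] object. Gene biotype is taken from the
#'   `gene_biotype`/`gene_type` attribute when present (otherwise
#'   `"unknown"`), gene names from `gene_name` (otherwise the gene id).
#'
#' @details Malformed lines (fewer than 9 columns) raise an error naming the
#'   line number. Transcripts without any exon feature are dropped with a
#'   warning.
#' @seealso [writeGeneAnnotation()] for the inverse operation.
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfields < 9L)) {
    bad <- which(body)[which(nfields < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated columns, got ",
         nfields[which(nfields < 9L)[1L]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- mcols(gr)
  if (is.null(md$type) || is.null(md$gene_id) || is.null(md$transcript_id)) {
    stop("GTF must carry type, gene_id and transcript_id attributes")
  }
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  exm <- mcols(ex)

  biotype_col <- if (!is.null(exm$gene_biotype)) "gene_biotype" else
    if (!is.null(exm$gene_type)) "gene_type" else NA_character_

  ord <- order(exm$transcript_id, start(ex))
  ex <- ex[ord]
  exm <- mcols(ex)
  tx_ids <- exm$transcript_id
  exl <- S4Vectors::split(ex, factor(tx_ids, levels = unique(tx_ids)))

  # transcripts mentioned on transcript/gene rows but carrying no exon
  declared <- unique(md$transcript_id[md$type %in% c("transcript", "mRNA")])
  declared <- declared[!is.na(declared)]
  no_exon <- setdiff(declared, names(exl))
  if (length(no_exon)) {
    warning("dropping ", length(no_exon),
            " transcript(s) without exons: ",
            paste(utils::head(no_exon, 5), collapse = ", "))
  }

  first_ex <- unlist(range(exl))  # one range per transcript
  str_chr <- as.character(strand(first_ex))
  if (any(str_chr == "*")) stop("transcripts must be stranded (+ or -)")
  tx_first <- !duplicated(tx_ids)
  tx <- data.frame(
    transcript_id = tx_ids[tx_first],
    gene_id = exm$gene_id[tx_first],
    chrom = as.character(seqnames(first_ex)),
    strand = str_chr,
    tss = ifelse(str_chr == "+", start(first_ex), end(first_ex)),
    tes = ifelse(str_chr == "+", end(first_ex), start(first_ex)),
    n_exons = as.integer(lengths(exl)),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- tx$transcript_id

  # exon_rank in transcription direction
  exl <- GRangesList(lapply(seq_along(exl), function(i) {
    e <- exl[[i]]
    mcols(e) <- NULL
    r <- seq_along(e)
    if (tx$strand[i] == "-") r <- rev(r)
    mcols(e)$exon_rank <- r
    e
  }))
  names(exl) <- tx$transcript_id

  g_first <- !duplicated(exm$gene_id)
  genes <- data.frame(
    gene_id = exm$gene_id[g_first],
    gene_name = if (!is.null(exm$gene_name)) {
      ifelse(is.na(exm$gene_name[g_first]), exm$gene_id[g_first],
             exm$gene_name[g_first])
    } else exm$gene_id[g_first],
    biotype = if (!is.na(biotype_col)) {
      bt <- exm[[biotype_col]][g_first]
      ifelse(is.na(bt), "unknown", bt)
    } else "unknown",
    principal = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(genes) <- genes$gene_id

  new("GeneModels", exons = exl, transcripts = tx, genes = genes)
}

#' Write GeneModels back to GTF
#'
#' Emits one `exon` feature per exon interval with `gene_id`,
#' `transcript_id`, `gene_name`, `gene_biotype` and `exon_number`
#' attributes, so that [readGeneAnnotation()] reconstructs an identical
#' object (round-trip property).
#'
#' @param x A [GeneModels].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(x, path) {
  ex <- unlist(x@exons, use.names = FALSE)
  tx_rep <- rep(x@transcripts$transcript_id, lengths(x@exons))
  gene_rep <- rep(x@transcripts$gene_id, lengths(x@exons))
  gmeta <- x@genes[gene_rep, ]
  mcols(ex) <- DataFrame(
    source = "FractionSeq",
    type = "exon",
    gene_id = gene_rep,
    transcript_id = tx_rep,
    gene_name = gmeta$gene_name,
    gene_biotype = gmeta$biotype,
    exon_number = as.character(mcols(ex)$exon_rank)
  )
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Read a per-transcript expression table
#'
#' @param path TSV with a `transcript_id` column followed by one TPM column
#'   per replicate.
#' @return `data.frame` with rownames = transcript ids, one numeric column
#'   per replicate (TPM, non-negative).
#' @export
readExpressionTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"transcript_id" %in% names(tab)) {
    stop("expression table needs a transcript_id column")
  }
  rownames(tab) <- tab$transcript_id
  tab$transcript_id <- NULL
  if (any(as.matrix(tab) < 0, na.rm = TRUE)) stop("TPM values must be >= 0")
  tab
}

# principal-isoform rule for one gene; expr is a numeric matrix of TPM,
# rows = this gene's transcripts
.principal_for_gene <- function(tx_ids, expr, minExpressedReps, totalReps) {
  expressed <- rowSums(expr > 0) >= minExpressedReps
  if (!any(expressed)) return(NA_character_)
  cand <- tx_ids[expressed]
  means <- rowMeans(expr[expressed, , drop = FALSE])
  # highest mean TPM; ties broken by lexicographic transcript id
  ord <- order(-means, cand)
  cand[ord[1L]]
}

#' Select the principal (highest-expressed) isoform per gene
#'
#' Among a gene's transcripts with TPM > 0 in at least `minExpressedReps`
#' of `totalReps` replicates, the one with the highest mean TPM becomes the
#' gene's principal isoform; its TSS and poly(A)-site anchors then drive all
#' downstream window quantification. Genes where no isoform passes the
#' expression filter keep `principal = NA`. Ties on mean TPM are broken by
#' lexicographic transcript id, making the selection deterministic and
#' invariant to transcript input order.
#'
#' @param x A [GeneModels].
#' @param expr Expression table as returned by [readExpressionTable()]:
#'   rows = transcripts, columns = replicates, values = TPM.
#' @param minExpressedReps Minimum number of replicates with TPM > 0
#'   (default 3, against 4 replicates in the original design).
#' @param totalReps Total replicates considered; defaults to `ncol(expr)`.
#' @return `x` with the `principal` column of [geneTable()] filled in.
#' @export
selectPrincipalIsoforms <- function(x, expr, minExpressedReps = 3L,
                                    totalReps = ncol(expr)) {
  stopifnot(is(x, "GeneModels"))
  tx <- x@transcripts
  missing_ids <- setdiff(tx$transcript_id, rownames(expr))
  if (length(missing_ids)) {
    stop("transcripts missing from expression table: ",
         paste(missing_ids, collapse = ", "))
  }
  em <- as.matrix(expr[, seq_len(totalReps), drop = FALSE])
  by_gene <- split(tx$transcript_id, tx$gene_id)
  principal <- vapply(by_gene, function(ids) {
    .principal_for_gene(ids, em[ids, , drop = FALSE],
                        minExpressedReps, totalReps)
  }, character(1))
  x@genes$principal <- unname(principal[x@genes$gene_id])
  validObject(x)
  x
}

#' Default histone gene-name prefixes
#'
#' Replication-dependent histone genes are conventionally recognisable by
#' name (HIST1/2/3/4 clusters in older nomenclature; H1-, H2A, H2B, H3, H4
#' cluster symbols in current HGNC nomenclature). The exact list is
#' configurable in [filterProteinCodingSet()].
#' @return Character vector of name prefixes.
#' @export
histonePrefixes <- function() {
  c("HIST1", "HIST2", "HIST3", "HIST4",
    "H1-", "H2AC", "H2AB", "H2BC", "H3C", "H3-", "H4C", "H4-")
}

#' Filter to the analysis gene set
#'
#' Applies the standard gene-set filters for the fractionation analysis:
#' keep protein-coding genes whose principal isoform has at least two exons
#' (intron-containing), drop histone genes (by gene-name prefix), and
#' optionally restrict to an explicit keep-list (e.g. genes with peptide
#' support). Genes without a selected principal isoform are always dropped.
#'
#' Applying the filter twice gives the same result as applying it once.
#'
#' @param x A [GeneModels] after [selectPrincipalIsoforms()].
#' @param dropIntronless Drop genes whose principal isoform is single-exon.
#' @param dropHistone Drop genes whose name starts with one of
#'   `histonePrefixes`.
#' @param histonePrefixes Character vector of name prefixes; see
#'   [histonePrefixes()].
#' @param keepIds Optional character vector of gene ids to retain
#'   (intersected with the other filters).
#' @return A [GeneModels] restricted to the retained genes (their
#'   transcripts and exons subset accordingly). An empty result is allowed
#'   and reported via `message()`.
#' @export
filterProteinCodingSet <- function(x, dropIntronless = TRUE,
                                   dropHistone = TRUE,
                                   histonePrefixes = FractionSeq::histonePrefixes(),
                                   keepIds = NULL) {
  stopifnot(is(x, "GeneModels"))
  gn <- x@genes
  tx <- x@transcripts
  keep <- !is.na(gn$principal) & gn$biotype == "protein_coding"
  if (dropIntronless) {
    n_ex <- tx[gn$principal, "n_exons"]
    keep <- keep & !is.na(n_ex) & n_ex >= 2L
  }
  if (dropHistone) {
    is_hist <- Reduce(`|`, lapply(histonePrefixes,
                                  function(p) startsWith(gn$gene_name, p)))
    keep <- keep & !is_hist
  }
  if (!is.null(keepIds)) keep <- keep & gn$gene_id %in% keepIds
  if (!any(keep)) message("filterProteinCodingSet: no genes retained")
  subsetGenes(x, gn$gene_id[keep])
}

#' Subset GeneModels to a set of genes
#'
#' @param x A [GeneModels].
#' @param geneIds Gene ids to retain (order preserved from `x`).
#' @return The subset [GeneModels].
#' @export
subsetGenes <- function(x, geneIds) {
  keep_g <- x@genes$gene_id %in% geneIds
  keep_t <- x@transcripts$gene_id %in% geneIds
  new("GeneModels",
      exons = x@exons[keep_t],
      transcripts = x@transcripts[keep_t, , drop = FALSE],
      genes = x@genes[keep_g, , drop = FALSE])
}

# transcript table restricted to principal isoforms, one row per gene;
# used by window-based quantification (RTI, metagene)
.principal_tx_table <- function(x) {
  gn <- x@genes
  pr <- gn$principal
  has <- !is.na(pr)
  tt <- x@transcripts[pr[has], , drop = FALSE]
  tt$gene_id <- gn$gene_id[has]
  rownames(tt) <- tt$gene_id
  tt
}
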