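toy_gtf <- function(path, lines) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, src, type, start, end, strand, attrs) {
  paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
}

attrs <- function(gid, tid, biotype = "protein_coding", name = NULL) {
  a <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
               gid, tid, biotype)
  if (!is.null(name)) a <- paste0(a, sprintf(' gene_name "%s";', name))
  a
}

test_that("GTF parsing applies transcription-direction TSS/TES conventions", {
  p <- toy_gtf(tempfile(fileext = ".gtf"), c(
    gtf_line("c1", "src", "exon", 101, 200, "+", attrs("g1", "t1")),
    gtf_line("c1", "src", "exon", 301, 400, "+", attrs("g1", "t1")),
    gtf_line("c1", "src", "exon", 1101, 1200, "-", attrs("g2", "t2")),
    gtf_line("c1", "src", "exon", 1301, 1400, "-", attrs("g2", "t2"))
  ))
  gm <- readGeneAnnotation(p)
  tx <- transcriptTable(gm)
  expect_equal(tx["t1", "tss"], 101)
  expect_equal(tx["t1", "tes"], 400)
  expect_equal(tx["t1", "n_exons"], 2L)
  # minus strand: TSS is the highest coordinate
  expect_equal(tx["t2", "tss"], 1400)
  expect_equal(tx["t2", "tes"], 1101)
  # exon ranks run in transcription direction
  expect_equal(S4Vectors::mcols(exonsByTranscript(gm)[["t2"]])$exon_rank,
               c(2L, 1L))
  expect_equal(geneTable(gm)$biotype, c("protein_coding", "protein_coding"))
})

test_that("malformed GTF lines raise an error naming the line number", {
  p <- toy_gtf(tempfile(fileext = ".gtf"), c(
    gtf_line("c1", "src", "exon", 101, 200, "+", attrs("g1", "t1")),
    "c1\tsrc\texon\t301\t400\t.\t+"  # 8 columns only
  ))
  expect_error(readGeneAnnotation(p), "line 2")
})

test_that("transcripts without exons are dropped with a warning", {
  p <- toy_gtf(tempfile(fileext = ".gtf"), c(
    gtf_line("c1", "src", "transcript", 101, 400, "+", attrs("g1", "t1")),
    gtf_line("c1", "src", "exon", 101, 200, "+", attrs("g1", "t1")),
    gtf_line("c1", "src", "transcript", 501, 700, "+", attrs("g2", "t9"))
  ))
  expect_warning(gm <- readGeneAnnotation(p), "t9")
  expect_false("t9" %in% transcriptTable(gm)$transcript_id)
})

test_that("GTF round-trip reproduces the gene models", {
  cfg <- simulationConfig(nGenes = 15L, seed = 8L)
  co <- simulateCohort(cfg)
  p <- tempfile(fileext = ".gtf")
  writeGeneAnnotation(co$models, p)
  gm2 <- readGeneAnnotation(p)
  expect_identical(transcriptTable(gm2), transcriptTable(co$models))
  expect_identical(geneTable(gm2)[, c("gene_id", "gene_name", "biotype")],
                   geneTable(co$models)[, c("gene_id", "gene_name", "biotype")])
  e1 <- exonsByTranscript(co$models)
  e2 <- exonsByTranscript(gm2)
  for (i in seq_along(e1)) {
    expect_equal(IRanges::start(e1[[i]]), IRanges::start(e2[[i]]))
    expect_equal(IRanges::end(e1[[i]]), IRanges::end(e2[[i]]))
    expect_equal(S4Vectors::mcols(e1[[i]])$exon_rank,
                 S4Vectors::mcols(e2[[i]])$exon_rank)
  }
})

two_tx_models <- function() {
  e1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 301), c(200, 400)),
                               strand = "+", exon_rank = 1:2)
  e2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 351), c(200, 400)),
                               strand = "+", exon_rank = 1:2)
  exl <- GenomicRanges::GRangesList(t1 = e1, t2 = e2)
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   chrom = "c1", strand = "+", tss = 101, tes = 400,
                   n_exons = 2L, row.names = c("t1", "t2"),
                   stringsAsFactors = FALSE)
  gn <- data.frame(gene_id = "g1", gene_name = "g1",
                   biotype = "protein_coding", principal = NA_character_,
                   row.names = "g1", stringsAsFactors = FALSE)
  new("GeneModels", exons = exl, transcripts = tx, genes = gn)
}

test_that("principal isoform is the highest-mean TPM among sufficiently expressed", {
  gm <- two_tx_models()
  # t1 expressed 4/4 at mean 5; t2 higher mean but only 2/4 replicates
  expr <- data.frame(r1 = c(5, 18), r2 = c(5, 18), r3 = c(5, 0), r4 = c(5, 0),
                     row.names = c("t1", "t2"))
  out <- selectPrincipalIsoforms(gm, expr, minExpressedReps = 3L)
  expect_equal(geneTable(out)$principal, "t1")

  # nothing expressed -> principal absent
  expr0 <- expr; expr0[] <- 0
  out0 <- selectPrincipalIsoforms(gm, expr0, minExpressedReps = 3L)
  expect_true(is.na(geneTable(out0)$principal))

  # exact tie -> lexicographically first transcript
  exprT <- data.frame(r1 = c(5, 5), r2 = c(5, 5), r3 = c(5, 5), r4 = c(5, 5),
                      row.names = c("t2", "t1"))
  outT <- selectPrincipalIsoforms(gm, exprT, minExpressedReps = 3L)
  expect_equal(geneTable(outT)$principal, "t1")

  # missing transcript -> error listing the id
  expect_error(selectPrincipalIsoforms(gm, expr["t1", , drop = FALSE]), "t2")
})

test_that("principal isoform selection is invariant to transcript order", {
  gm <- two_tx_models()
  expr <- data.frame(r1 = c(5, 9), r2 = c(6, 9), r3 = c(5, 9), r4 = c(6, 9),
                     row.names = c("t1", "t2"))
  a <- geneTable(selectPrincipalIsoforms(gm, expr))$principal
  b <- geneTable(selectPrincipalIsoforms(gm, expr[c("t2", "t1"), ]))$principal
  expect_identical(a, b)
  expect_equal(a, "t2")
})

test_that("gene-set filter removes intronless and histone genes, idempotently", {
  mk <- function(id, n_ex, biotype, name) {
    starts <- 101 + (seq_len(n_ex) - 1) * 300
    m <- toy_gene_models(starts, starts + 99, gene_id = id,
                         transcript_id = paste0(id, "_t"), biotype = biotype)
    m@genes$gene_name <- name
    m
  }
  combine <- function(a, b) {
    new("GeneModels",
        exons = c(a@exons, b@exons),
        transcripts = rbind(a@transcripts, b@transcripts),
        genes = rbind(a@genes, b@genes))
  }
  gm <- Reduce(combine, list(
    mk("g_multi", 3, "protein_coding", "GENE1"),
    mk("g_single", 1, "protein_coding", "GENE2"),
    mk("g_hist", 3, "protein_coding", "H2AC4"),
    mk("g_linc", 3, "lncRNA", "LINC9")
  ))
  out <- filterProteinCodingSet(gm)
  expect_equal(geneTable(out)$gene_id, "g_multi")
  # subset of input and idempotent
  expect_true(all(geneTable(out)$gene_id %in% geneTable(gm)$gene_id))
  out2 <- filterProteinCodingSet(out)
  expect_identical(geneTable(out2), geneTable(out))
  # keep-list intersects
  none <- suppressMessages(filterProteinCodingSet(gm, keepIds = "g_hist"))
  expect_equal(nrow(geneTable(none)), 0L)
})
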