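test_that("exonic counting respects split, strand and once-per-gene rules", {
  gm <- toy_gene_models(c(1001, 2201), c(1200, 2400))  # + strand, 2 exons
  recs <- rbind(
    # block fully inside exon 1 -> counted
    sam_pair("a", "c1", 1051, 1001, ts = "+"),
    # both blocks intronic, the N gap spans exon 2 entirely -> counted only
    # without split-awareness (span overlaps the exon)
    sam_pair("b", "c1", 1301, 1301, cigar2 = "50M1100N50M", ts = "+"),
    # intron-only contiguous pair -> never counted
    sam_pair("d", "c1", 1301, 1351, ts = "+"),
    # antisense pair over exon 1 -> only counted without strand matching
    sam_pair("e", "c1", 1001, 1101, ts = "-"),
    # spliced pair across the junction, both blocks exonic -> counted once
    sam_pair("f", "c1", 1051, 1181, cigar2 = "20M1000N30M", ts = "+"))
  p <- write_sam(recs, tempfile(fileext = ".sam"))
  pairs <- readAlignments(p)
  expect_equal(unname(countExonic(pairs, gm)), 2L)                    # a, f
  expect_equal(unname(countExonic(pairs, gm, splitAware = FALSE)), 3L)  # + b
  expect_equal(unname(countExonic(pairs, gm, strandSpecific = FALSE)), 3L) # + e
})

test_that("median-of-ratios size factors behave on reference cases", {
  m <- cbind(s1 = c(10, 100, 50, 0), s2 = c(10, 100, 50, 80))
  sf <- sizeFactorsMedianRatio(m)
  expect_equal(unname(sf), c(1, 1))  # zero row excluded, identical otherwise
  m2 <- cbind(s1 = c(10, 100, 50), s2 = 2 * c(10, 100, 50))
  sf2 <- sizeFactorsMedianRatio(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  expect_error(sizeFactorsMedianRatio(cbind(c(1, 0), c(0, 1))),
               "pseudo-reference")
})

test_that("the NB Wald test is antisymmetric and excludes all-zero genes", {
  set.seed(14)
  n <- 300
  mu <- rlnorm(n, log(150), 0.4)
  counts <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 20))
  rownames(counts) <- paste0("g", seq_len(n))
  counts["g7", ] <- 0L
  expect_message(resAB <- differentialEnrichment(counts, 1:3, 4:6),
                 "excluded")
  expect_equal(excludedGenes(resAB), "g7")
  resBA <- suppressMessages(differentialEnrichment(counts, 4:6, 1:3))
  tAB <- enrichmentTable(resAB)
  tBA <- enrichmentTable(resBA)
  expect_equal(tAB$log2FC, -tBA$log2FC)
  expect_equal(tAB$p, tBA$p)
  expect_true(all(tAB$padj >= 0 & tAB$padj <= 1))
  # BH: padj monotone non-decreasing in p-rank
  o <- order(tAB$p)
  expect_true(all(diff(cummax(tAB$padj[o])) >= 0))
  expect_error(differentialEnrichment(counts, 1, 2:6), "2 replicates")
})

test_that("enrichment classification applies thresholds and partitions genes", {
  r <- data.frame(gene_id = c("a", "b", "c", "d"),
                  baseMean = 100, log2FC = c(1.5, -1.2, 1.5, 0.2),
                  p = c(0.001, 0.01, 0.15, 0.9),
                  padj = c(0.01, 0.04, 0.2, 0.95),
                  category = NA_character_, lowConfidence = FALSE,
                  stringsAsFactors = FALSE)
  x <- new("EnrichmentResult", results = r, excluded = character(),
           groupA = "chromatin", groupB = "nucleoplasm",
           lfcThreshold = NA_real_, alpha = NA_real_)
  out <- enrichmentTable(classifyFractionEnrichment(x))
  expect_equal(out$category,
               c("nucleoplasm-enriched", "chromatin-enriched",
                 "non-enriched", "non-enriched"))
  expect_true(all(out$category %in% c("nucleoplasm-enriched",
                                      "chromatin-enriched", "non-enriched")))
})

test_that("chromatin-association index recovers the generative retention", {
  # identical distributions -> index ~ 0; doubled chromatin -> ~ 1
  set.seed(15)
  nas <- sapply(1:3, function(j) rpois(400, 300))
  rownames(nas) <- paste0("g", 1:400)
  ident <- cbind(sapply(1:3, function(j) rpois(400, 300)), nas)
  colnames(ident) <- c(paste0("chr_", 1:3), paste0("nas_", 1:3))
  ai0 <- enrichmentTable(differentialEnrichment(ident, 4:6, 1:3))
  expect_lt(abs(median(ai0$log2FC)), 0.1)

  # cohort with retention 4 on chromatin-enriched genes: the generative
  # chromatin/nascent ratio for that category is 2^(delta/2 * -1) * 4 = 8,
  # so the median association index recovers log2(8) = 3
  cfg <- simulationConfig(nGenes = 300L, seed = 16L,
    retention = c("chromatin-enriched" = 4, "nucleoplasm-enriched" = 1,
                  "non-enriched" = 1))
  co <- simulateCohort(cfg)
  se <- simulateFractionCounts(co$truth, cfg)
  ai <- enrichmentTable(chromatinAssociationIndex(se))
  idx <- ai$log2FC[match(co$truth$gene_id, ai$gene_id)]
  med <- tapply(idx, co$truth$category, median, na.rm = TRUE)
  expect_lt(abs(med[["chromatin-enriched"]] - 3), 0.3)
  expect_lt(abs(med[["non-enriched"]] - 0), 0.3)
})

test_that("the engine tracks an established NB test on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  n <- 600
  mu <- rlnorm(n, log(200), 0.5)
  fc <- rep(1, n); fc[1:60] <- 4
  counts <- cbind(sapply(1:3, function(j) rnbinom(n, mu = mu, size = 20)),
                  sapply(1:3, function(j) rnbinom(n, mu = mu * fc, size = 20)))
  rownames(counts) <- paste0("g", 1:n)
  colnames(counts) <- paste0("s", 1:6)
  mine <- enrichmentTable(differentialEnrichment(counts, 1:3, 4:6))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts,
           S4Vectors::DataFrame(cond = factor(rep(c("A", "B"), each = 3))),
           ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))
  # independent engines agree on the effect estimates and calls
  expect_gt(cor(mine$log2FC, ref$log2FoldChange), 0.95)
  both_sig <- (mine$padj < 0.05 & abs(mine$log2FC) > 1)
  ref_sig <- (!is.na(ref$padj) & ref$padj < 0.05 & abs(ref$log2FoldChange) > 1)
  expect_gt(mean(both_sig == ref_sig), 0.95)
})
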