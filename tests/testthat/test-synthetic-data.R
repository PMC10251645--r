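test_that("category allocation is exact and seeding is reproducible", {
  cfg <- simulationConfig(nGenes = 300L, seed = 1L)
  co <- simulateCohort(cfg)
  expect_equal(unname(table(co$truth$category)["chromatin-enriched"]), 100L,
               ignore_attr = TRUE)
  expect_equal(as.vector(table(co$truth$category)), c(100L, 100L, 100L))
  co2 <- simulateCohort(cfg)
  expect_identical(co$truth, co2$truth)
  # delta wiring: sign follows category, magnitude d
  expect_true(all(co$truth$delta[co$truth$category == "nucleoplasm-enriched"] == 2))
  expect_true(all(co$truth$delta[co$truth$category == "chromatin-enriched"] == -2))
  expect_true(all(co$truth$delta[co$truth$category == "non-enriched"] == 0))
  cfg0 <- simulationConfig(nGenes = 30L, delta = 0, seed = 1L)
  expect_true(all(simulateCohort(cfg0)$truth$delta == 0))
})

test_that("config validation rejects bad proportions and missing seed", {
  expect_error(simulationConfig(seed = 1, proportions =
    c("chromatin-enriched" = 0.5, "nucleoplasm-enriched" = 0.4,
      "non-enriched" = 0.4)), "sum to 1")
  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, dispersion = -1), "dispersion")
})

test_that("fraction counts follow the generative means", {
  # closed form of the unscaled means
  truth <- data.frame(gene_id = c("a", "b", "c"),
                      category = c("nucleoplasm-enriched", "chromatin-enriched",
                                   "non-enriched"),
                      lam = c(100, 100, 100), delta = c(2, -2, 0),
                      s = 0.5, rho = 0.1, retention = c(1, 1, 1))
  mu <- FractionSeq:::.fraction_means(truth)
  expect_equal(unname(mu[1, "nucleoplasm"] / mu[1, "chromatin"]), 4)
  expect_equal(unname(mu[2, "nucleoplasm"] / mu[2, "chromatin"]), 1 / 4)
  expect_equal(unname(mu[, "nascent"]), truth$lam)

  # Monte-Carlo recovery of the scaled ratio over 200 draws: with a
  # category-balanced cohort the per-fraction depth scaling is the ratio of
  # unscaled column sums, which the oracle computes exactly
  cfg <- simulationConfig(nGenes = 60L, seed = 3L, libSize = 2e5)
  co <- simulateCohort(cfg)
  mu <- FractionSeq:::.fraction_means(co$truth)
  scaleC <- cfg$libSize / sum(mu[, "chromatin"])
  scaleN <- cfg$libSize / sum(mu[, "nucleoplasm"])
  d2 <- co$truth$delta == 2
  expected_ratio <- 4 * scaleN / scaleC
  sims <- vapply(1:200, function(s) {
    cfg_s <- cfg; cfg_s$seed <- 1000L + s
    se <- simulateFractionCounts(co$truth, cfg_s)
    m <- SummarizedExperiment::assay(se, "counts")
    fr <- SummarizedExperiment::colData(se)$fraction
    sum(m[d2, fr == "nucleoplasm"]) / sum(m[d2, fr == "chromatin"])
  }, numeric(1))
  expect_lt(abs(mean(sims) / expected_ratio - 1), 0.10)
})

test_that("doubling library depth doubles expected counts", {
  cfg1 <- simulationConfig(nGenes = 100L, seed = 4L, libSize = 1e5,
                           dispersion = 0)
  cfg2 <- simulationConfig(nGenes = 100L, seed = 4L, libSize = 2e5,
                           dispersion = 0)
  co <- simulateCohort(cfg1)
  s1 <- sum(SummarizedExperiment::assay(simulateFractionCounts(co$truth, cfg1)))
  s2 <- sum(SummarizedExperiment::assay(simulateFractionCounts(co$truth, cfg2)))
  expect_lt(abs(s2 / s1 - 2), 0.05)
})

test_that("zero dispersion and zero delta give symmetric fractions", {
  cfg <- simulationConfig(nGenes = 200L, seed = 5L, delta = 0, dispersion = 0)
  co <- simulateCohort(cfg)
  se <- simulateFractionCounts(co$truth, cfg)
  m <- SummarizedExperiment::assay(se, "counts")
  fr <- SummarizedExperiment::colData(se)$fraction
  mc <- rowMeans(m[, fr == "chromatin"])
  mn <- rowMeans(m[, fr == "nucleoplasm"])
  # equal generative means: per-gene Poisson means match within MC error
  expect_lt(median(abs(mc - mn) / (mc + mn)), 0.1)
})

test_that("simulated alignments encode splicing probability and are reproducible", {
  cfg <- simulationConfig(nGenes = 6L, seed = 6L, readsPerGene = 400L,
    splicingProb = c("chromatin-enriched" = 1, "nucleoplasm-enriched" = 1,
                     "non-enriched" = 1))
  co <- simulateCohort(cfg)
  p1 <- tempfile(fileext = ".sam")
  simulateAlignments(co$truth, co$models, cfg, p1)
  # s = 1, q = 1: every pair carries an N gap
  cig <- vapply(strsplit(grep("^@", readLines(p1), value = TRUE,
                              invert = TRUE), "\t"), `[[`, "", 6L)
  by_pair <- split(grepl("N", cig), rep(seq_len(length(cig) / 2), each = 2))
  expect_true(all(vapply(by_pair, any, logical(1))))
  # byte-identical under the same seed
  p2 <- tempfile(fileext = ".sam")
  simulateAlignments(co$truth, co$models, cfg, p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seed: different data, same schema
  cfg2 <- cfg; cfg2$seed <- 7L
  p3 <- tempfile(fileext = ".sam")
  co3 <- simulateCohort(cfg2)
  simulateAlignments(co3$truth, co3$models, cfg2, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
  expect_silent(pr <- readAlignments(p3))
})

test_that("signal tracks realize the read-through geometry", {
  base <- function(rho) {
    simulationConfig(nGenes = 4L, seed = 9L, exonCountRange = c(4L, 4L),
      exonLength = 400L, intronLength = 800L,   # gene length 4000
      readthroughFraction = c("chromatin-enriched" = rho,
                              "nucleoplasm-enriched" = rho,
                              "non-enriched" = rho))
  }
  co <- simulateCohort(base(0))
  tr0 <- simulateSignalTracks(co$truth, co$models, downstreamWindow = 2000L)
  rt0 <- readthroughIndex(tr0, co$models, tesWindow = 2000L)
  expect_true(all(rt0$tes_signal == 0))
  expect_true(all(is.na(rt0$rti)))   # no finite ratio, pseudocount undefined

  co5 <- simulateCohort(base(0.5))
  tr5 <- simulateSignalTracks(co5$truth, co5$models, downstreamWindow = 2000L)
  rt5 <- readthroughIndex(tr5, co5$models, tesWindow = 2000L)
  expect_equal(rt5$ratio, rep(4, 4))

  # doubling rho doubles the downstream sum
  co25 <- simulateCohort(base(0.25))
  tr25 <- simulateSignalTracks(co25$truth, co25$models, downstreamWindow = 2000L)
  rt25 <- readthroughIndex(tr25, co25$models, tesWindow = 2000L)
  expect_equal(rt5$tes_signal, 2 * rt25$tes_signal)
})

test_that("bedGraph export/import round-trips track values", {
  cfg <- simulationConfig(nGenes = 10L, seed = 10L)
  co <- simulateCohort(cfg)
  tr <- simulateSignalTracks(co$truth, co$models)
  prefix <- tempfile()
  exportBedGraph(tr, prefix)
  tr2 <- importBedGraph(paste0(prefix, ".fwd.bedGraph"),
                        paste0(prefix, ".rev.bedGraph"),
                        seqlengths = vapply(tr@fwd, length, numeric(1)))
  tt <- transcriptTable(co$models)
  for (i in seq_len(nrow(tt))) {
    lo <- min(tt$tss[i], tt$tes[i])
    hi <- max(tt$tss[i], tt$tes[i])
    expect_equal(quantifyInterval(tr2, tt$chrom[i], lo, hi, tt$strand[i]),
                 quantifyInterval(tr, tt$chrom[i], lo, hi, tt$strand[i]))
  }
})
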