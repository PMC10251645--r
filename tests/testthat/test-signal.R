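test_that("proper-pair filtering keeps flagged records and drops unmapped", {
  # 10 records: 3 proper pairs (6 records), 1 non-proper pair, 2 unmapped
  recs <- rbind(
    sam_pair("p1", "c1", 1001, 1101, ts = "+"),
    sam_pair("p2", "c1", 2001, 2101, ts = "-"),
    sam_pair("p3", "c1", 3001, 3101, ts = "+"),
    c("q1", 65L, "c1", 4001, 255, "50M", "=", 4101, 0, strrep("A", 50), "*"),
    c("q1", 129L, "c1", 4101, 255, "50M", "=", 4001, 0, strrep("A", 50), "*"),
    c("u1", 77L, "*", 0, 0, "*", "*", 0, 0, strrep("A", 50), "*"),
    c("u1", 141L, "*", 0, 0, "*", "*", 0, 0, strrep("A", 50), "*"))
  p <- write_sam(recs, tempfile(fileext = ".sam"))
  pairs <- readAlignments(p, requireProperPairs = TRUE)
  expect_equal(length(pairs), 3L)           # 6 records retained
  all_pairs <- readAlignments(p, requireProperPairs = FALSE)
  expect_equal(length(all_pairs), 4L)
})

test_that("3' reduction takes mate-2 last aligned base and mate-1 strand", {
  recs <- rbind(
    # transcription +: mate2 forward at [1001,1050] -> position 1050
    sam_pair("a", "c1", 5001, 1001, ts = "+"),
    # transcription -: mate2 reverse at [2001,2050] -> position 2001
    sam_pair("b", "c1", 7001, 2001, ts = "-"),
    # gapped mate2 forward [3001..3020]M[100N][3121..3150] -> 3150
    sam_pair("c", "c1", 9001, 3001, cigar2 = "20M100N30M", ts = "+"))
  p <- write_sam(recs, tempfile(fileext = ".sam"))
  pos <- threePrimeReduce(readAlignments(p))
  df <- data.frame(pos = IRanges::start(GenomicRanges::ranges(pos)),
                   strand = as.character(GenomicRanges::strand(pos)))
  df <- df[order(df$pos), ]
  expect_equal(df$pos, c(1050L, 2001L, 3150L))
  expect_equal(df$strand, c("+", "-", "+"))
  expect_equal(length(pos), 3L)  # output count == valid pair count
})

test_that("coverage bins apply the RPKM formula and conserve raw mass", {
  set.seed(11)
  n <- 400L
  g <- GenomicRanges::GRanges("c1",
         IRanges::IRanges(sample.int(9999L, n, replace = TRUE), width = 1L),
         strand = sample(c("+", "-"), n, TRUE),
         seqinfo = GenomeInfoDb::Seqinfo("c1", 10000L))
  raw <- coverageTrack(g, binSize = 10L, normalization = "raw")
  total_mass <- sum(as.numeric(raw@fwd[["c1"]])) / 10 +
    sum(as.numeric(raw@rev[["c1"]])) / 10
  expect_equal(total_mass, n)

  # RPKM = count / ((bs/1000) * (total/1e6)); with bin value spread per
  # base, an interval covering one full bin sums to value * 10
  ten <- GenomicRanges::GRanges("c1", IRanges::IRanges(rep(15L, 10), width = 1L),
                                strand = "+",
                                seqinfo = GenomeInfoDb::Seqinfo("c1", 10000L))
  rp <- coverageTrack(ten, binSize = 10L, normalization = "RPKM")
  expect_equal(quantifyInterval(rp, "c1", 11, 20) / 10,
               10 / ((10 / 1000) * (10 / 1e6)))
  # doubling the total record count halves the per-bin RPKM
  twenty <- c(ten, GenomicRanges::GRanges("c1",
    IRanges::IRanges(rep(995L, 10), width = 1L), strand = "+",
    seqinfo = GenomeInfoDb::Seqinfo("c1", 10000L)))
  rp2 <- coverageTrack(twenty, binSize = 10L, normalization = "RPKM")
  expect_equal(quantifyInterval(rp2, "c1", 11, 20),
               quantifyInterval(rp, "c1", 11, 20) / 2)
  expect_error(coverageTrack(ten, binSize = 0L), "binSize")
})

test_that("interval quantification matches a per-base oracle and is additive", {
  set.seed(12)
  v <- rpois(5000, 3) * runif(5000)
  trk <- make_track(list(c1 = v))
  for (k in 1:50) {
    s <- sample.int(4900L, 1L)
    e <- s + sample.int(100L, 1L) - 1L
    expect_equal(quantifyInterval(trk, "c1", s, e), sum(v[s:e]))
  }
  # additivity over a partition
  expect_equal(quantifyInterval(trk, "c1", 101, 300),
               quantifyInterval(trk, "c1", 101, 200) +
                 quantifyInterval(trk, "c1", 201, 300))
  # constant track: v * L
  cons <- make_track(list(c1 = rep(2.5, 1000)))
  expect_equal(quantifyInterval(cons, "c1", 11, 110), 2.5 * 100)
  expect_equal(quantifyInterval(cons, "c1", 5, 4), 0)
  expect_error(quantifyInterval(trk, "c2", 1, 10), "chromosome")
  expect_warning(out <- quantifyInterval(trk, "c1", 4990, 5050), "clipped")
  expect_equal(out, sum(v[4990:5000]))
})

test_that("binned correlation is scale-invariant and near zero for noise", {
  set.seed(13)
  len <- 100000L
  a <- rpois(len, 0.2)
  t1 <- make_track(list(c1 = a))
  t2 <- make_track(list(c1 = 2 * a))
  m <- binnedGenomeCorrelation(list(x = t1, y = t2), binSize = 1000L)
  expect_equal(diag(m), c(x = 1, y = 1))
  expect_equal(m["x", "y"], 1)
  # two independent noise tracks over 1e4 bins
  b1 <- make_track(list(c1 = rpois(len, 1)))
  b2 <- make_track(list(c1 = rpois(len, 1)))
  m2 <- binnedGenomeCorrelation(list(u = b1, w = b2), binSize = 10L)
  expect_lt(abs(m2["u", "w"]), 0.05)
  expect_error(binnedGenomeCorrelation(list(t1)), "two tracks")
})
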