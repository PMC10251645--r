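# fixture builders shared across the suite; everything is generated in code

write_sam <- function(recs, path, sq = c(c1 = 100000L)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ch in names(sq)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, sq[[ch]]), con)
  }
  if (nrow(recs)) {
    writeLines(apply(recs, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

# one properly-paired fragment; transcription strand `ts` under the dUTP
# convention (mate 1 opposite, mate 2 on `ts`); cigar2 may contain N
sam_pair <- function(qname, chrom, pos1, pos2, cigar2 = "50M",
                     ts = "+", readLen = 50L) {
  n_m <- sum(as.integer(regmatches(cigar2,
    gregexpr("[0-9]+(?=M)", cigar2, perl = TRUE))[[1]]))
  if (ts == "+") { f1 <- 83L; f2 <- 163L } else { f1 <- 99L; f2 <- 147L }
  rbind(
    c(qname, f1, chrom, pos1, 255L, paste0(readLen, "M"), "=", pos2, 0L,
      strrep("A", readLen), "*"),
    c(qname, f2, chrom, pos2, 255L, cigar2, "=", pos1, 0L,
      strrep("A", n_m), "*"))
}

# minimal single-transcript gene models
toy_gene_models <- function(exon_starts, exon_ends, strand = "+",
                            chrom = "c1", gene_id = "G1",
                            transcript_id = "T1",
                            biotype = "protein_coding") {
  e <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(exon_starts, exon_ends),
                              strand = strand)
  r <- seq_along(e)
  if (strand == "-") r <- rev(r)
  S4Vectors::mcols(e)$exon_rank <- r
  exl <- GenomicRanges::GRangesList(e)
  names(exl) <- transcript_id
  tss <- if (strand == "+") min(exon_starts) else max(exon_ends)
  tes <- if (strand == "+") max(exon_ends) else min(exon_starts)
  tx <- data.frame(transcript_id = transcript_id, gene_id = gene_id,
                   chrom = chrom, strand = strand, tss = tss, tes = tes,
                   n_exons = length(e), row.names = transcript_id,
                   stringsAsFactors = FALSE)
  gn <- data.frame(gene_id = gene_id, gene_name = gene_id, biotype = biotype,
                   principal = transcript_id, row.names = gene_id,
                   stringsAsFactors = FALSE)
  new("GeneModels", exons = exl, transcripts = tx, genes = gn)
}

# strand-specific per-base track from plain numeric vectors
make_track <- function(fwd, rev = NULL) {
  to_rll <- function(x) {
    rl <- IRanges::RleList(lapply(x, S4Vectors::Rle))
    names(rl) <- names(x)
    rl
  }
  if (is.null(rev)) rev <- lapply(fwd, function(v) numeric(length(v)))
  new("SignalTrack", fwd = to_rll(fwd), rev = to_rll(rev), binSize = 1L,
      normalization = "raw", stranded = TRUE)
}

# independent splicing-index oracle: parses SAM text directly (no
# GenomicAlignments) and recounts spliced/total pairs per transcript span
brute_force_splicing <- function(samPath, tx_table) {
  lines <- readLines(samPath)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  chrom <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  blocks_of <- function(pos, cig) {
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    cur <- pos
    bs <- ce <- integer(0)
    bstart <- pos
    open <- FALSE
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "D", "=", "X")) {
        if (!open) { bstart <- cur; open <- TRUE }
        cur <- cur + len[i]
      } else if (op[i] == "N") {
        if (open) { bs <- c(bs, bstart); ce <- c(ce, cur - 1L); open <- FALSE }
        cur <- cur + len[i]
      }
    }
    if (open) { bs <- c(bs, bstart); ce <- c(ce, cur - 1L) }
    cbind(bs, ce)
  }
  n_tx <- nrow(tx_table)
  n_total <- n_spliced <- integer(n_tx)
  for (qn in unique(qname)) {
    idx <- which(qname == qn)
    is1 <- bitwAnd(flag[idx], 64L) > 0L
    m1 <- idx[is1][1L]
    ts <- if (bitwAnd(flag[m1], 16L) > 0L) "+" else "-"  # dUTP: flip mate 1
    blocks <- do.call(rbind, lapply(idx, function(i) blocks_of(pos[i], cigar[i])))
    spl <- any(grepl("N", cigar[idx], fixed = TRUE))
    for (t in seq_len(n_tx)) {
      if (tx_table$chrom[t] != chrom[idx[1]] || tx_table$strand[t] != ts) next
      lo <- min(tx_table$tss[t], tx_table$tes[t])
      hi <- max(tx_table$tss[t], tx_table$tes[t])
      if (any(blocks[, 1] <= hi & blocks[, 2] >= lo)) {
        n_total[t] <- n_total[t] + 1L
        if (spl) n_spliced[t] <- n_spliced[t] + 1L
      }
    }
  }
  data.frame(transcript_id = tx_table$transcript_id,
             n_spliced = n_spliced, n_total = n_total,
             stringsAsFactors = FALSE)
}
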