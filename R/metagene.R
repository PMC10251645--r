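# area-weighted resampling of a per-base vector to nout bins: each output
# bin averages the source bases it covers, with fractional bases weighted
# by overlap, so a constant input stays constant and mass is conserved
.resample_area <- function(x, nout) {
  L <- length(x)
  cs <- c(0, cumsum(x))
  # cumulative signal at fractional position t in [0, L]
  cum_at <- function(t) {
    k <- pmin(floor(t), L - 1)
    cs[k + 1] + (t - k) * x[k + 1]
  }
  edges <- seq(0, L, length.out = nout + 1)
  vals <- cum_at(edges)
  diff(vals) / diff(edges)
}

# mean of consecutive n-base chunks; chunks with no defined base are NA
.bin_means <- function(x, n) {
  nb <- length(x) / n
  m <- matrix(x, nrow = n)
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Scale-regions metagene matrix
#'
#' Builds a regions-by-bins matrix in which each gene contributes a fixed
#' upstream flank (`b` bases before the TSS in transcription direction,
#' binned at `bs`), its gene body linearly rescaled to `m/bs` bins by
#' area-weighted resampling, and a fixed downstream flank (`a` bases past
#' the TES). Minus-strand genes are reversed so every row reads TSS to TES
#' left to right. Flank bins falling outside the chromosome are missing
#' values. When `maxThreshold` is set, any region containing a bin value
#' above it is excluded entirely (and counted), mirroring excluded-region
#' semantics rather than per-bin clipping.
#'
#' With the defaults (`b = a = 2500`, `m = 4000`, `bs = 10`) each region
#' yields 250 + 400 + 250 = 900 bins.
#'
#' @param track A [SignalTrack].
#' @param models A [GeneModels] with principal isoforms, or a `data.frame`
#'   with columns `gene_id`, `chrom`, `strand`, `tss`, `tes`.
#' @param b,a Upstream/downstream flank lengths in bases.
#' @param m Common rescaled gene-body length in bases.
#' @param bs Bin size in bases; `b`, `a` and `m` must be divisible by it.
#' @param maxThreshold Optional region-exclusion threshold.
#' @return A [MetaProfile]; rownames of the matrix are gene ids.
#' @export
scaleRegionsMatrix <- function(track, models, b = 2500L, a = 2500L,
                               m = 4000L, bs = 10L, maxThreshold = NULL) {
  if (b %% bs != 0 || a %% bs != 0 || m %% bs != 0) {
    stop("b, a and m must be divisible by bs")
  }
  tt <- if (is(models, "GeneModels")) .principal_tx_table(models) else models
  ub <- as.integer(b / bs)
  bb <- as.integer(m / bs)
  db <- as.integer(a / bs)
  nbins <- ub + bb + db
  rows <- matrix(NA_real_, nrow(tt), nbins,
                 dimnames = list(tt$gene_id, NULL))
  for (i in seq_len(nrow(tt))) {
    st <- tt$strand[i]
    tss <- tt$tss[i]
    tes <- tt$tes[i]
    ch <- tt$chrom[i]
    if (st == "+") {
      up <- trackValues(track, ch, tss - b, tss - 1L, st)
      body <- trackValues(track, ch, tss, tes, st)
      down <- trackValues(track, ch, tes + 1L, tes + a, st)
    } else {
      up <- rev(trackValues(track, ch, tss + 1L, tss + b, st))
      body <- rev(trackValues(track, ch, tes, tss, st))
      down <- rev(trackValues(track, ch, tes - a, tes - 1L, st))
    }
    rows[i, ] <- c(.bin_means(up, bs),
                   .resample_area(body, bb),
                   .bin_means(down, bs))
  }
  excluded <- 0L
  if (!is.null(maxThreshold)) {
    over <- apply(rows, 1, function(r) any(r > maxThreshold, na.rm = TRUE))
    excluded <- sum(over)
    rows <- rows[!over, , drop = FALSE]
  }
  new("MetaProfile", matrix = rows, upstreamBins = ub, bodyBins = bb,
      downstreamBins = db, binSize = as.integer(bs),
      nRegionsExcluded = excluded)
}

#' Per-bin ratio of two metagene profiles
#'
#' Used for phospho/total polymerase and IP/Input displays. In
#' `"ratio-of-means"` mode (default) the mean profiles are divided
#' bin-wise; in `"mean-of-ratios"` mode each region's bins are ratioed
#' first and then averaged (requires both profiles to hold the same
#' regions). Bins with a zero or undefined denominator are missing.
#'
#' @param numerator,denominator [MetaProfile]s with identical bin layouts
#'   computed over the same gene set.
#' @param mode See description.
#' @return Numeric vector of per-bin ratios (`NA` where undefined).
#' @export
ratioProfile <- function(numerator, denominator,
                         mode = c("ratio-of-means", "mean-of-ratios")) {
  mode <- match.arg(mode)
  same_layout <-
    numerator@upstreamBins == denominator@upstreamBins &&
    numerator@bodyBins == denominator@bodyBins &&
    numerator@downstreamBins == denominator@downstreamBins
  if (!same_layout) stop("profiles have different bin layouts")
  if (mode == "ratio-of-means") {
    num <- meanProfile(numerator)
    den <- meanProfile(denominator)
    out <- ifelse(!is.na(den) & den != 0, num / den, NA_real_)
  } else {
    if (nrow(numerator@matrix) != nrow(denominator@matrix)) {
      stop("mean-of-ratios mode requires identical region sets")
    }
    rat <- numerator@matrix / denominator@matrix
    rat[!is.finite(rat)] <- NA_real_
    out <- colMeans(rat, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
  }
  unname(out)
}
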