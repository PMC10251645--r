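# pairwise two-sided Wilcoxon p-value matrix over a list of numeric vectors
.pairwise_wilcox <- function(vals) {
  k <- length(vals)
  pm <- matrix(NA_real_, k, k, dimnames = list(names(vals), names(vals)))
  diag(pm) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pm[i, j] <- pm[j, i] <- wilcox.test(vals[[i]], vals[[j]],
                                          alternative = "two.sided",
                                          exact = FALSE)$p.value
    }
  }
  pm
}

# draw `target` elements from group `g` stratified over pooled quantile
# bins; bins the group cannot fill are widened to their neighbours
.stratified_draw <- function(bin_of_group, target_per_bin, warned_env) {
  nb <- length(target_per_bin)
  picked <- integer(0)
  avail <- split(seq_along(bin_of_group), factor(bin_of_group, levels = seq_len(nb)))
  short <- 0L
  for (b in seq_len(nb)) {
    want <- target_per_bin[b]
    have <- avail[[b]]
    if (want <= length(have)) {
      picked <- c(picked, if (want > 0) have[sample.int(length(have), want)])
      avail[[b]] <- setdiff(have, picked)
    } else {
      picked <- c(picked, have)
      short <- short + (want - length(have))
      avail[[b]] <- integer(0)
    }
  }
  if (short > 0L) {
    if (!warned_env$done) {
      warning("some quantile bins could not be filled; ",
              "widening to neighbouring bins")
      warned_env$done <- TRUE
    }
    rest <- setdiff(unlist(avail, use.names = FALSE), picked)
    if (length(rest) < short) stop("group too small for requested subset")
    picked <- c(picked, rest[sample.int(length(rest), short)])
  }
  picked
}

#' Expression-matched gene subsets by iterative random subsampling
#'
#' Draws same-size (or same-fraction) gene subsets from each enrichment
#' category so that the matching covariate (typically log-expression) no
#' longer differs significantly between any pair of subsets. Sampling is
#' stratified: the pooled covariate distribution is cut into quantile bins
#' and every group contributes to each bin proportionally to the pooled
#' bin mass, which makes the matched distributions similar by construction;
#' each iteration is then scored by the minimum pairwise two-sided Wilcoxon
#' rank-sum p-value on the covariate, and the best iteration is returned.
#' Success means that minimum exceeds `alpha`. Iteration stops early once
#' successful. The whole procedure is a pure function of
#' `(inputs, seed)`.
#'
#' @param groups Either a `data.frame` with columns `gene_id`, `category`,
#'   `covariate`, or a named list of data.frames with `gene_id` and
#'   `covariate`.
#' @param mode `"n"` for fixed-size subsets, `"fraction"` for
#'   `floor(frac * group size)` per group.
#' @param n Subset size in fixed-size mode (default 500).
#' @param frac Fraction in fraction mode (default 0.10).
#' @param alpha Significance level defining "no significant difference"
#'   (default 0.05).
#' @param maxIter Maximum iterations (default 100).
#' @param nBins Number of pooled quantile bins (default 20).
#' @param logTransform Apply `log10(x + 1e-3)` to the covariate before
#'   binning and testing (default `TRUE`; expression values are positive
#'   and right-skewed).
#' @param seed Mandatory seed.
#' @return A [MatchedSubsets].
#' @export
iterativeSubsampleMatch <- function(groups, mode = c("n", "fraction"),
                                    n = 500L, frac = 0.10, alpha = 0.05,
                                    maxIter = 100L, nBins = 20L,
                                    logTransform = TRUE, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  if (is.data.frame(groups)) {
    groups <- split(groups[, c("gene_id", "covariate")], groups$category)
  }
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  cov_list <- lapply(groups, function(g) {
    x <- g$covariate
    if (logTransform) log10(x + 1e-3) else x
  })
  sizes <- if (mode == "n") {
    rep(as.integer(n), k)
  } else {
    vapply(groups, function(g) as.integer(floor(frac * nrow(g))), integer(1))
  }
  too_small <- vapply(groups, nrow, integer(1)) < sizes
  if (any(too_small)) {
    stop("group(s) smaller than requested subset size: ",
         paste(names(groups)[too_small], collapse = ", "))
  }

  pooled <- unlist(cov_list, use.names = FALSE)
  # small groups cannot support fine stratification: cap the bin count so
  # each group holds a handful of genes per bin on average
  nBins <- max(1L, min(as.integer(nBins),
                       floor(min(vapply(groups, nrow, integer(1))) / 5)))
  breaks <- unique(quantile(pooled, probs = seq(0, 1, length.out = nBins + 1)))
  bin_of <- lapply(cov_list, function(x) {
    findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  })
  nb <- length(breaks) - 1L
  # per-bin sampling mass: the overlap of the group distributions (the
  # per-bin minimum of group counts); proportional-to-pooled targets would
  # ask sparse groups for genes they do not have in the tails, leaving the
  # subsets unmatched whenever the groups differ
  bin_counts <- vapply(bin_of, tabulate, nbins = nb, integer(nb))
  cap <- apply(bin_counts, 1, min)
  if (sum(cap) == 0L) stop("group covariate distributions do not overlap")
  bin_mass <- cap / sum(cap)

  targets <- lapply(seq_len(k), function(gi) {
    avail <- bin_counts[, gi]
    tgt <- pmin(floor(sizes[gi] * bin_mass), avail)
    # distribute the remainder: first into bins with overlap headroom
    # (largest fractional part first), then wherever the group has genes
    rem <- sizes[gi] - sum(tgt)
    frac <- sizes[gi] * bin_mass - floor(sizes[gi] * bin_mass)
    for (pass in 1:2) {
      if (rem == 0L) break
      room <- if (pass == 1L) pmin(cap, avail) - tgt else avail - tgt
      for (b in order(frac, decreasing = TRUE)) {
        if (rem == 0L) break
        add <- min(rem, max(0L, room[b]))
        tgt[b] <- tgt[b] + add
        rem <- rem - add
      }
    }
    tgt
  })

  set.seed(as.integer(seed))
  warned_env <- new.env()
  warned_env$done <- FALSE
  best_minp <- -Inf
  best <- NULL
  iter_used <- 0L
  for (it in seq_len(maxIter)) {
    iter_used <- it
    idx <- lapply(seq_len(k), function(gi) {
      .stratified_draw(bin_of[[gi]], targets[[gi]], warned_env)
    })
    vals <- lapply(seq_len(k), function(gi) cov_list[[gi]][idx[[gi]]])
    names(vals) <- names(groups)
    pm <- .pairwise_wilcox(vals)
    minp <- min(pm[upper.tri(pm)])
    if (minp > best_minp) {
      best_minp <- minp
      best <- list(idx = idx, pm = pm)
    }
    if (best_minp > alpha) break
  }
  subsets <- lapply(seq_len(k), function(gi) {
    sort(groups[[gi]]$gene_id[best$idx[[gi]]])
  })
  names(subsets) <- names(groups)
  new("MatchedSubsets", subsets = subsets, pvalues = best$pm,
      nIterationsUsed = iter_used, seed = as.integer(seed),
      success = best_minp > alpha, mode = mode, alpha = alpha)
}
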