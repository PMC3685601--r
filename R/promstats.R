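# Promoter-set statistics: positional TFBS density and GC profiles around
# the anchor, nearest-anchor distances for external peak sets, and p-value
# cutoff sweeps.

# Anchor-relative extent [lo, hi) of each promoter in a set.
.anchorExtents <- function(promoters) {
  info <- promoters@info
  lo <- integer(nrow(info))
  for (j in seq_len(nrow(info))) lo[j] <- .anchorRel(info[j, ], 0L)
  data.frame(lo = lo, hi = lo + (info$gend - info$gstart))
}

.binProfile <- function(binStarts, values) {
  data.frame(bin_start = binStarts, bin_end = binStarts + diff(binStarts)[1],
             value = values)
}

#' Positional density of predicted sites around the anchor
#'
#' Hit start positions (anchor-relative) are collected in bins of
#' \code{binWidth} bases; bin \code{[0, binWidth)} starts at the anchor
#' base, upstream bins are negative. With \code{perPromoter = TRUE} counts
#' are divided by the number of promoters covering each bin (clip-aware);
#' with \code{normalization = "max1"} the profile is scaled so its maximum
#' is 1 (plot scaling).
#'
#' @param hits hit data.frame carrying \code{start_anchor} (from
#'   \code{\link{scanPromoterSet}}).
#' @param promoters the scanned \linkS4class{PromoterSet}.
#' @param binWidth bin width in bases; default 50.
#' @param normalization \code{"raw"} (default) or \code{"max1"}.
#' @param perPromoter divide by per-bin promoter coverage first.
#' @return data.frame with columns \code{bin_start}, \code{bin_end},
#'   \code{value} (contiguous, sorted).
#' @export
tfbsDensityProfile <- function(hits, promoters, binWidth = 50,
                               normalization = c("raw", "max1"),
                               perPromoter = FALSE) {
  normalization <- match.arg(normalization)
  if (binWidth <= 0) stop("binWidth must be positive")
  ext <- .anchorExtents(promoters)
  kLo <- floor(min(ext$lo) / binWidth)
  kHi <- ceiling(max(ext$hi) / binWidth)
  nb <- kHi - kLo
  binStarts <- (kLo + 0:(nb - 1L)) * binWidth
  counts <- numeric(nb)
  if (nrow(hits)) {
    k <- floor(hits$start_anchor / binWidth) - kLo + 1L
    k <- k[k >= 1L & k <= nb]
    tab <- tabulate(k, nbins = nb)
    counts <- as.numeric(tab)
  }
  if (perPromoter) {
    cov <- vapply(seq_len(nb), function(i) {
      b0 <- binStarts[i]
      sum(ext$lo < b0 + binWidth & ext$hi > b0)
    }, numeric(1))
    counts <- ifelse(cov > 0, counts / cov, 0)
  }
  if (normalization == "max1" && max(counts) > 0)
    counts <- counts / max(counts)
  .binProfile(binStarts, counts)
}

#' Positional GC content around the anchor
#'
#' Fraction of G/C bases per anchor-relative bin, pooled over all
#' promoters covering the bin (clipped promoters contribute only to the
#' bins they cover).
#'
#' @param promoters a \linkS4class{PromoterSet}.
#' @param binWidth bin width in bases; default 50.
#' @return data.frame with columns \code{bin_start}, \code{bin_end},
#'   \code{value} (GC fraction; NA for uncovered bins).
#' @export
gcProfile <- function(promoters, binWidth = 50) {
  if (binWidth <= 0) stop("binWidth must be positive")
  ext <- .anchorExtents(promoters)
  kLo <- floor(min(ext$lo) / binWidth)
  kHi <- ceiling(max(ext$hi) / binWidth)
  nb <- kHi - kLo
  binStarts <- (kLo + 0:(nb - 1L)) * binWidth
  gcSum <- numeric(nb)
  nSum <- numeric(nb)
  seqs <- as.character(promoters@sequences)
  for (j in seq_along(seqs)) {
    code <- encodeDNA(seqs[[j]])
    isGC <- code %in% c(2L, 3L)
    rel <- ext$lo[j] + seq_along(code) - 1L
    k <- floor(rel / binWidth) - kLo + 1L
    gcSum <- gcSum + tabulate(k[isGC], nbins = nb)
    nSum <- nSum + tabulate(k, nbins = nb)
  }
  value <- ifelse(nSum > 0, gcSum / nSum, NA_real_)
  .binProfile(binStarts, value)
}

#' Signed distance of peaks to the nearest anchor
#'
#' For each peak (e.g. a ChIP peak center) the signed distance to the
#' nearest anchor on the same chromosome. The sign is negative upstream of
#' the anchor: on the anchor's strand when a \code{strand} column is
#' supplied, genomic-left otherwise. Distance ties prefer the smaller
#' absolute value and then the negative sign. Peaks on chromosomes without
#' anchors are skipped with a message giving the count.
#'
#' @param peaks data.frame with columns \code{chrom}, \code{position}.
#' @param anchors data.frame with columns \code{chrom}, \code{position}
#'   and optionally \code{strand}.
#' @return numeric vector of signed distances (one per retained peak),
#'   suitable for histogramming in 50-base bins.
#' @export
nearestAnchorDistance <- function(peaks, anchors) {
  stranded <- "strand" %in% names(anchors)
  out <- numeric(0)
  skipped <- 0L
  for (ch in unique(peaks$chrom)) {
    pk <- peaks$position[peaks$chrom == ch]
    an <- anchors[anchors$chrom == ch, , drop = FALSE]
    if (!nrow(an)) {
      skipped <- skipped + length(pk)
      next
    }
    ord <- order(an$position)
    pos <- an$position[ord]
    str <- if (stranded) an$strand[ord] else rep("+", length(pos))
    i <- findInterval(pk, pos)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(pos))
    dLo <- abs(pk - pos[lo])
    dHi <- abs(pk - pos[hi])
    signedOf <- function(idx) {
      d <- pk - pos[idx]
      ifelse(str[idx] == "-", -d, d)
    }
    sLo <- signedOf(lo)
    sHi <- signedOf(hi)
    pick <- ifelse(dLo < dHi, sLo,
                   ifelse(dHi < dLo, sHi, pmin(sLo, sHi)))
    out <- c(out, pick)
  }
  if (skipped)
    message(skipped, " peak(s) on chromosomes without anchors skipped")
  out
}

#' Hit, promoter and model percentages across p-value cutoffs
#'
#' Scans every (model, promoter, strand) combination once and
#' re-thresholds at each cutoff. The 100\% baseline corresponds to the
#' values obtained without any cutoff: all possible hit positions
#' (\eqn{\sum \max(0, \mathrm{len} - L + 1)} per model, promoter and
#' strand), all promoters and all models. A cutoff of 1 reproduces that
#' baseline by construction.
#'
#' @param calibs list of \linkS4class{CalibratedModel}.
#' @param promoters a \linkS4class{PromoterSet}.
#' @param cutoffs p-value cutoffs in (0, 1], any order; reported sorted
#'   descending.
#' @return data.frame with columns \code{p_cutoff}, \code{pct_hits},
#'   \code{pct_promoters}, \code{pct_pfms}, each column non-increasing as
#'   the cutoff tightens.
#' @export
cutoffSweep <- function(calibs, promoters, cutoffs) {
  stopifnot(is(promoters, "PromoterSet"))
  if (any(cutoffs <= 0 | cutoffs > 1)) stop("cutoffs must lie in (0, 1]")
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  seqs <- as.character(promoters@sequences)
  nProm <- length(seqs)
  nMod <- length(calibs)
  totalPos <- 0
  nHits <- setNames(numeric(length(cutoffs)), cutoffs)
  promHit <- matrix(FALSE, nProm, length(cutoffs))
  modHit <- matrix(FALSE, nMod, length(cutoffs))
  for (m in seq_len(nMod)) {
    L <- motifLength(calibs[[m]])
    for (j in seq_len(nProm)) {
      nw <- max(0L, nchar(seqs[[j]]) - L + 1L)
      totalPos <- totalPos + 2 * nw
      if (!nw) next
      p <- .scanAll(calibs[[m]], seqs[[j]], "both")$p_value
      for (k in seq_along(cutoffs)) {
        cnt <- if (cutoffs[k] >= 1) length(p) else sum(p < cutoffs[k])
        nHits[k] <- nHits[k] + cnt
        if (cnt > 0) {
          promHit[j, k] <- TRUE
          modHit[m, k] <- TRUE
        }
      }
    }
  }
  data.frame(p_cutoff = cutoffs,
             pct_hits = 100 * nHits / max(1, totalPos),
             pct_promoters = 100 * colSums(promHit) / max(1L, nProm),
             pct_pfms = 100 * colSums(modHit) / max(1L, nMod),
             row.names = NULL)
}
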