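# Over-representation of features between positive and negative gene sets:
# mean occurrences per gene, ratios, percentile-bootstrap CIs, and
# co-occurring pairs with separation constraints.

# Resolve requested accessions against a store (version-stripped match);
# missing accessions are dropped with a logged count.
.resolveGenes <- function(store, genome, accessions, quiet = FALSE) {
  .checkGenome(store, genome)
  stored <- store@promoters[[genome]]@info$accession
  idx <- match(stripVersion(accessions), stripVersion(stored))
  dropped <- sum(is.na(idx))
  resolved <- stored[idx[!is.na(idx)]]
  resolved <- unique(resolved)
  if (dropped && !quiet)
    message(sprintf("%d of %d gene(s) not represented in genome %s; dropped",
                    dropped, length(accessions), genome))
  list(accessions = resolved, nDropped = dropped)
}

.filterHits <- function(hits, pCutoff = NULL) {
  if (is.null(pCutoff)) return(hits)
  hits[hits$p_value < pCutoff, , drop = FALSE]
}

#' Mean occurrence of features per gene
#'
#' For each feature, the number of hits in each resolved gene's promoter
#' and the mean over genes. Accessions absent from the store are dropped
#' (with a message giving the count).
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id.
#' @param accessions gene set (accessions; versions ignored).
#' @param features feature ids; default all features in the store.
#' @param pCutoff optional p-value re-threshold applied to stored hits
#'   (strict, \code{p < pCutoff}).
#' @return list with \code{mean} (named numeric per feature),
#'   \code{counts} (genes x features matrix), \code{nResolved},
#'   \code{nDropped}.
#' @export
meanOccurrence <- function(store, genome, accessions, features = NULL,
                           pCutoff = NULL) {
  if (is.null(features)) features <- store@features
  res <- .resolveGenes(store, genome, accessions)
  if (!length(res$accessions)) stop("no gene of the set is in the store")
  hits <- .filterHits(store@hits[[genome]], pCutoff)
  hits <- hits[hits$accession %in% res$accessions &
                 hits$feature_id %in% features, , drop = FALSE]
  counts <- table(factor(hits$accession, levels = res$accessions),
                  factor(hits$feature_id, levels = features))
  counts <- matrix(as.integer(counts), nrow = length(res$accessions),
                   dimnames = list(res$accessions, features))
  list(mean = colMeans(counts), counts = counts,
       nResolved = length(res$accessions), nDropped = res$nDropped)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Genes are resampled with replacement \code{nBoot} times; the interval is
#' the (2.5\%, 97.5\%) quantile pair of the resampled means (at the default
#' level). Deterministic given \code{seed}; the caller's RNG state is left
#' untouched.
#'
#' @param counts per-gene counts (numeric vector, length >= 1).
#' @param nBoot number of bootstrap replicates; default 1000.
#' @param level confidence level; default 0.95.
#' @param seed integer seed.
#' @return named numeric \code{c(lower, upper)}.
#' @export
bootstrapCI <- function(counts, nBoot = 1000, level = 0.95, seed = 1) {
  stopifnot(length(counts) >= 1, nBoot >= 1)
  means <- withSeed(seed, {
    idx <- matrix(sample.int(length(counts), length(counts) * nBoot,
                             replace = TRUE), ncol = nBoot)
    colMeans(matrix(counts[idx], ncol = nBoot))
  })
  alpha <- (1 - level) / 2
  q <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(lower = q[1], upper = q[2])
}

.rankRatios <- function(df) {
  ord <- order(is.na(df$ratio), -ifelse(is.na(df$ratio), 0, df$ratio))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Feature over-representation between two gene sets
#'
#' For each feature t, the mean occurrence per gene in the positive set
#' (\eqn{\bar P_t}) and negative set (\eqn{\bar N_t}) and their ratio
#' \eqn{r = \bar P_t / \bar N_t}, with percentile-bootstrap 95\% confidence
#' intervals for both means. Features absent from the negative set have an
#' undefined ratio; they are flagged and ranked last rather than dropped.
#'
#' With \code{homologGenome} and \code{homology}, both gene sets are first
#' restricted to genes having at least one homolog in that genome, and a
#' gene's count for feature t contributes only when some homolog's promoter
#' also carries a hit of t (otherwise it counts 0) -- the cross-genome
#' conservation cross-check.
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id.
#' @param positive,negative gene sets (accession vectors).
#' @param features feature ids; default all.
#' @param pCutoff optional strict p-value re-threshold.
#' @param nBoot,level,seed bootstrap settings (see
#'   \code{\link{bootstrapCI}}).
#' @param homologGenome,homology optional cross-genome filter (see
#'   Details).
#' @return data.frame sorted by ratio descending with columns
#'   \code{feature_id}, \code{pos_mean}, \code{neg_mean}, \code{ratio},
#'   \code{ratio_undefined}, \code{ci_pos_lower}, \code{ci_pos_upper},
#'   \code{ci_neg_lower}, \code{ci_neg_upper}, \code{n_pos}, \code{n_neg}.
#' @export
overrepRatios <- function(store, genome, positive, negative,
                          features = NULL, pCutoff = NULL, nBoot = 1000,
                          level = 0.95, seed = 1, homologGenome = NULL,
                          homology = NULL) {
  if (is.null(features)) features <- store@features
  countsOf <- function(geneSet) {
    mo <- meanOccurrence(store, genome, geneSet, features, pCutoff)
    mo$counts
  }
  pos <- countsOf(positive)
  neg <- countsOf(negative)
  if (!is.null(homologGenome)) {
    if (is.null(homology)) stop("homology table required with homologGenome")
    pos <- .homologMask(store, genome, homologGenome, homology, pos,
                        features, pCutoff)
    neg <- .homologMask(store, genome, homologGenome, homology, neg,
                        features, pCutoff)
    if (!nrow(pos) || !nrow(neg))
      stop("no genes with homologs in ", homologGenome)
  }
  seeds <- childSeeds(seed, 2L * length(features))
  rows <- lapply(seq_along(features), function(k) {
    f <- features[k]
    cp <- pos[, f]
    cn <- neg[, f]
    cip <- bootstrapCI(cp, nBoot, level, seeds[2 * k - 1])
    cin <- bootstrapCI(cn, nBoot, level, seeds[2 * k])
    pm <- mean(cp)
    nm <- mean(cn)
    data.frame(feature_id = f, pos_mean = pm, neg_mean = nm,
               ratio = if (nm > 0) pm / nm else NA_real_,
               ratio_undefined = nm == 0,
               ci_pos_lower = cip[["lower"]], ci_pos_upper = cip[["upper"]],
               ci_neg_lower = cin[["lower"]], ci_neg_upper = cin[["upper"]],
               n_pos = nrow(pos), n_neg = nrow(neg),
               stringsAsFactors = FALSE)
  })
  .rankRatios(do.call(rbind, rows))
}

# Restrict a count matrix to genes with homologs in genomeB and zero out
# counts whose homolog promoters lack the feature.
.homologMask <- function(store, genome, genomeB, homology, counts,
                         features, pCutoff) {
  hmap <- .homologMap(homology, genome, genomeB)
  keep <- stripVersion(rownames(counts)) %in% names(hmap)
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) return(counts)
  hitsB <- .filterHits(store@hits[[genomeB]], pCutoff)
  haveB <- unique(paste(stripVersion(hitsB$accession), hitsB$feature_id))
  for (g in rownames(counts)) {
    homs <- hmap[[stripVersion(g)]]
    for (f in features) {
      if (!any(paste(homs, f) %in% haveB)) counts[g, f] <- 0L
    }
  }
  counts
}

#' Count co-occurring hit pairs in one hit table
#'
#' All unordered pairs of hits (features may be equal) whose separation --
#' the gap in bases between the end of the upstream hit and the start of
#' the downstream hit -- lies within \code{[minSep, maxSep]} inclusive.
#' Overlapping hits (negative gap) never pair; strand is ignored.
#'
#' @param hits hit data.frame with columns \code{feature_id},
#'   \code{start_rel}, \code{width}.
#' @param minSep,maxSep inclusive gap bounds in bases (defaults 10, 100).
#' @return named integer vector; names are unordered feature-pair keys
#'   \code{"A|B"} (alphabetical, \code{"A|A"} for self-pairs).
#' @export
countHitPairs <- function(hits, minSep = 10, maxSep = 100) {
  if (minSep > maxSep) stop("minSep must not exceed maxSep")
  n <- nrow(hits)
  if (n < 2L) return(setNames(integer(0), character(0)))
  ord <- order(hits$start_rel)
  st <- hits$start_rel[ord]
  en <- st + hits$width[ord]
  ft <- hits$feature_id[ord]
  keys <- character(0)
  for (i in seq_len(n - 1L)) {
    gap <- st[(i + 1L):n] - en[i]
    sel <- which(gap >= minSep & gap <= maxSep)
    if (length(sel)) {
      j <- i + sel
      a <- pmin(ft[i], ft[j])
      b <- pmax(ft[i], ft[j])
      keys <- c(keys, paste(a, b, sep = "|"))
    }
  }
  if (!length(keys)) return(setNames(integer(0), character(0)))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

#' Per-gene counts of co-occurring feature pairs
#'
#' Counts hit pairs per promoter (see \code{\link{countHitPairs}}) for each
#' resolved gene of a set.
#'
#' @inheritParams meanOccurrence
#' @param minSep,maxSep inclusive gap bounds in bases.
#' @return list with \code{counts} (genes x pair-keys matrix; keys
#'   \code{"A|B"}), \code{mean}, \code{nResolved}, \code{nDropped}.
#' @export
pairOccurrences <- function(store, genome, accessions, minSep = 10,
                            maxSep = 100, features = NULL, pCutoff = NULL) {
  if (minSep > maxSep) stop("minSep must not exceed maxSep")
  res <- .resolveGenes(store, genome, accessions)
  if (!length(res$accessions)) stop("no gene of the set is in the store")
  hits <- .filterHits(store@hits[[genome]], pCutoff)
  if (!is.null(features))
    hits <- hits[hits$feature_id %in% features, , drop = FALSE]
  perGene <- lapply(res$accessions, function(a)
    countHitPairs(hits[hits$accession == a, , drop = FALSE], minSep, maxSep))
  keys <- sort(unique(unlist(lapply(perGene, names), use.names = FALSE)))
  counts <- matrix(0L, nrow = length(res$accessions), ncol = length(keys),
                   dimnames = list(res$accessions, keys))
  for (i in seq_along(perGene)) {
    if (length(perGene[[i]])) counts[i, names(perGene[[i]])] <- perGene[[i]]
  }
  list(counts = counts, mean = colMeans(counts),
       nResolved = length(res$accessions), nDropped = res$nDropped)
}

#' Over-represented feature pairs between two gene sets
#'
#' Like \code{\link{overrepRatios}} but on per-gene pair counts with a
#' separation window. Pairs never seen in the negative set have undefined
#' ratios (flagged, ranked last).
#'
#' @inheritParams overrepRatios
#' @param minSep,maxSep inclusive gap bounds in bases (defaults 10, 100).
#' @return data.frame sorted by ratio descending with columns
#'   \code{pair}, \code{pos_mean}, \code{neg_mean}, \code{ratio},
#'   \code{ratio_undefined}, \code{min_sep}, \code{max_sep}, \code{n_pos},
#'   \code{n_neg}.
#' @export
pairOverrep <- function(store, genome, positive, negative, minSep = 10,
                        maxSep = 100, features = NULL, pCutoff = NULL) {
  pos <- pairOccurrences(store, genome, positive, minSep, maxSep, features,
                         pCutoff)
  neg <- pairOccurrences(store, genome, negative, minSep, maxSep, features,
                         pCutoff)
  keys <- sort(union(colnames(pos$counts), colnames(neg$counts)))
  meanOf <- function(x, k) if (k %in% names(x$mean)) x$mean[[k]] else 0
  rows <- lapply(keys, function(k) {
    pm <- meanOf(pos, k)
    nm <- meanOf(neg, k)
    data.frame(pair = k, pos_mean = pm, neg_mean = nm,
               ratio = if (nm > 0) pm / nm else NA_real_,
               ratio_undefined = nm == 0,
               min_sep = minSep, max_sep = maxSep,
               n_pos = pos$nResolved, n_neg = neg$nResolved,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(pair = character(0), pos_mean = numeric(0),
                      neg_mean = numeric(0), ratio = numeric(0),
                      ratio_undefined = logical(0), min_sep = integer(0),
                      max_sep = integer(0), n_pos = integer(0),
                      n_neg = integer(0)))
  .rankRatios(do.call(rbind, rows))
}
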