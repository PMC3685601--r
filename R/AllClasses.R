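# Central S4 classes. Row order of all 4xL matrices is fixed to A,C,G,T.

#' Position frequency matrix (raw counts)
#'
#' A motif summarized as per-position base counts over aligned binding
#' sites, the format distributed by JASPAR. Rows are fixed to A,C,G,T.
#'
#' @slot id accession, e.g. \code{"MA0001.1"}.
#' @slot name factor name, possibly empty.
#' @slot counts 4 x L numeric matrix of non-negative counts; every column
#'   must contain at least one strictly positive count.
#' @seealso \code{\link{readJaspar}}, \code{\link{toFrequencies}}
#' @export
setClass("PFM", slots = c(id = "character", name = "character",
                          counts = "matrix"))

setValidity("PFM", function(object) {
  m <- object@counts
  if (!is.numeric(m) || nrow(m) != 4L) return("counts must be a 4 x L numeric matrix")
  if (ncol(m) < 1L) return("motif length L must be >= 1")
  if (!identical(rownames(m), DNA_BASES4)) return("counts rows must be named A,C,G,T")
  if (any(!is.finite(m)) || any(m < 0)) return("counts must be finite and non-negative")
  if (any(colSums(m) <= 0)) return("every column needs at least one positive count")
  TRUE
})

#' Column probability matrix of a motif
#'
#' Per-position relative base frequencies \eqn{f_{a,i}} derived from a
#' \linkS4class{PFM}, optionally regularized by a pseudocount (recorded for
#' provenance).
#'
#' @slot id motif accession.
#' @slot f 4 x L matrix of probabilities; each column sums to 1.
#' @slot pseudocount non-negative pseudocount used in the conversion.
#' @seealso \code{\link{toFrequencies}}, \code{\link{buildScoreModel}}
#' @export
setClass("FrequencyMatrix", slots = c(id = "character", f = "matrix",
                                      pseudocount = "numeric"))

setValidity("FrequencyMatrix", function(object) {
  f <- object@f
  if (nrow(f) != 4L || !identical(rownames(f), DNA_BASES4))
    return("f must be a 4 x L matrix with rows A,C,G,T")
  if (any(f < 0) || any(f > 1)) return("frequencies must lie in [0,1]")
  if (any(abs(colSums(f) - 1) > 1e-12)) return("columns must sum to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    return("pseudocount must be a single non-negative number")
  TRUE
})

#' Log-likelihood-ratio scoring model
#'
#' Weights \eqn{w_{a,i} = \ln(f_{a,i} / b_a)} against a background base
#' distribution \eqn{b}; a window of length L scores
#' \eqn{S = \sum_i w_{s_i, i}}. \code{sMin}/\code{sMax} are the sums of
#' column minima/maxima, the reachable score range.
#'
#' @slot id motif accession.
#' @slot weights 4 x L matrix of finite log-likelihood ratios (nats).
#' @slot background length-4 probability vector (A,C,G,T), all entries > 0.
#' @slot sMin,sMax reachable score bounds.
#' @seealso \code{\link{buildScoreModel}}, \code{\link{scoreDistribution}}
#' @export
setClass("ScoreModel", slots = c(id = "character", weights = "matrix",
                                 background = "numeric",
                                 sMin = "numeric", sMax = "numeric"))

setValidity("ScoreModel", function(object) {
  w <- object@weights
  if (nrow(w) != 4L || !identical(rownames(w), DNA_BASES4))
    return("weights must be a 4 x L matrix with rows A,C,G,T")
  if (any(!is.finite(w))) return("weights must be finite")
  b <- object@background
  if (length(b) != 4L || any(b <= 0) || abs(sum(b) - 1) > 1e-12)
    return("background must be 4 positive probabilities summing to 1")
  if (object@sMin > object@sMax) return("sMin must not exceed sMax")
  if (abs(sum(apply(w, 2, max)) - object@sMax) > 1e-9)
    return("sMax must equal the sum of column maxima")
  TRUE
})

#' Exact null distribution of a model's score
#'
#' Discretized distribution of the window score under the background,
#' obtained by column-wise convolution on an integer grid with
#' \code{granularity} grid units per nat. The grid is stored implicitly as
#' \code{gridMin + 0:(length(pmf) - 1)}; \code{sf[k]} is
#' \eqn{P(\mathrm{score} \ge \mathrm{grid}[k])}.
#'
#' @slot modelId motif accession.
#' @slot granularity grid units per score unit (nat).
#' @slot gridMin lowest integer grid score.
#' @slot L motif length (bounds the accumulated rounding error of a raw
#'   score sum at L/2 grid units).
#' @slot pmf probability mass per grid bin (sums to 1).
#' @slot sf survival function per grid bin, non-increasing, \code{sf[1] == 1}.
#' @seealso \code{\link{scoreDistribution}}, \code{\link{pvalueOfScore}}
#' @export
setClass("ScoreDistribution", slots = c(modelId = "character",
                                        granularity = "numeric",
                                        gridMin = "integer", L = "integer",
                                        pmf = "numeric", sf = "numeric"))

setValidity("ScoreDistribution", function(object) {
  if (object@granularity <= 0) return("granularity must be positive")
  if (length(object@pmf) != length(object@sf)) return("pmf and sf lengths differ")
  if (abs(sum(object@pmf) - 1) > 1e-9) return("pmf must sum to 1")
  if (any(diff(object@sf) > 1e-12)) return("sf must be non-increasing")
  if (abs(object@sf[1] - 1) > 1e-9) return("sf at the lowest bin must be 1")
  TRUE
})

#' A scoring model with its exact p-value calibration
#'
#' @slot model the \linkS4class{ScoreModel}.
#' @slot dist the \linkS4class{ScoreDistribution} at the chosen granularity.
#' @slot pMin smallest reachable p-value (p-value of the maximum score);
#'   models with \code{pMin} at or above a cutoff cannot produce hits there.
#' @seealso \code{\link{calibrateModel}}, \code{\link{scoreThreshold}}
#' @export
setClass("CalibratedModel", slots = c(model = "ScoreModel",
                                      dist = "ScoreDistribution",
                                      pMin = "numeric"))

setValidity("CalibratedModel", function(object) {
  if (object@pMin <= 0 || object@pMin > 1) return("pMin must lie in (0, 1]")
  TRUE
})

#' A strand-oriented promoter set
#'
#' Fixed-flank windows around each gene's anchor (TSS, or CSS when the TSS
#' is unannotated), with sequences stored 5'->3' of the gene so that
#' position 0 is the most-upstream retained base. Genomic coordinates are
#' 0-based half-open.
#'
#' @slot genomeId genome label the promoters were extracted from.
#' @slot info data.frame with one row per promoter: \code{accession},
#'   \code{symbol}, \code{chrom}, \code{strand}, \code{anchor_type}
#'   (\code{"TSS"}/\code{"CSS"}), \code{anchor_pos}, \code{flank},
#'   \code{gstart}, \code{gend}, \code{clipped}, \code{layer}.
#' @slot sequences \code{DNAStringSet} named by accession, in gene
#'   orientation.
#' @seealso \code{\link{extractPromoters}}
#' @export
setClass("PromoterSet", slots = c(genomeId = "character", info = "data.frame",
                                  sequences = "DNAStringSet"))

setValidity("PromoterSet", function(object) {
  info <- object@info
  need <- c("accession", "chrom", "strand", "anchor_type", "anchor_pos",
            "flank", "gstart", "gend", "clipped")
  if (!all(need %in% names(info)))
    return(paste("info must contain columns:", paste(need, collapse = ", ")))
  if (nrow(info) != length(object@sequences))
    return("info rows and sequences differ in number")
  if (anyDuplicated(stripVersion(info$accession)))
    return("promoter accessions must be unique (after version stripping)")
  if (!identical(names(object@sequences), info$accession))
    return("sequence names must match info$accession in order")
  if (nrow(info) && any(width(object@sequences) != info$gend - info$gstart))
    return("sequence lengths must equal gend - gstart")
  if (nrow(info) && any(info$gend - info$gstart > 2 * info$flank))
    return("window length must not exceed 2*flank")
  TRUE
})

#' Layered gene-centered annotation store
#'
#' Holds, per genome, a promoter set and its predicted hits, each tagged
#' with a layer (\code{"default"} or \code{"user"}); queries always see the
#' union of layers.
#'
#' @slot promoters named list: genome id -> \linkS4class{PromoterSet}.
#' @slot hits named list: genome id -> hit data.frame (sorted by accession,
#'   start_rel, feature_id, strand; carries a \code{layer} column).
#' @slot features character vector of known feature (motif) ids.
#' @seealso \code{\link{buildStore}}, \code{\link{queryGenes}}
#' @export
setClass("AnnotationStore", slots = c(promoters = "list", hits = "list",
                                      features = "character"))

setValidity("AnnotationStore", function(object) {
  if (!identical(names(object@promoters), names(object@hits)))
    return("promoters and hits must cover the same genomes")
  for (g in names(object@promoters)) {
    acc <- object@promoters[[g]]@info$accession
    h <- object@hits[[g]]
    if (nrow(h) && !all(h$accession %in% acc))
      return(sprintf("genome %s: hits reference unknown promoters", g))
  }
  TRUE
})

# ---- feature query expression tree --------------------------------------

#' Feature query expressions
#'
#' Combinatorial queries over predicted sites in a promoter:
#' \code{featureTerm(f, minCount)} is satisfied when the promoter carries at
#' least \code{minCount} hits of feature \code{f}; \code{featureAnd}/
#' \code{featureOr} combine sub-queries; \code{featurePair} requires a pair
#' of hits of two features (possibly equal) whose gap lies within
#' \code{[minSep, maxSep]} bases.
#'
#' @name FeatureQuery
#' @aliases FeatureQuery-class FeatureTerm-class FeatureAnd-class
#'   FeatureOr-class FeaturePair-class
#' @seealso \code{\link{queryGenes}}
NULL

#' @export
setClass("FeatureQuery", representation("VIRTUAL"))

#' @export
setClass("FeatureTerm", contains = "FeatureQuery",
         slots = c(feature = "character", minCount = "integer"))

#' @export
setClass("FeatureAnd", contains = "FeatureQuery", slots = c(queries = "list"))

#' @export
setClass("FeatureOr", contains = "FeatureQuery", slots = c(queries = "list"))

#' @export
setClass("FeaturePair", contains = "FeatureQuery",
         slots = c(featureA = "character", featureB = "character",
                   minSep = "integer", maxSep = "integer",
                   minCount = "integer"))

setValidity("FeaturePair", function(object) {
  if (object@minSep > object@maxSep) return("minSep must not exceed maxSep")
  TRUE
})
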