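# Accessor generics and show methods. Slots are never accessed directly by
# user code; these accessors are the supported surface.

#' @describeIn PFM motif accession
#' @param x an object.
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @describeIn PFM motif length L (number of columns)
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @export
setMethod("motifId", "PFM", function(x) x@id)
#' @export
setMethod("motifId", "FrequencyMatrix", function(x) x@id)
#' @export
setMethod("motifId", "ScoreModel", function(x) x@id)
#' @export
setMethod("motifId", "ScoreDistribution", function(x) x@modelId)
#' @export
setMethod("motifId", "CalibratedModel", function(x) x@model@id)

#' @export
setMethod("motifLength", "PFM", function(x) ncol(x@counts))
#' @export
setMethod("motifLength", "FrequencyMatrix", function(x) ncol(x@f))
#' @export
setMethod("motifLength", "ScoreModel", function(x) ncol(x@weights))
#' @export
setMethod("motifLength", "CalibratedModel", function(x) ncol(x@model@weights))

#' Motif count matrix
#' @param x a \linkS4class{PFM}.
#' @return 4 x L count matrix (rows A,C,G,T).
#' @export
motifCounts <- function(x) {
  stopifnot(is(x, "PFM"))
  x@counts
}

#' Column probability matrix
#' @param x a \linkS4class{FrequencyMatrix}.
#' @return 4 x L probability matrix.
#' @export
frequencyMatrix <- function(x) {
  stopifnot(is(x, "FrequencyMatrix"))
  x@f
}

#' Log-likelihood-ratio weight matrix
#' @param x a \linkS4class{ScoreModel} or \linkS4class{CalibratedModel}.
#' @return 4 x L weight matrix in nats.
#' @export
weightMatrix <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@model
  stopifnot(is(x, "ScoreModel"))
  x@weights
}

#' Reachable score bounds of a model
#' @param x a \linkS4class{ScoreModel} or \linkS4class{CalibratedModel}.
#' @return a number (nats).
#' @export
scoreMin <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@model
  x@sMin
}

#' @rdname scoreMin
#' @export
scoreMax <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@model
  x@sMax
}

#' Background base distribution of a model
#' @param x a \linkS4class{ScoreModel} or \linkS4class{CalibratedModel}.
#' @return named probability vector (A,C,G,T).
#' @export
modelBackground <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@model
  x@background
}

#' Integer score grid of a distribution
#' @param x a \linkS4class{ScoreDistribution} or \linkS4class{CalibratedModel}.
#' @return ascending integer grid (units of 1/granularity nats).
#' @export
scoreGrid <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@dist
  x@gridMin + 0:(length(x@pmf) - 1L)
}

#' @rdname scoreGrid
#' @export
scorePmf <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@dist
  x@pmf
}

#' @rdname scoreGrid
#' @export
scoreSurvival <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@dist
  x@sf
}

#' @rdname scoreGrid
#' @export
scoreGranularity <- function(x) {
  if (is(x, "CalibratedModel")) x <- x@dist
  x@granularity
}

#' Smallest reachable p-value of a calibrated model
#' @param x a \linkS4class{CalibratedModel}.
#' @return probability in (0, 1].
#' @export
pMin <- function(x) {
  stopifnot(is(x, "CalibratedModel"))
  x@pMin
}

#' Underlying model / distribution of a calibration
#' @param x a \linkS4class{CalibratedModel}.
#' @export
scoreModel <- function(x) {
  stopifnot(is(x, "CalibratedModel"))
  x@model
}

#' @rdname scoreModel
#' @export
scoreDist <- function(x) {
  stopifnot(is(x, "CalibratedModel"))
  x@dist
}

# ---- PromoterSet accessors ----------------------------------------------

#' Genome label of a promoter set
#' @param x a \linkS4class{PromoterSet}.
#' @export
genomeId <- function(x) {
  stopifnot(is(x, "PromoterSet"))
  x@genomeId
}

#' Promoter metadata table
#' @param x a \linkS4class{PromoterSet}.
#' @return data.frame, one row per promoter.
#' @export
promoterInfo <- function(x) {
  stopifnot(is(x, "PromoterSet"))
  x@info
}

#' Promoter sequences
#' @param x a \linkS4class{PromoterSet}.
#' @return \code{DNAStringSet} named by accession, gene orientation.
#' @export
promoterSequences <- function(x) {
  stopifnot(is(x, "PromoterSet"))
  x@sequences
}

#' @export
setMethod("length", "PromoterSet", function(x) nrow(x@info))

#' @export
setMethod("names", "PromoterSet", function(x) x@info$accession)

# ---- show methods -------------------------------------------------------

#' @export
setMethod("show", "PFM", function(object) {
  cat(sprintf("PFM %s%s: L=%d, total counts per column %s\n",
              object@id,
              if (nzchar(object@name)) paste0(" (", object@name, ")") else "",
              ncol(object@counts),
              paste(signif(range(colSums(object@counts)), 4), collapse = "-")))
})

#' @export
setMethod("show", "ScoreModel", function(object) {
  cat(sprintf("ScoreModel %s: L=%d, score range [%.4f, %.4f] nats\n",
              object@id, ncol(object@weights), object@sMin, object@sMax))
})

#' @export
setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf(
    "ScoreDistribution %s: granularity %g, %d grid bins [%d, %d]\n",
    object@modelId, object@granularity, length(object@pmf),
    object@gridMin, object@gridMin + length(object@pmf) - 1L))
})

#' @export
setMethod("show", "CalibratedModel", function(object) {
  cat(sprintf("CalibratedModel %s: L=%d, p_min = %.6g\n",
              object@model@id, ncol(object@model@weights), object@pMin))
})

#' @export
setMethod("show", "PromoterSet", function(object) {
  cat(sprintf("PromoterSet (%s): %d promoters", object@genomeId,
              nrow(object@info)))
  if (nrow(object@info)) {
    cat(sprintf(", flank %s, %d clipped",
                paste(unique(object@info$flank), collapse = "/"),
                sum(object@info$clipped)))
  }
  cat("\n")
})

#' @export
setMethod("show", "AnnotationStore", function(object) {
  cat(sprintf("AnnotationStore: %d genome(s), %d feature(s)\n",
              length(object@promoters), length(object@features)))
  for (g in names(object@promoters)) {
    cat(sprintf("  %s: %d promoters, %d hits\n", g,
                nrow(object@promoters[[g]]@info), nrow(object@hits[[g]])))
  }
})
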