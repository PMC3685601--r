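# Exact score-distribution calibration: the null distribution of the window
# score is computed by column-wise convolution on an integer grid, giving
# exact p-values for the discretized model (Staden-style dynamic program).

#' Exact null distribution of a model's score
#'
#' Weights are scaled by \code{granularity} grid units per nat and rounded
#' half-up to integers; the distribution of the window score under the
#' background is then the L-fold convolution of the per-column score
#' distributions: \eqn{D_i(t) = \sum_a b_a D_{i-1}(t - \delta_{a,i})}.
#' The survival function is the reverse cumulative sum of the pmf.
#'
#' @param model a non-degenerate \linkS4class{ScoreModel}.
#' @param granularity grid units per nat; default \code{1e4}, at which the
#'   discretization error of p-values is negligible for motif-length models.
#' @return a \linkS4class{ScoreDistribution}.
#' @export
scoreDistribution <- function(model, granularity = 1e4) {
  stopifnot(is(model, "ScoreModel"))
  if (length(granularity) != 1L || granularity <= 0)
    stop("granularity must be a single positive number")
  delta <- roundHalfUp(model@weights * granularity)  # 4 x L integer deltas
  b <- model@background
  pmf <- 1
  gmin <- 0
  for (i in seq_len(ncol(delta))) {
    d <- delta[, i]
    dmin <- min(d)
    new <- numeric(length(pmf) + (max(d) - dmin))
    for (a in 1:4) {
      off <- d[a] - dmin
      idx <- seq.int(off + 1L, off + length(pmf))
      new[idx] <- new[idx] + b[a] * pmf
    }
    pmf <- new
    gmin <- gmin + dmin
  }
  sf <- rev(cumsum(rev(pmf)))
  sf[1] <- 1  # exact by construction; pin down float error
  new("ScoreDistribution", modelId = model@id, granularity = granularity,
      gridMin = as.integer(gmin), L = ncol(delta), pmf = pmf, sf = sf)
}

#' Calibrate a scoring model to exact p-values
#'
#' @param model a \linkS4class{ScoreModel}.
#' @param granularity grid units per nat.
#' @return a \linkS4class{CalibratedModel} with the distribution and the
#'   smallest reachable p-value (p-value of the maximum score).
#' @export
calibrateModel <- function(model, granularity = 1e4) {
  d <- scoreDistribution(model, granularity)
  new("CalibratedModel", model = model, dist = d, pMin = d@sf[length(d@sf)])
}

#' Read, regularize and calibrate a motif collection in one step
#'
#' Convenience pipeline: \code{\link{toFrequencies}} then
#' \code{\link{buildScoreModel}} then \code{\link{calibrateModel}} for each
#' PFM.
#'
#' @param pfms list of \linkS4class{PFM} (e.g. from \code{\link{readJaspar}}).
#' @param pseudocount passed to \code{\link{toFrequencies}}.
#' @param background passed to \code{\link{buildScoreModel}}.
#' @param granularity passed to \code{\link{calibrateModel}}.
#' @return named list of \linkS4class{CalibratedModel} (names = motif ids).
#' @export
calibrateMotifs <- function(pfms, pseudocount = 0.8,
                            background = uniformBackground(),
                            granularity = 1e4) {
  out <- lapply(pfms, function(p)
    calibrateModel(buildScoreModel(toFrequencies(p, pseudocount), background),
                   granularity))
  names(out) <- vapply(pfms, motifId, character(1))
  out
}

#' p-value of a raw score
#'
#' \eqn{P(\mathrm{score} \ge s)} under the background, evaluated on the
#' integer grid (\code{s * granularity} rounded half-up). Scores at or
#' below the grid minimum give 1. A raw score is a sum of L unrounded
#' weights, so its rounded value can overshoot the grid maximum (a sum of
#' L rounded weights) by up to L/2 grid units; overshoot within that
#' tolerance is clamped to the top bin (the model's minimum p-value), and
#' only scores beyond it -- genuinely unreachable -- give 0.
#'
#' @param dist a \linkS4class{ScoreDistribution} (or
#'   \linkS4class{CalibratedModel}).
#' @param s raw score(s) in nats; vectorized.
#' @return probabilities in [0, 1]; NA scores give NA.
#' @export
pvalueOfScore <- function(dist, s) {
  if (is(dist, "CalibratedModel")) dist <- dist@dist
  stopifnot(is(dist, "ScoreDistribution"))
  k <- roundHalfUp(s * dist@granularity)
  idx <- k - dist@gridMin + 1
  n <- length(dist@sf)
  slack <- ceiling(dist@L / 2)
  p <- rep(NA_real_, length(s))
  ok <- !is.na(idx)
  idx[ok & idx > n & idx <= n + slack] <- n
  lo <- ok & idx <= 1
  hi <- ok & idx > n
  mid <- ok & !lo & !hi
  p[lo] <- 1
  p[hi] <- 0
  p[mid] <- dist@sf[idx[mid]]
  p
}

#' Score threshold for a p-value cutoff
#'
#' The smallest grid score whose p-value is strictly below the cutoff (a
#' hit is a window with p-value smaller than the cutoff). When even the
#' maximum score cannot go below the cutoff (\code{pMin(calib) >= pCutoff})
#' the cutoff is unreachable and \code{NA} is returned.
#'
#' @param calib a \linkS4class{CalibratedModel}.
#' @param pCutoff probability in (0, 1].
#' @return raw score in nats, or \code{NA_real_} when unreachable.
#' @export
scoreThreshold <- function(calib, pCutoff) {
  stopifnot(is(calib, "CalibratedModel"))
  if (length(pCutoff) != 1L || pCutoff <= 0 || pCutoff > 1)
    stop("pCutoff must lie in (0, 1]")
  d <- calib@dist
  i <- which(d@sf < pCutoff)
  if (!length(i)) return(NA_real_)
  (d@gridMin + i[1] - 1) / d@granularity
}

#' Table of minimum reachable p-values
#'
#' One row per model, sorted by \code{p_min} ascending: which models can
#' still produce hits as the cutoff tightens.
#'
#' @param calibs list of \linkS4class{CalibratedModel}.
#' @return data.frame with columns \code{model_id}, \code{p_min}.
#' @export
minPvalueTable <- function(calibs) {
  if (!length(calibs))
    return(data.frame(model_id = character(0), p_min = numeric(0)))
  df <- data.frame(model_id = vapply(calibs, motifId, character(1)),
                   p_min = vapply(calibs, pMin, numeric(1)),
                   row.names = NULL)
  df[order(df$p_min, df$model_id), , drop = FALSE]
}

#' Write a minimum-p-value table as tab-delimited text
#'
#' p-values are written in scientific notation with 6 significant digits.
#'
#' @param tbl data.frame from \code{\link{minPvalueTable}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMinPvalueTable <- function(tbl, path) {
  out <- data.frame(model_id = tbl$model_id,
                    p_min = sprintf("%.5e", tbl$p_min))
  writeTsv(out, path)
}

#' Normalize a raw score to the 0-100 scale
#'
#' Linear rescaling with 100 at the model's maximum reachable score and 0
#' at its minimum: \eqn{100 (s - s_{min}) / (s_{max} - s_{min})}.
#'
#' @param model a \linkS4class{ScoreModel} or \linkS4class{CalibratedModel}.
#' @param s raw score(s) within \code{[scoreMin, scoreMax]}; vectorized.
#' @return numbers in [0, 100].
#' @export
normalizeScore <- function(model, s) {
  if (is(model, "CalibratedModel")) model <- model@model
  stopifnot(is(model, "ScoreModel"))
  eps <- 1e-9 * max(1, abs(model@sMax), abs(model@sMin))
  bad <- !is.na(s) & (s < model@sMin - eps | s > model@sMax + eps)
  if (any(bad))
    stop("score outside the reachable range [",
         format(model@sMin), ", ", format(model@sMax), "]")
  pmin(100, pmax(0, 100 * (s - model@sMin) / (model@sMax - model@sMin)))
}
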