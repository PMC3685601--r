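# Sliding-window scanner: calibrated models over promoter sequences on both
# strands, emitting hits with p-value strictly below a cutoff.

# Forward-strand window scores along an integer-coded sequence. `weights`
# is any 4 x L matrix: the model's exact weights for raw scores, or the
# rounded integer deltas the calibration grid uses, so that window p-values
# are exact lookups into the survival function rather than re-rounded
# sums. Windows containing any non-ACGT base score NA ("no score").
.slideScores <- function(weights, code) {
  L <- ncol(weights)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  for (i in seq_len(L)) {
    s <- s + weights[, i][code[i:(i + nw - 1L)]]
  }
  s
}

#' Score one window under a model
#'
#' The log-likelihood-ratio score \eqn{S = \sum_i w_{s_i,i}} of a DNA window
#' of exactly the model's length. Windows containing any base outside
#' A,C,G,T have no defensible likelihood under the model and return
#' \code{NA} (skipped by the scanner).
#'
#' @param model a \linkS4class{ScoreModel} or \linkS4class{CalibratedModel}.
#' @param window character string of length L (alphabet A,C,G,T,N).
#' @return raw score in nats, or \code{NA_real_}.
#' @export
scoreWindow <- function(model, window) {
  if (is(model, "CalibratedModel")) model <- model@model
  stopifnot(is(model, "ScoreModel"))
  code <- encodeDNA(window)
  if (length(code) != ncol(model@weights))
    stop("window length ", length(code), " does not match model length ",
         ncol(model@weights))
  if (anyNA(code)) return(NA_real_)
  sum(model@weights[cbind(code, seq_along(code))])
}

.emptyHits <- function(withAccession = FALSE) {
  df <- data.frame(feature_id = character(0), strand = character(0),
                   start_rel = integer(0), width = integer(0),
                   raw_score = numeric(0), norm_score = numeric(0),
                   p_value = numeric(0))
  if (withAccession)
    df <- cbind(data.frame(accession = character(0),
                           start_anchor = integer(0)), df)
  df
}

# All scoreable windows of one sequence with their p-values; used both by
# the cutoff filter and by cutoff sweeps that re-threshold a single scan.
# Raw scores are exact weight sums; p-values come from integer scores on
# the calibration grid (same rounded weights as the DP), so every window's
# p-value is the exact discretized tail probability.
.scanAll <- function(calib, seq, strands = "both") {
  model <- calib@model
  dist <- calib@dist
  L <- ncol(model@weights)
  delta <- roundHalfUp(model@weights * dist@granularity)
  seq <- as.character(seq)
  n <- nchar(seq)
  code <- encodeDNA(seq)
  pOf <- function(sInt) dist@sf[as.integer(sInt) - dist@gridMin + 1L]
  res <- list()
  sF <- .slideScores(model@weights, code)
  okF <- which(!is.na(sF))
  if (length(okF)) {
    kF <- .slideScores(delta, code)
    res$f <- data.frame(strand = "+", start_rel = okF - 1L,
                        raw_score = sF[okF], p_value = pOf(kF[okF]))
  }
  if (strands == "both") {
    rcCode <- encodeDNA(as.character(reverseComplement(DNAString(seq))))
    sR <- .slideScores(model@weights, rcCode)
    okR <- which(!is.na(sR))
    if (length(okR)) {
      kR <- .slideScores(delta, rcCode)
      # hit anchored at the leftmost forward-strand base it covers
      res$r <- data.frame(strand = "-", start_rel = n - L - (okR - 1L),
                          raw_score = sR[okR], p_value = pOf(kR[okR]))
    }
  }
  if (!length(res)) {
    return(data.frame(strand = character(0), start_rel = integer(0),
                      raw_score = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, res)
}

#' Scan one sequence with a calibrated model
#'
#' Slides the model over every window of the sequence; on the reverse
#' strand the model is applied to the reverse complement and the hit is
#' reported at the leftmost forward-strand base of the covered interval
#' with strand \code{"-"}. A window is a hit when its exact p-value is
#' strictly below \code{pCutoff} (with \code{pCutoff >= 1}, every scoreable
#' window is reported -- the no-cutoff baseline).
#'
#' @param calib a \linkS4class{CalibratedModel}.
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param pCutoff p-value cutoff, default \code{1e-4}.
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return data.frame of hits with columns \code{feature_id},
#'   \code{strand}, \code{start_rel} (0-based leftmost base),
#'   \code{width}, \code{raw_score}, \code{norm_score}, \code{p_value},
#'   sorted by \code{start_rel} then strand. Sequences shorter than the
#'   model give an empty table.
#' @export
scanSequence <- function(calib, seq, pCutoff = 1e-4,
                         strands = c("both", "forward")) {
  stopifnot(is(calib, "CalibratedModel"))
  strands <- match.arg(strands)
  if (length(pCutoff) != 1L || pCutoff <= 0)
    stop("pCutoff must be a single positive probability")
  df <- .scanAll(calib, seq, strands)
  keep <- if (pCutoff >= 1) rep(TRUE, nrow(df)) else df$p_value < pCutoff
  df <- df[keep, , drop = FALSE]
  model <- calib@model
  out <- data.frame(feature_id = rep(model@id, nrow(df)),
                    strand = df$strand,
                    start_rel = df$start_rel,
                    width = rep(ncol(model@weights), nrow(df)),
                    raw_score = df$raw_score,
                    norm_score = if (nrow(df)) normalizeScore(model, df$raw_score) else numeric(0),
                    p_value = df$p_value)
  out <- out[order(out$start_rel, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter set with a motif collection
#'
#' Runs \code{\link{scanSequence}} over the cross product of promoters and
#' calibrated models and fills in promoter accessions and anchor-relative
#' coordinates (\code{start_anchor}; negative = upstream of the TSS/CSS
#' anchor). Output order is deterministic: promoter, feature, start, strand.
#'
#' @param calibs list of \linkS4class{CalibratedModel}.
#' @param promoters a \linkS4class{PromoterSet}.
#' @param pCutoff p-value cutoff, default \code{1e-4}.
#' @param strands \code{"both"} or \code{"forward"}.
#' @return hit data.frame with columns \code{accession},
#'   \code{start_anchor}, \code{feature_id}, \code{strand},
#'   \code{start_rel}, \code{width}, \code{raw_score}, \code{norm_score},
#'   \code{p_value}.
#' @export
scanPromoterSet <- function(calibs, promoters, pCutoff = 1e-4,
                            strands = c("both", "forward")) {
  stopifnot(is(promoters, "PromoterSet"))
  strands <- match.arg(strands)
  info <- promoters@info
  if (anyDuplicated(info$accession))
    stop("duplicate promoter accessions")
  seqs <- as.character(promoters@sequences)
  pieces <- list()
  for (j in seq_len(nrow(info))) {
    for (calib in calibs) {
      h <- scanSequence(calib, seqs[[j]], pCutoff, strands)
      if (!nrow(h)) next
      h$accession <- info$accession[j]
      h$start_anchor <- .anchorRel(info[j, ], h$start_rel)
      pieces[[length(pieces) + 1L]] <- h
    }
  }
  if (!length(pieces)) return(.emptyHits(withAccession = TRUE))
  out <- do.call(rbind, pieces)
  out <- out[, c("accession", "start_anchor", "feature_id", "strand",
                 "start_rel", "width", "raw_score", "norm_score", "p_value")]
  out <- out[order(match(out$accession, info$accession),
                   match(out$feature_id,
                         vapply(calibs, motifId, character(1))),
                   out$start_rel, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits as BED6
#'
#' One line per hit: chrom = promoter accession, 0-based half-open
#' interval in promoter coordinates, name = feature id, score = normalized
#' score rounded to integer, strand.
#'
#' @param hits hit data.frame from \code{\link{scanPromoterSet}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeHitsBed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   hits$accession, hits$start_rel,
                   hits$start_rel + hits$width, hits$feature_id,
                   as.integer(round(hits$norm_score)), hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a hit table as CSV
#'
#' Plain CSV round-trip of the scanner's hit table (used by the
#' command-line workflow to feed stored hits back into queries).
#'
#' @param hits hit data.frame.
#' @param path file path.
#' @return \code{readHitsCsv} returns the hit data.frame.
#' @export
writeHitsCsv <- function(hits, path) {
  write.csv(hits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHitsCsv
#' @export
readHitsCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "start_anchor", "feature_id", "strand",
            "start_rel", "width", "raw_score", "norm_score", "p_value")
  if (!all(need %in% names(df)))
    stop("hit CSV lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df[, need]
}
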