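# Reading, validating and transforming position frequency matrices.

#' Read position frequency matrices in JASPAR raw-count format
#'
#' Parses the plain-text JASPAR dialect: a header line starting with
#' \code{">"} (\code{>ID name}) followed by four count rows, either bare
#' numbers or labelled \code{A [ 3 1 0 ]} style. When row labels are present
#' they are honored (rows may appear in any order); unlabelled rows are
#' assumed to be in A,C,G,T order. Rows are normalized to A,C,G,T in the
#' returned objects.
#'
#' @param path path to a motif file.
#' @return list of \linkS4class{PFM} objects (empty list for an empty file).
#' @examples
#' tf <- tempfile(fileext = ".jaspar")
#' writeLines(c(">M1 test", "4 0", "0 4", "0 0", "0 0"), tf)
#' readJaspar(tf)
#' @export
readJaspar <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) {
    if (all(!nzchar(trimws(lines)))) return(list())
    stop("malformed motif file (no '>' header found): ", path)
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    h <- sub("^>\\s*", "", lines[hdr[k]])
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    id <- if (length(toks)) toks[1] else ""
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    body <- lines[seq(hdr[k] + 1L, length.out = max(0L, ends[k] - hdr[k]))]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 4L)
      stop(sprintf("record '%s' near line %d: expected 4 count rows, got %d",
                   id, hdr[k], length(body)))
    body <- body[1:4]
    labels <- character(4)
    rows <- vector("list", 4)
    for (j in 1:4) {
      ln <- trimws(body[j])
      m <- regmatches(ln, regexec("^([ACGTacgt])\\s*[:\\[]?\\s*(.*)$", ln))[[1]]
      if (length(m) == 3 && m[2] %in% c(DNA_BASES4, tolower(DNA_BASES4))) {
        labels[j] <- toupper(m[2])
        ln <- m[3]
      }
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[\\s,]+",
                                                   perl = TRUE)[[1]]))
      if (!length(vals) || anyNA(vals))
        stop(sprintf("record '%s' line %d: cannot parse counts", id,
                     hdr[k] + j))
      if (any(vals < 0))
        stop(sprintf("record '%s' line %d: negative count", id, hdr[k] + j))
      rows[[j]] <- vals
    }
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop(sprintf("record '%s' near line %d: rows of unequal length (%s)",
                   id, hdr[k], paste(lens, collapse = ",")))
    m <- do.call(rbind, rows)
    if (all(nzchar(labels))) {
      if (anyDuplicated(labels))
        stop(sprintf("record '%s': duplicated row label", id))
      m <- m[match(DNA_BASES4, labels), , drop = FALSE]
    } else if (any(nzchar(labels))) {
      stop(sprintf("record '%s': mixture of labelled and unlabelled rows", id))
    }
    rownames(m) <- DNA_BASES4
    out[[k]] <- new("PFM", id = id, name = name, counts = m)
  }
  out
}

#' Write PFMs in the JASPAR raw-count dialect
#'
#' @param pfms list of \linkS4class{PFM} objects.
#' @param path output file.
#' @param labels write \code{A [ ... ]}-style row labels (default) or bare
#'   rows.
#' @return invisibly, \code{path}.
#' @export
writeJaspar <- function(pfms, path, labels = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    hdr <- paste0(">", p@id, if (nzchar(p@name)) paste0(" ", p@name) else "")
    writeLines(hdr, con)
    for (a in DNA_BASES4) {
      row <- paste(format(p@counts[a, ], trim = TRUE), collapse = " ")
      writeLines(if (labels) sprintf("%s [ %s ]", a, row) else row, con)
    }
  }
  invisible(path)
}

#' Uniform background base distribution
#'
#' The default null model: \eqn{b_A = b_C = b_G = b_T = 0.25}.
#'
#' @return named probability vector.
#' @export
uniformBackground <- function() {
  setNames(rep(0.25, 4), DNA_BASES4)
}

#' Convert counts to column probabilities
#'
#' \eqn{f_{a,i} = (n_{a,i} + p \cdot 0.25) / (N_i + p)} where \eqn{N_i} is
#' the column total and \eqn{p} the pseudocount, distributed according to a
#' uniform reference composition. With \code{pseudocount = 0} the raw
#' relative frequencies are returned (zero cells then make the model
#' unbuildable, see \code{\link{buildScoreModel}}).
#'
#' @param pfm a \linkS4class{PFM}.
#' @param pseudocount non-negative regularizer; default 0.8.
#' @return a \linkS4class{FrequencyMatrix}.
#' @examples
#' p <- new("PFM", id = "M", name = "", counts = matrix(
#'   c(3, 1, 0, 0), 4, 1, dimnames = list(c("A","C","G","T"), NULL)))
#' frequencyMatrix(toFrequencies(p, 0.8))  # (3.2, 1.2, 0.2, 0.2) / 4.8
#' @export
toFrequencies <- function(pfm, pseudocount = 0.8) {
  stopifnot(is(pfm, "PFM"))
  if (length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  tot <- colSums(pfm@counts)
  denom <- tot + pseudocount
  if (any(denom == 0)) stop("column total plus pseudocount is zero")
  f <- sweep(pfm@counts + pseudocount * 0.25, 2, denom, "/")
  # guard against accumulated float error in the column sums
  f <- sweep(f, 2, colSums(f), "/")
  new("FrequencyMatrix", id = pfm@id, f = f, pseudocount = pseudocount)
}

#' Build a log-likelihood-ratio scoring model
#'
#' \eqn{w_{a,i} = \ln(f_{a,i} / b_a)}. All frequencies must be strictly
#' positive (use a pseudocount); a model whose columns are all uniform
#' relative to the background has no score range and is rejected.
#'
#' @param freq a \linkS4class{FrequencyMatrix}.
#' @param background length-4 probability vector; default uniform.
#' @return a \linkS4class{ScoreModel}.
#' @export
buildScoreModel <- function(freq, background = uniformBackground()) {
  stopifnot(is(freq, "FrequencyMatrix"))
  b <- unname(background)
  if (length(b) != 4L || any(b <= 0) || abs(sum(b) - 1) > 1e-12)
    stop("background must be 4 positive probabilities summing to 1")
  if (any(freq@f == 0))
    stop("non-finite weight: zero frequency at pseudocount ",
         freq@pseudocount, " (motif ", freq@id, ")")
  w <- log(freq@f / b)
  rownames(w) <- DNA_BASES4
  sMax <- sum(apply(w, 2, max))
  sMin <- sum(apply(w, 2, min))
  if (sMax - sMin < 1e-12)
    stop("degenerate model: all columns uniform under the background (motif ",
         freq@id, ")")
  new("ScoreModel", id = freq@id, weights = w,
      background = setNames(b, DNA_BASES4), sMin = sMin, sMax = sMax)
}

#' GC content of a motif
#'
#' Mean over columns of \eqn{f_{C,i} + f_{G,i}}.
#'
#' @param freq a \linkS4class{FrequencyMatrix}.
#' @return fraction in [0, 1].
#' @export
pfmGCContent <- function(freq) {
  stopifnot(is(freq, "FrequencyMatrix"))
  mean(freq@f["C", ] + freq@f["G", ])
}

#' Consensus word of a motif
#'
#' The word formed by the per-column argmax (ties broken towards A<C<G<T).
#'
#' @param x a \linkS4class{PFM}, \linkS4class{FrequencyMatrix},
#'   \linkS4class{ScoreModel} or \linkS4class{CalibratedModel}.
#' @return DNA string of length L.
#' @export
consensusWord <- function(x) {
  m <- if (is(x, "PFM")) x@counts
       else if (is(x, "FrequencyMatrix")) x@f
       else weightMatrix(x)
  paste(DNA_BASES4[apply(m, 2, which.max)], collapse = "")
}
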