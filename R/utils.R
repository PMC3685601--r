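# Shared helpers: deterministic rounding, seed management, small parsers.

#' Round half away from zero upwards
#'
#' Rounds to the nearest integer with ties going up (towards +Inf), the
#' convention used when scaling score weights onto the integer p-value grid.
#' Base \code{round()} rounds half to even and is not suitable there.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @examples
#' roundHalfUp(c(0.5, 1.5, -0.5, -1.5))  # 1 2 0 -1
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

#' Strip a trailing RefSeq-style version suffix
#'
#' @param x character vector of accessions, e.g. \code{"NM_000001.2"}.
#' @return accessions without the \code{".<digits>"} suffix.
#' @examples
#' stripVersion("NM_000001.2")
#' @export
stripVersion <- function(x) sub("\\.[0-9]+$", "", x)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All package randomness flows through this.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fan one parent seed out into n reproducible child seeds (< 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Integer-coded DNA: A=1, C=2, G=3, T=4, anything else NA.
.dnaLut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

encodeDNA <- function(seq) {
  v <- utf8ToInt(as.character(seq))
  v[v > 127L | v < 1L] <- 1L  # map exotic bytes onto an NA slot safely
  out <- .dnaLut[v]
  out
}

DNA_BASES4 <- c("A", "C", "G", "T")

# Write a data.frame as plain tab-delimited text (header, no quoting).
#' Write a table as tab-delimited text
#'
#' Used for profiles, sweep tables and enrichment results.
#'
#' @param x data.frame.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
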