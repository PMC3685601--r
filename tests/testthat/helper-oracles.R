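# Independent oracles: exhaustive enumeration over all 4^L words, and a
# nested-loop pair counter. These never call the code paths they check.

# Enumerate the scores of every word. `weights` may be the exact weight
# matrix (continuous oracle) or pre-rounded integer deltas (grid oracle).
enumWordScores <- function(weights, background) {
  s <- 0
  pr <- 1
  for (i in seq_len(ncol(weights))) {
    s <- as.vector(outer(s, weights[, i], "+"))
    pr <- as.vector(outer(pr, background, "*"))
  }
  list(score = s, prob = pr)
}

# Tail probability P(score >= t) from an enumeration.
enumTail <- function(enum, t) {
  vapply(t, function(tt) sum(enum$prob[enum$score >= tt]), numeric(1))
}

# Enumeration on the same integer grid the DP uses (weights scaled by
# granularity, rounded half-up), via direct summation per word.
enumGridScores <- function(model, granularity) {
  enumWordScores(floor(weightMatrix(model) * granularity + 0.5),
                 modelBackground(model))
}

# Brute-force pair counting: plain double loop over all hit index pairs,
# deciding upstream/downstream per pair without sorting.
bruteForcePairs <- function(hits, minSep, maxSep) {
  n <- nrow(hits)
  keys <- character(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        si <- hits$start_rel[i]; sj <- hits$start_rel[j]
        ei <- si + hits$width[i]; ej <- sj + hits$width[j]
        gap <- if (si <= sj) sj - ei else si - ej
        if (gap >= minSep && gap <= maxSep) {
          fs <- sort(c(hits$feature_id[i], hits$feature_id[j]))
          keys <- c(keys, paste(fs[1], fs[2], sep = "|"))
        }
      }
    }
  }
  if (!length(keys)) return(setNames(integer(0), character(0)))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

expect_same_pair_counts <- function(a, b) {
  keys <- sort(union(names(a), names(b)))
  av <- setNames(rep(0L, length(keys)), keys)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  expect_identical(av, bv)
}
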