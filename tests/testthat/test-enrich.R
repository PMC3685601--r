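# Over-representation: means, ratios, bootstrap intervals, pair counting.

enrichFixture <- function(nGenes = 8, seed = 201) {
  fx <- sparsePromoterFixture(nGenes, flank = 300, seed = seed)
  acc <- names(fx$promoters)
  # plant known counts: gene j gets j-1 hits of TF1
  rows <- do.call(rbind, lapply(seq_along(acc), function(j) {
    if (j == 1) return(NULL)
    mkHits(acc[j], "TF1", seq(0L, by = 60L, length.out = j - 1L))
  }))
  st <- buildStore(list(A = fx$promoters), list(A = rows))
  list(store = st, acc = acc)
}

test_that("mean occurrence counts hits per resolved gene", {
  ef <- enrichFixture()
  mo <- meanOccurrence(ef$store, "A", ef$acc[1:3], features = "TF1")
  expect_equal(unname(mo$mean), mean(c(0, 1, 2)))
  expect_equal(unname(mo$counts[, "TF1"]), c(0, 1, 2))
  # zero-hit set
  mo0 <- meanOccurrence(ef$store, "A", ef$acc[1], features = "TF1")
  expect_equal(unname(mo0$mean), 0)
  # missing accessions are dropped with a message, resolved count logged
  expect_message(
    mo2 <- meanOccurrence(ef$store, "A", c(ef$acc[1:3], "NM_9999"),
                          features = "TF1"),
    "dropped")
  expect_identical(mo2$nResolved, 3L)
  expect_identical(mo2$nDropped, 1L)
  expect_error(suppressMessages(meanOccurrence(ef$store, "A", "NM_9999")),
               "no gene")
})

test_that("identical sets give unit ratios; undefined ratios are flagged", {
  ef <- enrichFixture()
  res <- overrepRatios(ef$store, "A", ef$acc, ef$acc, nBoot = 50, seed = 4)
  expect_equal(res$ratio, 1)
  expect_false(any(res$ratio_undefined))
  # feature present only in the positive set: flagged, ranked last
  pos <- ef$acc[5:8]
  neg <- ef$acc[1]   # zero TF1 hits
  res2 <- overrepRatios(ef$store, "A", pos, neg, nBoot = 50, seed = 4)
  expect_true(res2$ratio_undefined[nrow(res2)])
  expect_true(is.na(res2$ratio[nrow(res2)]))
})

test_that("duplicating every gene leaves means and ratios unchanged", {
  ef <- enrichFixture()
  pos <- ef$acc[5:8]
  neg <- ef$acc[2:4]
  r1 <- overrepRatios(ef$store, "A", pos, neg, nBoot = 20, seed = 7)
  r2 <- overrepRatios(ef$store, "A", rep(pos, 2), rep(neg, 2), nBoot = 20,
                      seed = 7)
  expect_equal(r1$pos_mean, r2$pos_mean)
  expect_equal(r1$neg_mean, r2$neg_mean)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("percentile bootstrap is deterministic, centered and calibrated", {
  expect_equal(unname(bootstrapCI(c(2, 2, 2, 2), nBoot = 100, seed = 1)),
               c(2, 2))
  x <- c(0, 1, 1, 2, 3, 5, 0, 2)
  ci1 <- bootstrapCI(x, nBoot = 500, seed = 42)
  ci2 <- bootstrapCI(x, nBoot = 500, seed = 42)
  expect_identical(ci1, ci2)
  # the sample mean lies inside its own interval
  expect_true(ci1[["lower"]] <= mean(x) && mean(x) <= ci1[["upper"]])
  # coverage of the true mean under a Poisson law: ~95% over replicates
  nRep <- 500
  lam <- 2
  seeds <- promscan:::childSeeds(77, nRep)
  covered <- vapply(seq_len(nRep), function(r) {
    y <- promscan:::withSeed(seeds[r], rpois(30, lam))
    ci <- bootstrapCI(y, nBoot = 200, seed = seeds[r] + 1)
    ci[["lower"]] <= lam && lam <= ci[["upper"]]
  }, logical(1))
  se <- sqrt(0.95 * 0.05 / nRep)
  expect_lt(abs(mean(covered) - 0.95), 3 * se + 0.02)
})

test_that("pair gaps honor inclusive boundaries and self-pairs", {
  # two hits with controllable gap: end of first = 18
  gapHits <- function(gap) mkHits("g", c("X", "Y"), c(10L, 18L + gap))
  expect_length(countHitPairs(gapHits(9)), 0)
  expect_identical(unname(countHitPairs(gapHits(10))), 1L)
  expect_identical(unname(countHitPairs(gapHits(100))), 1L)
  expect_length(countHitPairs(gapHits(101)), 0)
  expect_length(countHitPairs(mkHits("g", "X", 10L)), 0)
  # overlapping hits never pair
  expect_length(countHitPairs(mkHits("g", c("X", "Y"), c(10L, 12L))), 0)
  # three mutually in-range hits of one feature: 3 self-pairs
  three <- mkHits("g", "X", c(0L, 30L, 60L), width = 5L)
  expect_identical(unname(countHitPairs(three, 10, 100)), 3L)
  expect_identical(names(countHitPairs(three, 10, 100)), "X|X")
  expect_error(countHitPairs(three, 50, 10), "minSep")
})

test_that("pair counting matches a brute-force double loop", {
  seeds <- promscan:::childSeeds(303, 200)
  for (k in seq_len(200)) {
    n <- 2 + (seeds[k] %% 7)
    hits <- promscan:::withSeed(seeds[k], mkHits(
      "g", sample(c("A", "B", "C"), n, replace = TRUE),
      sort(sample.int(400L, n)), width = sample(4:12, n, replace = TRUE)))
    expect_same_pair_counts(countHitPairs(hits, 10, 100),
                            bruteForcePairs(hits, 10, 100))
  }
})

test_that("pair over-representation ranks planted co-occurrence first", {
  fx <- sparsePromoterFixture(6, flank = 300, seed = 211)
  acc <- names(fx$promoters)
  pos <- acc[1:3]
  neg <- acc[4:6]
  # E2F-like pair planted in positives with gap 40; negatives carry the
  # same features far apart
  rows <- rbind(mkHits(pos, "TFa", 100L),
                mkHits(pos, "TFb", 148L),
                mkHits(neg, "TFa", 100L),
                mkHits(neg, "TFb", 500L))
  st <- buildStore(list(A = fx$promoters), list(A = rows))
  res <- pairOverrep(st, "A", pos, neg, 10, 100)
  expect_identical(res$pair[1], "TFa|TFb")
  expect_true(res$ratio_undefined[1])   # absent from negatives entirely
  expect_equal(res$pos_mean[1], 1)
  # symmetric in feature order by construction of the key
  res2 <- pairOverrep(st, "A", pos, neg, 10, 100)
  expect_identical(res$pair, res2$pair)
  # no negative-set pairs anywhere: all ratios undefined
  expect_true(all(res$ratio_undefined | res$neg_mean > 0))
})
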