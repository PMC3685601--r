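# Layered store, two-step queries, homology filter, accession matching,
# CSV export.

storeFixture <- function() {
  fx <- sparsePromoterFixture(5, flank = 300, seed = 101)
  acc <- names(fx$promoters)
  hits <- rbind(mkHits(acc[1:3], "TF1", c(10L, 40L, 80L)),
                mkHits(acc[c(1, 4)], "TF2", c(200L, 220L)),
                mkHits(acc[1], "TF1", 120L))
  list(fx = fx, acc = acc,
       store = buildStore(list(A = fx$promoters), list(A = hits)),
       hits = hits)
}

test_that("layers union and collisions are policed", {
  fx <- sparsePromoterFixture(3, flank = 200, seed = 31)
  acc <- names(fx$promoters)
  defHits <- mkHits(acc[1], "TF1", 10L)
  usrHits <- mkHits(acc[1], "TF2", 50L)
  st <- buildStore(list(A = list(default = fx$promoters)),
                   list(A = list(default = defHits, user = usrHits)))
  h <- hitsForGene(st, "A", acc[1])
  expect_identical(sort(unique(h$feature_id)), c("TF1", "TF2"))
  expect_identical(sort(unique(h$layer)), c("default", "user"))
  # user promoters with novel accessions are visible in the view
  g2 <- makeGenome(3000, seed = 77, chromNames = "chr1")
  usrGenes <- data.frame(accession = "USR_1", symbol = "", chrom = "chr1",
                         strand = "+", tss = 1500L, css = 1600L)
  usrProm <- extractPromoters(g2, usrGenes, 200, genomeId = "A")
  st2 <- buildStore(list(A = list(default = fx$promoters,
                                  user = usrProm)), list(A = defHits))
  expect_true("USR_1" %in% names(storePromoters(st2, "A")))
  # same accession with different coordinates collides
  clashGenes <- fx$genes[1, ]
  clashGenes$tss <- clashGenes$tss + 50L
  clash <- extractPromoters(fx$genome, clashGenes, 200, genomeId = "A")
  expect_error(buildStore(list(A = list(default = fx$promoters,
                                        user = clash))), "collision")
  # hits must reference known promoters
  expect_error(buildStore(list(A = fx$promoters),
                          list(A = mkHits("NOPE", "TF1", 1L))),
               "unknown promoters")
})

test_that("queryGenes implements AND/OR over count-thresholded terms", {
  sf <- storeFixture()
  st <- sf$store
  expect_identical(queryGenes(st, "A", featureTerm("TF1")), sf$acc[1:3])
  expect_identical(queryGenes(st, "A", featureTerm("TF1", minCount = 2)),
                   sf$acc[1])
  expect_identical(queryGenes(st, "A", featureAnd(featureTerm("TF1"),
                                                  featureTerm("TF2"))),
                   sf$acc[1])
  expect_identical(queryGenes(st, "A", featureOr(featureTerm("TF1"),
                                                 featureTerm("TF2"))),
                   sort(sf$acc[1:4]))
  # OR with itself is idempotent
  expect_identical(queryGenes(st, "A", featureOr(featureTerm("TF2"),
                                                 featureTerm("TF2"))),
                   queryGenes(st, "A", featureTerm("TF2")))
  # AND of never co-occurring features is empty
  expect_identical(queryGenes(st, "A", featureAnd(featureTerm("TF1", 2),
                                                  featureTerm("TF2", 2))),
                   character(0))
  expect_error(queryGenes(st, "A", featureTerm("NOSUCH")), "unknown feature")
  expect_error(queryGenes(st, "Z", featureTerm("TF1")), "unknown genome")
  # pair terms respect the separation window: on gene 1, TF1@120 (end 128)
  # and TF2@200 have gap 72, inside [10, 100]; the two TF1 hits have gap
  # 102, outside it
  expect_identical(queryGenes(st, "A", featurePair("TF1", "TF2", 10, 100)),
                   sf$acc[1])
  expect_identical(queryGenes(st, "A", featurePair("TF1", "TF1", 10, 100)),
                   character(0))
  expect_identical(queryGenes(st, "A", featurePair("TF1", "TF1", 10, 110)),
                   sf$acc[1])
})

test_that("two-step consistency: gene list matches per-gene hit detail", {
  sf <- storeFixture()
  st <- sf$store
  for (f in storeFeatures(st)) {
    fromQuery <- queryGenes(st, "A", featureTerm(f))
    fromDetail <- sf$acc[vapply(sf$acc, function(a)
      any(hitsForGene(st, "A", a)$feature_id == f), logical(1))]
    expect_identical(fromQuery, sort(fromDetail))
  }
  # concatenating hitsForGene over all genes reproduces the hit table
  total <- sum(vapply(sf$acc, function(a)
    nrow(hitsForGene(st, "A", a)), integer(1)))
  expect_identical(total, nrow(sf$hits))
  expect_identical(nrow(hitsForGene(st, "A", sf$acc[5])), 0L)
  expect_error(hitsForGene(st, "A", "NOPE"), "unknown accession")
})

test_that("cross-genome filter requires a homolog with the same feature", {
  fxA <- sparsePromoterFixture(4, flank = 300, seed = 111, genomeId = "A")
  fxB <- sparsePromoterFixture(4, flank = 300, seed = 112, genomeId = "B")
  aAcc <- names(fxA$promoters)
  bAcc <- paste0(names(fxB$promoters), "B")
  infoB <- promoterInfo(fxB$promoters)
  infoB$accession <- bAcc
  promsB <- new("PromoterSet", genomeId = "B", info = infoB,
                sequences = setNames(promoterSequences(fxB$promoters), bAcc))
  # A: genes 1-3 have TF1; B homologs: 1 has TF1, 2 lacks it
  hitsA <- mkHits(aAcc[1:3], "TF1", c(5L, 6L, 7L))
  hitsB <- mkHits(bAcc[1], "TF1", 9L)
  st <- buildStore(list(A = fxA$promoters, B = promsB),
                   list(A = hitsA, B = hitsB))
  hom <- data.frame(group_id = c(1L, 1L, 2L, 2L),
                    genome_id = c("A", "B", "A", "B"),
                    accession = c(aAcc[1], bAcc[1], aAcc[2], bAcc[2]))
  # gene 3 has no homology group; gene 2's homolog lacks the hit
  expect_identical(crossGenomeFilter(st, "A", "B", hom, "TF1"), aAcc[1])
  # result is a subset of the single-term query
  expect_true(all(crossGenomeFilter(st, "A", "B", hom, "TF1") %in%
                    queryGenes(st, "A", featureTerm("TF1"))))
  # full conservation: filter equals the single-term result restricted to
  # genes with homologs
  hitsB2 <- mkHits(bAcc[1:3], "TF1", c(9L, 10L, 11L))
  st2 <- buildStore(list(A = fxA$promoters, B = promsB),
                    list(A = hitsA, B = hitsB2))
  hom2 <- data.frame(group_id = rep(1:4, each = 2),
                     genome_id = rep(c("A", "B"), 4),
                     accession = as.vector(rbind(aAcc, bAcc)))
  expect_identical(crossGenomeFilter(st2, "A", "B", hom2, "TF1"),
                   queryGenes(st2, "A", featureTerm("TF1")))
})

test_that("accession patterns are version-stripped and fully anchored", {
  fx <- sparsePromoterFixture(3, flank = 200, seed = 121)
  info <- promoterInfo(fx$promoters)
  info$accession <- c("NM_000001.2", "NM_000011", "NR_000200")
  proms <- new("PromoterSet", genomeId = "A", info = info,
               sequences = setNames(promoterSequences(fx$promoters),
                                    info$accession))
  st <- buildStore(list(A = proms))
  expect_identical(matchAccessions(st, "A", "NM_000001$"), "NM_000001.2")
  expect_identical(matchAccessions(st, "A", "NM_00001$"), character(0))
  expect_identical(matchAccessions(st, "A", "NM_.*"),
                   c("NM_000001.2", "NM_000011"))
  expect_error(matchAccessions(st, "A", "NM_[00"), "invalid pattern")
})

test_that("CSV export is sorted, formatted and re-importable", {
  sf <- storeFixture()
  st <- sf$store
  csv <- withr::local_tempfile(fileext = ".csv")
  exportCsv(st, "A", sf$acc, csv)
  back <- read.csv(csv)
  expect_identical(nrow(back), nrow(sf$hits))
  expect_identical(names(back)[1:6],
                   c("accession", "genome", "chrom", "strand", "feature_id",
                     "hit_strand"))
  # row count equals the sum over hitsForGene
  total <- sum(vapply(sf$acc, function(a)
    nrow(hitsForGene(st, "A", a)), integer(1)))
  expect_identical(nrow(back), total)
  # re-exporting the re-import reproduces the file byte-for-byte
  lines1 <- readLines(csv)
  expect_identical(sprintf("%.3f", back$raw_score),
                   vapply(strsplit(lines1[-1], ","), `[`, character(1), 11))
  # empty accession list gives a header-only file
  csv2 <- withr::local_tempfile(fileext = ".csv")
  exportCsv(st, "A", character(0), csv2)
  expect_length(readLines(csv2), 1L)
  expect_error(exportCsv(st, "A", "NOPE", csv2), "unknown accession")
})

test_that("homology tables round-trip and reject duplicate members", {
  hom <- data.frame(group_id = c(1L, 1L, 2L, 2L),
                    genome_id = c("A", "B", "A", "B"),
                    accession = c("NM_1", "MUS_1", "NM_2", "MUS_2"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeHomology(hom, tf)
  expect_identical(readHomology(tf), hom)
  bad <- hom
  bad$accession[3] <- "NM_1"
  writeHomology(bad, tf)
  expect_error(readHomology(tf), "unique")
})
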