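# Gene tables, deduplication, promoter extraction and anchor coordinates.

test_that("minimal dialect parses and flags anchorless rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NM_1\tG1\tchr1\t+\t10000\t10200",
               "NM_2\tG2\tchr1\t-\t\t5000"), tf)
  gt <- readGeneTable(tf, "minimal")
  expect_identical(gt$tss, c(10000L, NA_integer_))
  expect_identical(gt$css, c(10200L, 5000L))
  writeLines(c("NM_1\tG1\tchr1\t+\t10000\t10200",
               "NM_3\tG3\tchr1\t+\t\t"), tf)
  expect_error(readGeneTable(tf, "minimal"), "NM_3")
})

test_that("refGene dialect maps interval ends to anchors strand-aware", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  # layout with leading bin column
  writeLines(c(paste("0", "NM_10", "chr2", "+", "100", "900", "150", "850",
                     "1", "100,", "900,", "0", "GENEA", sep = "\t"),
               paste("0", "NM_11", "chr2", "-", "100", "900", "150", "850",
                     "1", "100,", "900,", "0", "GENEB", sep = "\t")), tf)
  gt <- readGeneTable(tf, "refgene")
  expect_identical(gt$tss, c(100L, 899L))
  expect_identical(gt$css, c(150L, 849L))
  expect_identical(gt$symbol, c("GENEA", "GENEB"))
  # same rows without the bin column parse identically
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("NM_10", "chr2", "+", "100", "900", "150", "850",
                     sep = "\t"),
               paste("NM_11", "chr2", "-", "100", "900", "150", "850",
                     sep = "\t")), tf2)
  gt2 <- readGeneTable(tf2, "refgene")
  expect_identical(gt2$tss, gt$tss)
  expect_identical(gt2$css, gt$css)
})

test_that("deduplication prefers the lexicographically first chromosome", {
  gt <- data.frame(accession = c("NM_1.2", "NM_1", "NM_2", "NM_2", "NM_3"),
                   symbol = "", chrom = c("chr1_random", "chr1", "chr2",
                                          "chr11", "chr5"),
                   strand = "+", tss = c(10L, 20L, 30L, 40L, 50L),
                   css = c(15L, 25L, 35L, 45L, 55L),
                   stringsAsFactors = FALSE)
  dd <- deduplicateGenes(gt)
  expect_identical(nrow(dd), 3L)
  expect_identical(dd$chrom[stripVersion(dd$accession) == "NM_1"], "chr1")
  # lexicographic: "chr11" < "chr2"
  expect_identical(dd$chrom[stripVersion(dd$accession) == "NM_2"], "chr11")
  # single records pass through unchanged
  expect_identical(deduplicateGenes(gt[5, ])$accession, "NM_3")
  # tie on chromosome keeps the lowest anchor
  gt2 <- gt[3:4, ]
  gt2$chrom <- "chr7"
  expect_identical(deduplicateGenes(gt2)$tss, 30L)
})

test_that("extraction arithmetic, clipping and strand orientation", {
  genome <- makeGenome(6000, seed = 41)
  gt <- data.frame(accession = c("NM_1", "NM_2", "NM_3"), symbol = "",
                   chrom = "chr1", strand = c("+", "-", "+"),
                   tss = c(3000L, 3000L, 500L), css = c(3100L, 2900L, 600L),
                   stringsAsFactors = FALSE)
  proms <- extractPromoters(genome, gt, flank = 2000)
  info <- promoterInfo(proms)
  expect_equal(info$gstart[1:2], c(1000L, 1000L))
  expect_equal(info$gend[1:2], c(5000L, 5000L))
  expect_equal(width(promoterSequences(proms))[1], 4000L)
  # minus strand: same genomic interval, reverse-complement sequence
  s1 <- promoterSequences(proms)[[1]]
  s2 <- promoterSequences(proms)[[2]]
  expect_identical(as.character(Biostrings::reverseComplement(s1)),
                   as.character(s2))
  # clipping at the chromosome start
  expect_identical(info$gstart[3], 0L)
  expect_identical(info$gend[3], 2500L)
  expect_true(info$clipped[3])
  expect_identical(width(promoterSequences(proms))[3], 2500L)
  # missing chromosome and out-of-range anchor raise
  gtBad <- gt[1, ]; gtBad$chrom <- "chrX"
  expect_error(extractPromoters(genome, gtBad, 2000), "missing")
  gtBad2 <- gt[1, ]; gtBad2$tss <- 7000L; gtBad2$css <- 7100L
  expect_error(extractPromoters(genome, gtBad2, 2000), "anchor")
})

test_that("CSS is the anchor exactly when the TSS is unknown", {
  genome <- makeGenome(20000, seed = 6)
  gt <- data.frame(accession = c("NM_1", "NM_2"), symbol = "",
                   chrom = "chr1", strand = "+",
                   tss = c(9000L, NA), css = c(9200L, 12000L),
                   stringsAsFactors = FALSE)
  info <- promoterInfo(extractPromoters(genome, gt, 1000))
  expect_identical(info$anchor_type, c("TSS", "CSS"))
  expect_identical(info$anchor_pos, c(9000L, 12000L))
})

test_that("anchor-relative coordinates span [-flank, flank) on both strands", {
  genome <- makeGenome(10000, seed = 17)
  gt <- data.frame(accession = c("NM_P", "NM_M"), symbol = "",
                   chrom = "chr1", strand = c("+", "-"),
                   tss = c(4000L, 6000L), css = c(4100L, 5900L),
                   stringsAsFactors = FALSE)
  proms <- extractPromoters(genome, gt, flank = 2000)
  for (acc in c("NM_P", "NM_M")) {
    expect_identical(anchorRelative(proms, acc, 0L), -2000L)
    expect_identical(anchorRelative(proms, acc, 2000L), 0L)
    expect_identical(anchorRelative(proms, acc, 3999L), 1999L)
  }
  expect_error(anchorRelative(proms, "NM_P", 4000L), "range")
  # hand check on a toy minus-strand gene: position 0 of the oriented
  # sequence is the most-upstream base, gend-1 genomically
  expect_identical(anchorRelative(proms, "NM_M", 1999L), -1L)
})

test_that("promoter sets round-trip through FASTA plus table", {
  fx <- sparsePromoterFixture(4, flank = 250, seed = 71)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writePromoterSet(fx$promoters, fa, tsv)
  back <- readPromoterSet(fa, tsv)
  expect_identical(promoterInfo(back)$accession,
                   promoterInfo(fx$promoters)$accession)
  expect_identical(as.character(promoterSequences(back)),
                   as.character(promoterSequences(fx$promoters)))
  expect_identical(genomeId(back), genomeId(fx$promoters))
})

test_that("TSS-CSS distances and quartiles", {
  gt <- data.frame(accession = paste0("NM_", 1:5), symbol = "",
                   chrom = "chr1", strand = "+",
                   tss = c(0L, 100L, 500L, NA, 1000L),
                   css = c(100L, 300L, 200L, 50L, 1400L))
  d <- tssCssDistances(gt)
  expect_identical(sort(d$distances), c(100L, 200L, 300L, 400L))
  expect_equal(unname(d$quartiles[2]), 250)
  none <- tssCssDistances(gt[4, ])
  expect_length(none$distances, 0)
  expect_null(none$quartiles)
  # quartiles of a generated log-normal law are recovered at n = 1e4
  law <- list(meanlog = log(373), sdlog = 1.0)
  genome <- makeGenome(5e6, seed = 10)
  big <- makeGeneTable(genome, 1e4, distanceLaw = law, margin = 100,
                       seed = 99)
  q <- tssCssDistances(big)$quartiles
  expected <- qlnorm(c(0.25, 0.5, 0.75), law$meanlog, law$sdlog)
  expect_true(all(abs(q / expected - 1) < 0.1))
})
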