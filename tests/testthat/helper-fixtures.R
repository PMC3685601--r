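# Fixture builders shared across tests. Everything is generated in code;
# no data files.

suppressPackageStartupMessages(library(Biostrings))

mkPFM <- function(counts, id = "M") {
  counts <- matrix(counts, nrow = 4, dimnames = list(c("A", "C", "G", "T"),
                                                     NULL))
  new("PFM", id = id, name = "", counts = counts)
}

# Frequency matrix straight from probabilities (pseudocount 0 recorded).
mkFreq <- function(f, id = "M") {
  f <- matrix(f, nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  new("FrequencyMatrix", id = id, f = f, pseudocount = 0)
}

# Model whose columns all prefer one base with probability pMax; the
# column argmax is unique, so the consensus is the single top word and
# p_min = 0.25^L under the uniform background.
uniqueMaxModel <- function(L, pMax = 0.7, bases = rep(1L, L), id = "U") {
  f <- sapply(seq_len(L), function(i) {
    col <- rep((1 - pMax) / 3, 4)
    col[bases[i]] <- pMax
    col
  })
  buildScoreModel(mkFreq(f, id))
}

# Model with two tied maxima in column 1 (A and C), unique elsewhere.
tiedMaxModel <- function(L, id = "T") {
  f <- sapply(seq_len(L), function(i) {
    if (i == 1) c(0.4, 0.4, 0.1, 0.1) else c(0.7, 0.1, 0.1, 0.1)
  })
  buildScoreModel(mkFreq(f, id))
}

# Reverse-complement symmetric model (consensus ACGT, a palindrome).
palindromicModel <- function(id = "P") {
  f <- cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
             c(0.1, 0.1, 0.7, 0.1), c(0.1, 0.1, 0.1, 0.7))
  buildScoreModel(mkFreq(f, id))
}

randomCalibs <- function(n, Ls, seed, granularity = 1e4, nSites = 20) {
  seeds <- promscan:::childSeeds(seed, n)
  lapply(seq_len(n), function(k) {
    pfm <- randomPFM(sprintf("R%02d", k), Ls[((k - 1) %% length(Ls)) + 1],
                     nSites = nSites, seed = seeds[k])
    calibrateModel(buildScoreModel(toFrequencies(pfm, 0.8)), granularity)
  })
}

# Small genome + gene table + promoter set; genes spaced so windows never
# overlap and never clip.
sparsePromoterFixture <- function(nGenes, flank, seed, genomeId = "A",
                                  gc = 0.5) {
  spacing <- 2L * flank + 200L
  len <- as.integer(nGenes * spacing + 2L * flank + 400L)
  genome <- makeGenome(len, gc = gc, seed = seed)
  tss <- as.integer(flank + 200L + spacing * (seq_len(nGenes) - 1L))
  genes <- data.frame(accession = sprintf("NM_%06d", seq_len(nGenes)),
                      symbol = sprintf("G%d", seq_len(nGenes)),
                      chrom = "chr1",
                      strand = rep(c("+", "-"), length.out = nGenes),
                      tss = tss, css = tss + 150L,
                      stringsAsFactors = FALSE)
  proms <- extractPromoters(genome, genes, flank, genomeId = genomeId)
  list(genome = genome, genes = genes, promoters = proms)
}

# Hand-built hit table rows.
mkHits <- function(accession, feature_id, start_rel, width = 8L,
                   strand = "+", p_value = 1e-5, start_anchor = NULL) {
  n <- max(length(accession), length(feature_id), length(start_rel))
  df <- data.frame(accession = rep_len(accession, n),
                   start_anchor = if (is.null(start_anchor))
                     rep_len(start_rel, n) else rep_len(start_anchor, n),
                   feature_id = rep_len(feature_id, n),
                   strand = rep_len(strand, n),
                   start_rel = rep_len(start_rel, n),
                   width = rep_len(as.integer(width), n),
                   raw_score = rep_len(1, n), norm_score = rep_len(50, n),
                   p_value = rep_len(p_value, n),
                   stringsAsFactors = FALSE)
  df
}
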