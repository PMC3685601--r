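# Deterministic, seeded generator of genomes, gene tables, homology maps,
# PFMs and planted-motif gene sets. One parent seed fans out into
# per-component child seeds so components can be regenerated independently.

#' Generate a random genome
#'
#' I.i.d. bases at a stated GC content, or a linear GC ramp along each
#' chromosome (\code{gc = list(from =, to =)}); G/C and A/T are split
#' evenly. Identical seeds give byte-identical sequences.
#'
#' @param lengths chromosome lengths (one per chromosome).
#' @param gc GC fraction in [0, 1], or \code{list(from, to)} ramp spec.
#' @param seed integer seed.
#' @param chromNames chromosome names; default \code{chr1..chrN}.
#' @param path optional FASTA output path.
#' @return \code{DNAStringSet} named by chromosome.
#' @export
makeGenome <- function(lengths, gc = 0.5, seed = 1,
                       chromNames = paste0("chr", seq_along(lengths)),
                       path = NULL) {
  stopifnot(all(lengths >= 1))
  gcRange <- if (is.list(gc)) c(gc$from, gc$to) else c(gc, gc)
  if (any(gcRange < 0 | gcRange > 1)) stop("gc must lie in [0, 1]")
  seqs <- withSeed(seed, lapply(lengths, function(len) {
    gcVec <- seq(gcRange[1], gcRange[2], length.out = len)
    isGC <- runif(len) < gcVec
    second <- runif(len) < 0.5
    paste(ifelse(isGC, ifelse(second, "G", "C"),
                 ifelse(second, "A", "T")), collapse = "")
  }))
  genome <- DNAStringSet(unlist(seqs))
  names(genome) <- chromNames
  if (!is.null(path)) writeXStringSet(genome, path)
  genome
}

#' Generate a random gene table
#'
#' Genes are placed uniformly on the genome (keeping \code{margin} bases
#' clear of chromosome ends so default flanks stay unclipped), with random
#' strand. TSS-CSS distances follow a log-normal law (defaults chosen to
#' mimic the skewed distances seen in mammalian annotation: median 373,
#' quartiles roughly 114 and 4280); the CSS lies downstream of the TSS on
#' the gene's strand. A stated fraction of genes loses its TSS annotation
#' (CSS fallback), and a stated fraction is duplicated onto a
#' \code{"_random"}-suffixed copy of its chromosome, emulating
#' multiply-mapped accessions.
#'
#' @param genome \code{DNAStringSet} (for chromosome names and lengths).
#' @param nGenes number of genes.
#' @param fracMissingTss expected fraction with unknown TSS; default 0.
#' @param fracDuplicates expected fraction duplicated on
#'   \code{"_random"} chromosomes; default 0.
#' @param distanceLaw list with \code{meanlog}, \code{sdlog} for the
#'   TSS-CSS distance.
#' @param margin clear zone at chromosome ends; default 2000.
#' @param seed integer seed.
#' @return gene data.frame in the minimal dialect (see
#'   \code{\link{readGeneTable}}).
#' @export
makeGeneTable <- function(genome, nGenes, fracMissingTss = 0,
                          fracDuplicates = 0,
                          distanceLaw = list(meanlog = log(373),
                                             sdlog = 1.76),
                          margin = 2000, seed = 1) {
  lens <- setNames(width(genome), names(genome))
  usable <- lens - 2 * margin
  if (all(usable < 1)) stop("chromosomes too short for the margin")
  lens <- lens[usable >= 1]
  usable <- usable[usable >= 1]
  withSeed(seed, {
    chrom <- sample(names(lens), nGenes, replace = TRUE,
                    prob = usable / sum(usable))
    tss <- margin + floor(runif(nGenes) * usable[chrom])
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    d <- pmax(1, round(rlnorm(nGenes, distanceLaw$meanlog,
                              distanceLaw$sdlog)))
    css <- ifelse(strand == "+", tss + d, tss - d)
    css <- pmin(pmax(css, 0), lens[chrom] - 1)
    df <- data.frame(accession = sprintf("NM_%06d", seq_len(nGenes)),
                     symbol = sprintf("GENE%d", seq_len(nGenes)),
                     chrom = chrom, strand = strand,
                     tss = as.integer(tss), css = as.integer(css),
                     stringsAsFactors = FALSE)
    drop <- runif(nGenes) < fracMissingTss
    df$tss[drop] <- NA_integer_
    dup <- which(runif(nGenes) < fracDuplicates)
    if (length(dup)) {
      extra <- df[dup, , drop = FALSE]
      extra$chrom <- paste0(extra$chrom, "_random")
      df <- rbind(df, extra)
    }
    rownames(df) <- NULL
    df
  })
}

#' Generate a random position frequency matrix
#'
#' Column base probabilities are drawn from a symmetric Dirichlet
#' (\code{concentration} < 1 gives sharp, informative columns) and turned
#' into counts over \code{nSites} aligned sites.
#'
#' @param id motif accession to assign.
#' @param L motif length.
#' @param nSites number of sites (column totals).
#' @param concentration Dirichlet concentration; default 0.5.
#' @param seed integer seed.
#' @return a \linkS4class{PFM}.
#' @export
randomPFM <- function(id, L, nSites = 20, concentration = 0.5, seed = 1) {
  counts <- withSeed(seed, {
    sapply(seq_len(L), function(i) {
      g <- stats::rgamma(4, shape = concentration)
      p <- g / sum(g)
      as.numeric(stats::rmultinom(1, nSites, p))
    })
  })
  counts <- matrix(counts, nrow = 4,
                   dimnames = list(DNA_BASES4, NULL))
  # guarantee a positive column total (rmultinom already ensures this)
  new("PFM", id = id, name = "", counts = counts)
}

#' Generate a bijective homology map over two gene sets
#'
#' Pairs a covered subset of genome-A genes one-to-one with genome-B
#' genes; the remaining genes stay ungrouped. Every group has exactly two
#' members.
#'
#' @param genesA,genesB accession vectors.
#' @param coverage fraction of the smaller set to pair, in [0, 1].
#' @param genomeA,genomeB genome ids recorded in the table.
#' @param seed integer seed.
#' @return homology data.frame (\code{group_id}, \code{genome_id},
#'   \code{accession}).
#' @export
makeHomology <- function(genesA, genesB, coverage = 1, genomeA = "A",
                         genomeB = "B", seed = 1) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  n <- floor(coverage * min(length(genesA), length(genesB)))
  if (n == 0)
    return(data.frame(group_id = integer(0), genome_id = character(0),
                      accession = character(0)))
  withSeed(seed, {
    a <- sample(genesA, n)
    b <- sample(genesB, n)
    data.frame(group_id = rep(seq_len(n), each = 2),
               genome_id = rep(c(genomeA, genomeB), n),
               accession = as.vector(rbind(a, b)),
               stringsAsFactors = FALSE)
  })
}

# Write `word` into chromosome `chrom` of genome at 0-based gpos,
# replacing bases (fixed length, coordinates stay stable).
.plantWord <- function(genome, chrom, gpos, word) {
  genome[[chrom]] <- replaceAt(genome[[chrom]],
                               IRanges(gpos + 1L, gpos + nchar(word)),
                               word)
  genome
}

# One insertion bookkeeping table shared by plantMotifs.
.occupiedOverlaps <- function(occ, chrom, s, e) {
  if (!nrow(occ)) return(FALSE)
  any(occ$chrom == chrom & occ$start < e & occ$end > s)
}

#' Plant motif occurrences into promoter windows
#'
#' Splits the genes into a positive and a negative set; each promoter
#' window receives a Poisson number of insertions of each feature's word
#' (\code{ratePos} per feature in positives, \code{rateNeg} in negatives).
#' Words replace bases at a uniformly drawn position inside the window, on
#' the gene's strand (reverse-complemented into genomic coordinates for
#' \code{-} strand genes); overlapping insertions are re-drawn (bounded
#' retries). With a second genome, homologous records and a homology map,
#' each planted site is copied to a uniform position in the homolog's
#' promoter with probability \code{conservation}.
#'
#' @param genome \code{DNAStringSet} to modify.
#' @param records deduplicated gene table for \code{genome}.
#' @param flank promoter flank the windows assume.
#' @param features named character vector: feature id -> word to plant.
#' @param ratePos,rateNeg expected insertions per promoter per feature.
#' @param fracPositive fraction of genes assigned to the positive set.
#' @param genomeB,recordsB,homology optional second genome for homolog
#'   conservation.
#' @param conservation probability a planted site is copied to the
#'   homolog.
#' @param seed integer seed.
#' @return list with \code{genome} (modified), \code{genomeB} (or NULL),
#'   \code{truth} (data.frame: genome, accession, feature_id, start_rel,
#'   start_anchor, strand), \code{positive}, \code{negative} (accession
#'   vectors).
#' @export
plantMotifs <- function(genome, records, flank, features, ratePos,
                        rateNeg, fracPositive = 0.5, genomeB = NULL,
                        recordsB = NULL, homology = NULL, conservation = 0,
                        genomeIdA = "A", genomeIdB = "B", seed = 1) {
  stopifnot(ratePos >= 0, rateNeg >= 0, !is.null(names(features)))
  seeds <- childSeeds(seed, 2L)
  n <- nrow(records)
  anchor <- ifelse(is.na(records$tss), records$css, records$tss)
  lensA <- setNames(width(genome), names(genome))
  lensB <- if (!is.null(genomeB)) setNames(width(genomeB), names(genomeB))
  truth <- list()
  occ <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  occB <- occ
  hmap <- if (!is.null(homology) && !is.null(genomeB))
    .homologMap(homology, genomeIdA, genomeIdB) else NULL
  withSeed(seeds[1], {
    pos <- sort(sample(records$accession, round(fracPositive * n)))
    neg <- setdiff(records$accession, pos)
    for (j in seq_len(n)) {
      accJ <- records$accession[j]
      rate <- if (accJ %in% pos) ratePos else rateNeg
      winLo <- anchor[j] - flank
      winHi <- anchor[j] + flank
      for (f in names(features)) {
        word <- features[[f]]
        L <- nchar(word)
        nIns <- rpois(1, rate)
        for (k in seq_len(nIns)) {
          placed <- FALSE
          for (try in 1:100) {
            startRel <- floor(runif(1) * (2 * flank - L + 1))
            if (records$strand[j] == "+") {
              g0 <- winLo + startRel
              w <- word
            } else {
              g0 <- winHi - startRel - L
              w <- as.character(reverseComplement(DNAString(word)))
            }
            if (g0 < 0 || g0 + L > lensA[[records$chrom[j]]]) next
            if (.occupiedOverlaps(occ, records$chrom[j], g0, g0 + L)) next
            genome <- .plantWord(genome, records$chrom[j], g0, w)
            occ <- rbind(occ, data.frame(chrom = records$chrom[j],
                                         start = g0, end = g0 + L))
            truth[[length(truth) + 1L]] <- data.frame(
              genome = genomeIdA, accession = accJ, feature_id = f,
              start_rel = startRel, start_anchor = startRel - flank,
              strand = "+", stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed)
            stop("could not place insertion without overlap (promoter ",
                 accJ, ")")
          # conserved copy in the homologous promoter
          if (placed && !is.null(hmap) && runif(1) < conservation) {
            homs <- hmap[[stripVersion(accJ)]]
            if (!is.null(homs) && length(homs)) {
              jb <- match(homs[1], stripVersion(recordsB$accession))
              if (!is.na(jb)) {
                anchorB <- if (is.na(recordsB$tss[jb])) recordsB$css[jb]
                           else recordsB$tss[jb]
                for (try in 1:100) {
                  srB <- floor(runif(1) * (2 * flank - L + 1))
                  if (recordsB$strand[jb] == "+") {
                    g0b <- anchorB - flank + srB
                    wb <- word
                  } else {
                    g0b <- anchorB + flank - srB - L
                    wb <- as.character(reverseComplement(DNAString(word)))
                  }
                  chB <- recordsB$chrom[jb]
                  if (g0b < 0 || g0b + L > lensB[[chB]]) next
                  if (.occupiedOverlaps(occB, chB, g0b, g0b + L)) next
                  genomeB <- .plantWord(genomeB, chB, g0b, wb)
                  occB <- rbind(occB, data.frame(chrom = chB, start = g0b,
                                                 end = g0b + L))
                  truth[[length(truth) + 1L]] <- data.frame(
                    genome = genomeIdB, accession = recordsB$accession[jb],
                    feature_id = f, start_rel = srB,
                    start_anchor = srB - flank, strand = "+",
                    stringsAsFactors = FALSE)
                  break
                }
              }
            }
          }
        }
      }
    }
    truthDf <- if (length(truth)) do.call(rbind, truth)
               else data.frame(genome = character(0),
                               accession = character(0),
                               feature_id = character(0),
                               start_rel = integer(0),
                               start_anchor = integer(0),
                               strand = character(0))
    list(genome = genome, genomeB = genomeB, truth = truthDf,
         positive = pos, negative = sort(neg))
  })
}
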