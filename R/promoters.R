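# Gene tables, deduplication and promoter window extraction.

#' Read a gene annotation table
#'
#' Two tab-delimited dialects are supported, both headerless:
#' \describe{
#'   \item{\code{minimal}}{columns accession, symbol, chrom, strand, tss,
#'     css; tss or css may be empty (unknown) but not both.}
#'   \item{\code{refgene}}{UCSC refGene layout (with or without the leading
#'     \code{bin} column, auto-detected): name, chrom, strand, txStart,
#'     txEnd, cdsStart, cdsEnd, ... The anchor positions are mapped
#'     strand-aware: on \code{+}, tss = txStart and css = cdsStart; on
#'     \code{-}, tss = txEnd - 1 and css = cdsEnd - 1 (the last transcribed
#'     base), since refGene stores intervals, not anchors.}
#' }
#' All coordinates are 0-based.
#'
#' @param path file path.
#' @param dialect \code{"minimal"} or \code{"refgene"}.
#' @return data.frame with columns \code{accession}, \code{symbol},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{css} (NA = unknown).
#' @export
readGeneTable <- function(path, dialect = c("minimal", "refgene")) {
  dialect <- match.arg(dialect)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL,
                    blank.lines.skip = TRUE)
  if (dialect == "minimal") {
    if (ncol(raw) < 6)
      stop("minimal gene table needs 6 columns, found ", ncol(raw))
    df <- data.frame(accession = raw[[1]], symbol = raw[[2]],
                     chrom = raw[[3]], strand = raw[[4]],
                     tss = suppressWarnings(as.integer(raw[[5]])),
                     css = suppressWarnings(as.integer(raw[[6]])),
                     stringsAsFactors = FALSE)
  } else {
    strandAt <- function(k) all(raw[[k]] %in% c("+", "-"))
    off <- if (ncol(raw) >= 4 && strandAt(4)) 1L
           else if (ncol(raw) >= 3 && strandAt(3)) 0L
           else stop("cannot locate the strand column in refGene table")
    if (ncol(raw) < off + 7)
      stop("refGene table too narrow")
    num <- function(k) as.integer(raw[[off + k]])
    strand <- raw[[off + 3]]
    txS <- num(4); txE <- num(5); cdS <- num(6); cdE <- num(7)
    minus <- strand == "-"
    tss <- ifelse(minus, txE - 1L, txS)
    css <- ifelse(minus, cdE - 1L, cdS)
    symbol <- if (ncol(raw) >= off + 12) raw[[off + 12]] else ""
    df <- data.frame(accession = raw[[off + 1]], symbol = symbol,
                     chrom = raw[[off + 2]], strand = strand,
                     tss = tss, css = css, stringsAsFactors = FALSE)
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("strand column must contain only '+'/'-'")
  bad <- which(is.na(df$tss) & is.na(df$css))
  if (length(bad))
    stop("row ", bad[1], " (", df$accession[bad[1]],
         "): neither TSS nor CSS given")
  if (any(c(df$tss, df$css) < 0, na.rm = TRUE))
    stop("coordinates must be non-negative")
  df
}

#' Write a gene table in the minimal dialect
#'
#' @param records gene data.frame (as from \code{\link{readGeneTable}}).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGeneTable <- function(records, path) {
  out <- records[, c("accession", "symbol", "chrom", "strand", "tss", "css")]
  out$tss <- ifelse(is.na(out$tss), "", as.character(out$tss))
  out$css <- ifelse(is.na(out$css), "", as.character(out$css))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Resolve multiply-mapped accessions to a single location
#'
#' A gene accession (version stripped) may only appear once in a promoter
#' set. Among duplicates the record whose chromosome name sorts first
#' lexicographically is kept, so assignments on regular chromosomes are
#' preferred over \code{"_random"}/\code{"_unknown"} entities (chr1 sorts
#' before chr1_random); note the rule is purely lexicographic, so e.g.
#' chr11 sorts before chr2. Ties on the chromosome keep the lowest anchor
#' coordinate.
#'
#' @param records gene data.frame.
#' @return deduplicated data.frame, ordered by accession.
#' @export
deduplicateGenes <- function(records) {
  if (!nrow(records)) return(records)
  key <- stripVersion(records$accession)
  anchor <- ifelse(is.na(records$tss), records$css, records$tss)
  # C-locale lexicographic order, independent of the session locale
  chromRank <- match(records$chrom, sort(unique(records$chrom), method = "radix"))
  ord <- order(key, chromRank, anchor)
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract anchored promoter windows from a genome
#'
#' For each gene the anchor is the TSS when annotated, else the CSS (genes
#' with unknown TSS are deliberately kept; in most genes the CSS lies close
#' enough to the TSS for the window to cover the active promoter). The
#' genomic window \code{[anchor - flank, anchor + flank)} is clipped at
#' chromosome ends (recorded in the \code{clipped} flag); sequences of
#' \code{-} strand genes are reverse-complemented so that position 0 is the
#' most-upstream base on the gene's strand.
#'
#' @param genome \code{DNAStringSet} (or FASTA path) with chromosome names
#'   matching the gene table.
#' @param records deduplicated gene data.frame (see
#'   \code{\link{deduplicateGenes}}).
#' @param flank bases on each side of the anchor; default 2000.
#' @param genomeId label recorded in the promoter set.
#' @return a \linkS4class{PromoterSet}.
#' @export
extractPromoters <- function(genome, records, flank = 2000,
                             genomeId = "genome") {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(is(genome, "DNAStringSet"))
  if (length(flank) != 1L || flank <= 0) stop("flank must be positive")
  flank <- as.integer(flank)
  if (anyDuplicated(stripVersion(records$accession)))
    stop("records contain duplicated accessions; run deduplicateGenes() first")
  miss <- setdiff(unique(records$chrom), names(genome))
  if (length(miss))
    stop("chromosome(s) missing from genome: ", paste(miss, collapse = ", "))
  lens <- setNames(width(genome), names(genome))[records$chrom]
  anchorType <- ifelse(is.na(records$tss), "CSS", "TSS")
  anchor <- ifelse(is.na(records$tss), records$css, records$tss)
  bad <- which(anchor < 0 | anchor >= lens)
  if (length(bad))
    stop("anchor outside chromosome for ", records$accession[bad[1]])
  gstart <- pmax(0L, anchor - flank)
  gend <- pmin(lens, anchor + flank)
  clipped <- gstart > anchor - flank | gend < anchor + flank
  n <- nrow(records)
  seqs <- vector("list", n)
  for (j in seq_len(n)) {
    s <- subseq(genome[[records$chrom[j]]], gstart[j] + 1L, gend[j])
    if (records$strand[j] == "-") s <- reverseComplement(s)
    seqs[[j]] <- s
  }
  sset <- DNAStringSet(seqs)
  names(sset) <- records$accession
  sym <- if ("symbol" %in% names(records)) records$symbol else rep("", n)
  info <- data.frame(accession = records$accession, symbol = sym,
                     chrom = records$chrom, strand = records$strand,
                     anchor_type = anchorType,
                     anchor_pos = as.integer(anchor),
                     flank = rep(flank, n),
                     gstart = as.integer(gstart), gend = as.integer(gend),
                     clipped = clipped, layer = rep("default", n),
                     stringsAsFactors = FALSE)
  rownames(info) <- NULL
  new("PromoterSet", genomeId = genomeId, info = info, sequences = sset)
}

# Vectorized anchor-relative coordinate for one promoter info row.
# Both strands map an unclipped window onto [-flank, flank); negative
# values are upstream of the anchor on the gene's strand.
.anchorRel <- function(inforow, startRel) {
  if (inforow$strand == "+") {
    inforow$gstart + startRel - inforow$anchor_pos
  } else {
    inforow$anchor_pos - inforow$gend + startRel
  }
}

#' Anchor-relative coordinate of a promoter position
#'
#' Maps a 0-based offset in the oriented promoter sequence onto the
#' coordinate relative to the anchor (TSS/CSS); negative values lie
#' upstream of the anchor on the gene's strand. Unclipped windows span
#' exactly \code{[-flank, flank)}.
#'
#' @param promoters a \linkS4class{PromoterSet}.
#' @param accession promoter accession.
#' @param startRel 0-based offset(s), \code{0 <= startRel < length}.
#' @return integer anchor-relative coordinate(s).
#' @export
anchorRelative <- function(promoters, accession, startRel) {
  stopifnot(is(promoters, "PromoterSet"))
  j <- match(accession, promoters@info$accession)
  if (is.na(j)) stop("unknown accession: ", accession)
  len <- promoters@info$gend[j] - promoters@info$gstart[j]
  if (any(startRel < 0 | startRel >= len))
    stop("startRel out of range [0, ", len, ")")
  .anchorRel(promoters@info[j, ], startRel)
}

#' TSS-CSS distance distribution
#'
#' For records annotated with both anchors, the absolute distance
#' \code{|css - tss|} and its quartiles (linear interpolation). Most genes
#' have the CSS within a few hundred bases of the TSS, which is what makes
#' the CSS a workable fallback anchor.
#'
#' @param records gene data.frame.
#' @return list with \code{distances} (integer vector) and
#'   \code{quartiles} (named numeric: 25\%, 50\%, 75\%; \code{NULL} when no
#'   record has both anchors).
#' @export
tssCssDistances <- function(records) {
  both <- !is.na(records$tss) & !is.na(records$css)
  d <- abs(records$css[both] - records$tss[both])
  list(distances = d,
       quartiles = if (length(d)) quantile(d, c(0.25, 0.5, 0.75)) else NULL)
}

#' Write a promoter set as FASTA plus metadata table
#'
#' FASTA headers are \code{accession|genome|chrom:gstart-gend|strand|anchor_type};
#' the companion tab-delimited table carries the full metadata needed to
#' reconstruct the \linkS4class{PromoterSet} with
#' \code{\link{readPromoterSet}}.
#'
#' @param promoters a \linkS4class{PromoterSet}.
#' @param fastaPath,tablePath output paths (table optional for FASTA-only
#'   export).
#' @return invisibly, \code{fastaPath}.
#' @export
writePromoterSet <- function(promoters, fastaPath, tablePath = NULL) {
  stopifnot(is(promoters, "PromoterSet"))
  info <- promoters@info
  seqs <- promoters@sequences
  names(seqs) <- sprintf("%s|%s|%s:%d-%d|%s|%s", info$accession,
                         promoters@genomeId, info$chrom, info$gstart,
                         info$gend, info$strand, info$anchor_type)
  writeXStringSet(seqs, fastaPath)
  if (!is.null(tablePath)) {
    tbl <- cbind(genome = promoters@genomeId, info)
    writeTsv(tbl, tablePath)
  }
  invisible(fastaPath)
}

#' Read a promoter set written by \code{\link{writePromoterSet}}
#'
#' @param fastaPath promoter FASTA.
#' @param tablePath companion metadata table.
#' @return a \linkS4class{PromoterSet}.
#' @export
readPromoterSet <- function(fastaPath, tablePath) {
  seqs <- readDNAStringSet(fastaPath)
  info <- read.delim(tablePath, stringsAsFactors = FALSE)
  gid <- unique(info$genome)
  if (length(gid) != 1L) stop("promoter table must describe one genome")
  acc <- sub("\\|.*$", "", names(seqs))
  if (!identical(acc, info$accession))
    stop("FASTA and table disagree on promoter accessions")
  names(seqs) <- acc
  info$genome <- NULL
  if (is.null(info$layer)) info$layer <- "default"
  new("PromoterSet", genomeId = gid, info = info, sequences = seqs)
}
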