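# Layered annotation store: promoters + hits per genome, two-step querying
# (gene list first, per-gene hit detail on demand), combinatorial queries,
# cross-genome homology filtering and CSV export.

.sortHits <- function(h) {
  h <- h[order(h$accession, h$start_rel, h$feature_id,
               match(h$strand, c("+", "-"))), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Build an annotation store
#'
#' Promoters and hit tables are supplied per genome, either as a single
#' object (taken as the \code{"default"} layer) or as a named list of
#' layers (e.g. \code{list(default = ..., user = ...)}). The queryable view
#' is always the union of layers: a user layer may add hits on default
#' promoters and promoters with novel accessions, but a user promoter that
#' redefines an existing accession with different coordinates is an error.
#'
#' @param promoters named list: genome id -> \linkS4class{PromoterSet} or
#'   named list of layer -> \linkS4class{PromoterSet}.
#' @param hits named list: genome id -> hit data.frame (from
#'   \code{\link{scanPromoterSet}}) or named list of layer -> data.frame.
#'   Genomes without hits may be omitted.
#' @return an \linkS4class{AnnotationStore}.
#' @export
buildStore <- function(promoters, hits = list()) {
  if (is.null(names(promoters)) || any(!nzchar(names(promoters))))
    stop("promoters must be a named list (genome ids)")
  proms <- list()
  hitTabs <- list()
  for (g in names(promoters)) {
    p <- promoters[[g]]
    layers <- if (is(p, "PromoterSet")) list(default = p) else p
    if (is.null(names(layers))) stop("promoter layers must be named")
    merged <- NULL
    for (ly in names(layers)) {
      ps <- layers[[ly]]
      stopifnot(is(ps, "PromoterSet"))
      info <- ps@info
      info$layer <- ly
      cur <- list(info = info, seqs = ps@sequences)
      if (is.null(merged)) {
        merged <- cur
      } else {
        key <- stripVersion(cur$info$accession)
        oldKey <- stripVersion(merged$info$accession)
        shared <- intersect(key, oldKey)
        for (k in shared) {
          a <- merged$info[oldKey == k, , drop = FALSE]
          b <- cur$info[key == k, , drop = FALSE]
          same <- a$chrom == b$chrom && a$gstart == b$gstart &&
            a$gend == b$gend && a$strand == b$strand
          if (!same)
            stop("accession collision across layers for differing promoters: ",
                 k, " (genome ", g, ")")
        }
        keep <- !(key %in% shared)
        merged$info <- rbind(merged$info, cur$info[keep, , drop = FALSE])
        merged$seqs <- c(merged$seqs, cur$seqs[keep])
      }
    }
    rownames(merged$info) <- NULL
    proms[[g]] <- new("PromoterSet", genomeId = g, info = merged$info,
                      sequences = merged$seqs)
    hg <- if (g %in% names(hits)) hits[[g]] else NULL
    hlayers <- if (is.null(hg)) list()
               else if (is.data.frame(hg)) list(default = hg) else hg
    tab <- .emptyHits(withAccession = TRUE)
    tab$layer <- character(0)
    for (ly in names(hlayers)) {
      h <- hlayers[[ly]]
      if (!nrow(h)) next
      h$layer <- ly
      tab <- rbind(tab, h[, names(tab)])
    }
    hitTabs[[g]] <- .sortHits(tab)
  }
  feats <- unique(unlist(lapply(hitTabs, function(h) h$feature_id),
                         use.names = FALSE))
  store <- new("AnnotationStore", promoters = proms, hits = hitTabs,
               features = sort(as.character(feats)))
  validObject(store)
  store
}

#' Genomes, features and tables held in a store
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id.
#' @return \code{storeGenomes}: character vector of genome ids;
#'   \code{storeFeatures}: known feature ids; \code{storePromoters}: the
#'   genome's \linkS4class{PromoterSet}; \code{storeHits}: the genome's
#'   full hit table (union of layers).
#' @export
storeGenomes <- function(store) names(store@promoters)

#' @rdname storeGenomes
#' @export
storeFeatures <- function(store) store@features

.checkGenome <- function(store, genome) {
  if (!genome %in% names(store@promoters))
    stop("unknown genome: ", genome)
}

#' @rdname storeGenomes
#' @export
storePromoters <- function(store, genome) {
  .checkGenome(store, genome)
  store@promoters[[genome]]
}

#' @rdname storeGenomes
#' @export
storeHits <- function(store, genome) {
  .checkGenome(store, genome)
  store@hits[[genome]]
}

# ---- feature query constructors -----------------------------------------

#' @rdname FeatureQuery
#' @param feature feature (motif) id.
#' @param minCount minimum number of hits required; default 1.
#' @export
featureTerm <- function(feature, minCount = 1) {
  new("FeatureTerm", feature = feature, minCount = as.integer(minCount))
}

#' @rdname FeatureQuery
#' @param ... sub-queries (\code{FeatureQuery} objects).
#' @export
featureAnd <- function(...) {
  qs <- list(...)
  if (!length(qs)) stop("featureAnd needs at least one sub-query")
  new("FeatureAnd", queries = qs)
}

#' @rdname FeatureQuery
#' @export
featureOr <- function(...) {
  qs <- list(...)
  if (!length(qs)) stop("featureOr needs at least one sub-query")
  new("FeatureOr", queries = qs)
}

#' @rdname FeatureQuery
#' @param featureA,featureB the two features of a pair (may be equal).
#' @param minSep,maxSep inclusive bounds on the gap in bases between the
#'   end of the upstream hit and the start of the downstream hit.
#' @export
featurePair <- function(featureA, featureB, minSep = 10, maxSep = 100,
                        minCount = 1) {
  new("FeaturePair", featureA = featureA, featureB = featureB,
      minSep = as.integer(minSep), maxSep = as.integer(maxSep),
      minCount = as.integer(minCount))
}

.queryFeatures <- function(query) {
  if (is(query, "FeatureTerm")) return(query@feature)
  if (is(query, "FeaturePair")) return(c(query@featureA, query@featureB))
  unlist(lapply(query@queries, .queryFeatures))
}

# Evaluate a query against one promoter's hit table.
.evalQuery <- function(query, hits) {
  if (is(query, "FeatureTerm")) {
    sum(hits$feature_id == query@feature) >= query@minCount
  } else if (is(query, "FeaturePair")) {
    sub <- hits[hits$feature_id %in% c(query@featureA, query@featureB), ,
                drop = FALSE]
    cnt <- countHitPairs(sub, query@minSep, query@maxSep)
    key <- paste(sort(c(query@featureA, query@featureB)), collapse = "|")
    !is.na(cnt[key]) && cnt[key] >= query@minCount
  } else if (is(query, "FeatureAnd")) {
    all(vapply(query@queries, .evalQuery, logical(1), hits = hits))
  } else if (is(query, "FeatureOr")) {
    any(vapply(query@queries, .evalQuery, logical(1), hits = hits))
  } else stop("unsupported query node")
}

# accession (version-stripped) -> homolog accessions in genome B
.homologMap <- function(homology, genomeA, genomeB) {
  a <- homology[homology$genome_id == genomeA, , drop = FALSE]
  b <- homology[homology$genome_id == genomeB, , drop = FALSE]
  bByGroup <- split(stripVersion(b$accession), b$group_id)
  out <- bByGroup[as.character(a$group_id)]
  names(out) <- stripVersion(a$accession)
  out[!vapply(out, is.null, logical(1))]
}

#' First-step query: which promoters satisfy a feature expression
#'
#' Returns the sorted accessions whose promoter satisfies the query; hit
#' details are deliberately not returned (fetch them per gene with
#' \code{\link{hitsForGene}}). With \code{homologGenome}, a gene is kept
#' only when at least one of its homologs in that genome also satisfies
#' the query (the cross-genome conservation cross-check).
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id to query.
#' @param query a \linkS4class{FeatureQuery} (see \code{\link{featureTerm}}).
#' @param homologGenome optional target genome id for the homology
#'   requirement.
#' @param homology homology table (see \code{\link{readHomology}});
#'   required with \code{homologGenome}.
#' @return sorted character vector of accessions.
#' @export
queryGenes <- function(store, genome, query, homologGenome = NULL,
                       homology = NULL) {
  .checkGenome(store, genome)
  unknown <- setdiff(unique(.queryFeatures(query)), store@features)
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  hits <- store@hits[[genome]]
  byAcc <- split(hits, hits$accession)
  acc <- names(byAcc)[vapply(byAcc, function(h) .evalQuery(query, h),
                             logical(1))]
  if (!is.null(homologGenome)) {
    .checkGenome(store, homologGenome)
    if (is.null(homology)) stop("homology table required with homologGenome")
    hmap <- .homologMap(homology, genome, homologGenome)
    hitsB <- store@hits[[homologGenome]]
    byAccB <- split(hitsB, stripVersion(hitsB$accession))
    keep <- vapply(acc, function(a) {
      hs <- hmap[[stripVersion(a)]]
      if (is.null(hs)) return(FALSE)
      any(vapply(hs, function(hb) {
        hh <- byAccB[[hb]]
        !is.null(hh) && .evalQuery(query, hh)
      }, logical(1)))
    }, logical(1))
    acc <- acc[keep]
  }
  sort(acc)
}

#' Second-step query: all hits on one promoter
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id.
#' @param accession promoter accession.
#' @return the promoter's complete hit table (union of layers), sorted by
#'   position, feature and strand.
#' @export
hitsForGene <- function(store, genome, accession) {
  .checkGenome(store, genome)
  ps <- store@promoters[[genome]]
  if (!accession %in% ps@info$accession)
    stop("unknown accession: ", accession)
  h <- store@hits[[genome]]
  h <- h[h$accession == accession, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Cross-genome conserved-hit filter
#'
#' Accessions in genome A whose promoter has at least one hit of the
#' feature, that belong to a homology group with a member in genome B, and
#' where at least one such homolog's promoter also carries a hit of the
#' feature. Genes without homologs are excluded regardless of their own
#' hits.
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genomeA,genomeB genome ids.
#' @param homology homology table (see \code{\link{readHomology}}).
#' @param featureId feature (motif) id.
#' @return sorted character vector of genome-A accessions.
#' @export
crossGenomeFilter <- function(store, genomeA, genomeB, homology, featureId) {
  queryGenes(store, genomeA, featureTerm(featureId),
             homologGenome = genomeB, homology = homology)
}

#' Match stored accessions against patterns
#'
#' Patterns are regular expressions applied to version-stripped accessions
#' (\code{"NM_000001$"} matches stored \code{"NM_000001.2"}). A pattern
#' anchored with a trailing \code{"$"} is also anchored at the start, so it
#' matches the full accession.
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id.
#' @param patterns character vector of patterns (e.g. a gene list file read
#'   with \code{\link{readGeneList}}).
#' @return sorted accessions (as stored) matching any pattern.
#' @export
matchAccessions <- function(store, genome, patterns) {
  .checkGenome(store, genome)
  acc <- store@promoters[[genome]]@info$accession
  stripped <- stripVersion(acc)
  hit <- rep(FALSE, length(acc))
  for (p in patterns) {
    p2 <- if (endsWith(p, "$") && !startsWith(p, "^")) paste0("^", p) else p
    m <- tryCatch(grepl(p2, stripped),
                  error = function(e)
                    stop("invalid pattern: '", p, "' (",
                         conditionMessage(e), ")"),
                  warning = function(w)
                    stop("invalid pattern: '", p, "' (",
                         conditionMessage(w), ")"))
    hit <- hit | m
  }
  sort(acc[hit])
}

#' Export hits for a set of genes as CSV
#'
#' One row per hit with genomic context:
#' \code{accession,genome,chrom,strand,feature_id,hit_strand,start_anchor,}
#' \code{end_anchor,gstart,gend,raw_score,norm_score,p_value}. Scores carry
#' 3 decimals, p-values scientific notation with 6 significant digits; rows
#' are sorted by accession, position, feature.
#'
#' @param store an \linkS4class{AnnotationStore}.
#' @param genome genome id.
#' @param accessions promoters to export (must exist in the store).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
exportCsv <- function(store, genome, accessions, path) {
  .checkGenome(store, genome)
  info <- store@promoters[[genome]]@info
  missing <- setdiff(accessions, info$accession)
  if (length(missing))
    stop("unknown accession(s): ", paste(missing, collapse = ", "))
  h <- store@hits[[genome]]
  h <- h[h$accession %in% accessions, , drop = FALSE]
  h <- h[order(h$accession, h$start_rel, h$feature_id), , drop = FALSE]
  j <- match(h$accession, info$accession)
  lines <- sprintf("%s,%s,%s,%s,%s,%s,%d,%d,%d,%d,%.3f,%.3f,%.5e",
                   h$accession, genome, info$chrom[j], info$strand[j],
                   h$feature_id, h$strand, h$start_anchor,
                   h$start_anchor + h$width, info$gstart[j], info$gend[j],
                   h$raw_score, h$norm_score, h$p_value)
  header <- paste("accession", "genome", "chrom", "strand", "feature_id",
                  "hit_strand", "start_anchor", "end_anchor", "gstart",
                  "gend", "raw_score", "norm_score", "p_value", sep = ",")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Read / write a homology table
#'
#' Tab-delimited homology groups: columns group_id, genome id, gene
#' accession (extra columns ignored). A (genome, accession) pair may appear
#' in only one group.
#'
#' @param path file path.
#' @return \code{readHomology}: data.frame with columns \code{group_id},
#'   \code{genome_id}, \code{accession}.
#' @export
readHomology <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("homology table needs >= 3 columns")
  df <- data.frame(group_id = as.integer(raw[[1]]),
                   genome_id = as.character(raw[[2]]),
                   accession = as.character(raw[[3]]),
                   stringsAsFactors = FALSE)
  key <- paste(df$genome_id, stripVersion(df$accession))
  if (anyDuplicated(key))
    stop("(genome, accession) pairs must be unique across homology groups")
  df
}

#' @rdname readHomology
#' @param homology homology data.frame.
#' @export
writeHomology <- function(homology, path) {
  write.table(homology[, c("group_id", "genome_id", "accession")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene list file
#'
#' Plain text, one accession pattern per line (commonly \code{"$"}-suffixed
#' to force full-length accession matches); empty lines dropped.
#'
#' @param path file path.
#' @return character vector of patterns.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
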