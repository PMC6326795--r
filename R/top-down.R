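## Phenotype-centric ("top-down") candidate generation: sentinel-flanking
## genes scored against curated annotation gene sets.

#' Sentinel-flanking genes by TSS window
#'
#' Returns the genes whose strand-aware transcription start site lies within
#' `window` bases of the sentinel position. The boundary is inclusive: a TSS
#' at exactly `pos +/- window` is retained.
#'
#' @param sentinel one-row sentinel data.frame (`rsid`, `chrom`, `pos`).
#' @param genes biotype-filtered gene model `GRanges`.
#' @param window half-window in bases (default 500000).
#' @return `GRanges` subset of flanking genes.
#' @export
flankingGenes <- function(sentinel, genes, window = 500000L) {
  stopifnot(window > 0)
  onchr <- as.character(GenomeInfoDb::seqnames(genes)) ==
    normalizeChrom(sentinel$chrom)
  genes[onchr & abs(geneTSS(genes) - sentinel$pos) <= window]
}

#' Score flanking genes against annotation sets
#'
#' Cross-references flanking genes against the loaded domain gene sets
#' (up to five sources). A gene found in at least one source becomes a
#' top-down candidate; its score is the number of distinct sources that list
#' it (1-5). Matching is on gene symbol (case-insensitive) or on gene_id,
#' per `matchKey`.
#'
#' @param flanking `GRanges` from [flankingGenes()].
#' @param annotationSets named list of character vectors
#'   (see [readAnnotationSets()]).
#' @param matchKey `"symbol"` (default) or `"gene_id"`.
#' @return data.frame `gene_id`, `symbol`, `sources` (';'-separated),
#'   `score`, ordered by decreasing score then gene_id.
#' @export
scoreGenes <- function(flanking, annotationSets, matchKey = "symbol") {
  key <- if (matchKey == "gene_id") flanking$gene_id else flanking$symbol
  keyN <- matchKeyNorm(key, caseInsensitive = matchKey == "symbol")
  inSource <- vapply(annotationSets, function(set) {
    keyN %in% matchKeyNorm(set, caseInsensitive = matchKey == "symbol")
  }, logical(length(keyN)))
  inSource <- matrix(inSource, nrow = length(keyN),
                     dimnames = list(NULL, names(annotationSets)))
  score <- as.integer(rowSums(inSource))
  hit <- score > 0L
  sources <- apply(inSource[hit, , drop = FALSE], 1L, function(row)
    paste(colnames(inSource)[row], collapse = ";"))
  out <- data.frame(gene_id = flanking$gene_id[hit],
                    symbol = flanking$symbol[hit],
                    sources = as.character(sources),
                    score = score[hit])
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn scoreGenes genes attaining the maximal top-down score at a
#'   locus (ties kept); empty input gives an empty set.
#' @param evidence data.frame as returned by `scoreGenes()`.
#' @export
topScoringGenes <- function(evidence) {
  if (!nrow(evidence)) return(character(0))
  sort(evidence$gene_id[evidence$score == max(evidence$score)])
}

#' @rdname report-accessors
#' @export
setMethod("topScoring", "data.frame", function(x) topScoringGenes(x))
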