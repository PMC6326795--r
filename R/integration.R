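## Integration of the two arms into per-locus reports and pipeline
## orchestration. Per-locus failures are isolated: a failing locus yields a
## report with status "error" and does not abort a batch run.

#' Concurrent candidate genes
#'
#' Genes identified by both the bottom-up and the top-down arm; these are
#' designated the most likely causal candidates.
#'
#' @param bu bottom-up evidence data.frame (from [assembleBottomUp()]).
#' @param td top-down evidence data.frame (from [scoreGenes()]).
#' @return sorted character vector of gene_ids.
#' @export
concurrentGenes <- function(bu, td) sort(intersect(bu$gene_id, td$gene_id))

#' Nearest-concurrent assignment
#'
#' Assigns exactly one gene to a locus: (i) when the locus has concurrent
#' candidates, the concurrent gene nearest to the sentinel; (ii) when it has
#' none, the gene nearest to the sentinel overall. Ties are broken like
#' [nearestGenes()] (distance, gene start, gene_id).
#'
#' @param concurrentIds character vector of concurrent gene_ids (may be empty).
#' @param sentinel one-row sentinel data.frame.
#' @param genes biotype-filtered gene model `GRanges`.
#' @param distanceTo `"body"` or `"tss"`.
#' @return a single gene_id.
#' @export
nearestConcurrentGene <- function(concurrentIds, sentinel, genes,
                                  distanceTo = "body") {
  rk <- .rankedGenes(sentinel, genes, distanceTo)
  if (is.null(rk))
    .fail("sentinel %s: no genes on chromosome %s; cannot assign a nearest gene",
          sentinel$rsid, sentinel$chrom)
  ids <- rk$genes$gene_id
  if (length(concurrentIds)) {
    hit <- ids[ids %in% concurrentIds]
    ## concurrent genes can sit outside the gene model only if they entered
    ## via eQTL evidence; fall back to lexicographic order for those
    if (!length(hit)) return(sort(concurrentIds)[1L])
    hit[1L]
  } else {
    ids[1L]
  }
}

## Assemble one LocusReport (no error isolation; see runPipeline).
.buildLocusReport <- function(sentinel, genes, proxies, eqtls, consequences,
                              annotationSets, config) {
  onchr <- any(as.character(GenomeInfoDb::seqnames(genes)) ==
                 normalizeChrom(sentinel$chrom))
  if (!onchr) {
    warning(sprintf("sentinel %s: chromosome %s absent from the gene model",
                    sentinel$rsid, sentinel$chrom), call. = FALSE)
    return(new("LocusReport", sentinel = sentinel,
               bottomUp = assembleBottomUp(sentinel, genes[0], proxies,
                                           eqtls[0, ], consequences[0, ], config),
               topDown = data.frame(gene_id = character(0), symbol = character(0),
                                    sources = character(0), score = integer(0)),
               concurrent = character(0), topScoring = character(0),
               nearestConcurrent = NA_character_, status = "empty",
               message = "chromosome absent from gene model"))
  }
  bu <- assembleBottomUp(sentinel, genes, proxies, eqtls, consequences, config)
  fl <- flankingGenes(sentinel, genes, window = config@window)
  td <- scoreGenes(fl, annotationSets, matchKey = config@matchKey)
  conc <- concurrentGenes(bu, td)
  new("LocusReport",
      sentinel = sentinel,
      bottomUp = bu,
      topDown = td,
      concurrent = conc,
      topScoring = topScoringGenes(td),
      nearestConcurrent = nearestConcurrentGene(conc, sentinel, genes,
                                                config@nearestDistance),
      status = "ok", message = "")
}

#' Run the full candidate-gene pipeline
#'
#' Produces one [LocusReport-class] per sentinel: bottom-up and top-down
#' candidate sets, their concurrent intersection, the top-scoring top-down
#' genes and the nearest-concurrent assignment. The run is deterministic
#' given identical inputs and configuration, and invariant to input row
#' order. A failure at one locus is logged on that locus's report (status
#' `"error"`) and does not abort the batch.
#'
#' @param sentinels sentinel data.frame (see [readSentinels()]).
#' @param genes gene model `GRanges` (see [readGeneModel()]); the configured
#'   biotype filter is (re-)applied here.
#' @param proxies proxy data.frame, already r2-filtered
#'   (see [readProxies()]).
#' @param consequences deduplicated consequence data.frame.
#' @param eqtls significance-filtered eQTL data.frame.
#' @param annotationSets named list of annotation gene sets (1-5 sources).
#' @param config a [QtlConfig-class].
#' @return a [LocusReportList-class], one report per sentinel, in sentinel
#'   order (sorted by rsid).
#' @export
#' @examples
#' loci <- exampleLoci()
#' reports <- runPipeline(loci$sentinels, loci$genes, loci$proxies,
#'                        loci$consequences, loci$eqtls, loci$annotationSets)
#' concurrent(reports[["rs1801133"]])
runPipeline <- function(sentinels, genes, proxies, consequences, eqtls,
                        annotationSets, config = qtlConfig()) {
  stopifnot(is(config, "QtlConfig"))
  genes <- filterBiotype(genes, config@biotypeFilter)
  if (length(annotationSets) > 5L)
    .fail("more than five annotation sources loaded")
  sentinels <- sentinels[order(sentinels$rsid), , drop = FALSE]
  reports <- lapply(seq_len(nrow(sentinels)), function(i) {
    s <- sentinels[i, , drop = FALSE]
    rownames(s) <- NULL
    tryCatch(
      .buildLocusReport(s, genes, proxies, eqtls, consequences,
                        annotationSets, config),
      error = function(e) {
        warning(sprintf("locus %s failed: %s", s$rsid, conditionMessage(e)),
                call. = FALSE)
        new("LocusReport", sentinel = s,
            bottomUp = data.frame(gene_id = character(0), symbol = character(0),
                                  ld_overlap = logical(0), nearest_rank = integer(0),
                                  eqtl_sentinel_tissues = character(0),
                                  eqtl_proxy_tissues = character(0),
                                  impact_sentinel = character(0),
                                  impact_proxy = character(0)),
            topDown = data.frame(gene_id = character(0), symbol = character(0),
                                 sources = character(0), score = integer(0)),
            concurrent = character(0), topScoring = character(0),
            nearestConcurrent = NA_character_, status = "error",
            message = conditionMessage(e))
      })
  })
  LocusReportList(reports, config = config)
}
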