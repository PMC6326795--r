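#' Pipeline configuration
#'
#' Holds the tunable parameters of the candidate-gene pipeline. Defaults follow
#' the framework's standard settings: three nearest protein-coding genes, a
#' +/- 500 kb transcription-start-site window for flanking genes, an LD proxy
#' threshold of r2 >= 0.8, +/- 5 kb padding on the LD range, and pre-filtered
#' (FDR 0.05 upstream) cis-eQTL input.
#'
#' @slot kNearest integer, number of nearest genes reported per sentinel.
#' @slot window integer, half-width in bases of the TSS flanking window.
#' @slot r2Threshold numeric, inclusive LD r-squared cutoff for proxies.
#' @slot ldPad integer, bases of padding added to each side of the LD span.
#' @slot eqtlMode `"prefiltered"` (rows are already significant) or
#'   `"threshold"` (filter on a p-value column at read time).
#' @slot eqtlThreshold numeric, p-value cutoff used in `"threshold"` mode.
#' @slot biotypeFilter character vector of gene biotypes retained, or
#'   `character(0)` to keep all biotypes.
#' @slot includeSentinel logical, whether the sentinel position participates in
#'   the LD span (it is its own r2 = 1 proxy); the no-proxy fallback is then a
#'   special case of the general rule.
#' @slot nearestDistance `"body"` (distance to the closed gene interval) or
#'   `"tss"` (distance to the strand-aware TSS).
#' @slot matchKey `"symbol"` or `"gene_id"`: key used to match genes against
#'   annotation sets (symbols matched case-insensitively).
#' @seealso [qtlConfig()]
#' @export
setClass("QtlConfig", representation(
  kNearest = "integer",
  window = "integer",
  r2Threshold = "numeric",
  ldPad = "integer",
  eqtlMode = "character",
  eqtlThreshold = "numeric",
  biotypeFilter = "character",
  includeSentinel = "logical",
  nearestDistance = "character",
  matchKey = "character"
))

setValidity("QtlConfig", function(object) {
  msg <- character(0)
  if (object@kNearest < 1L) msg <- c(msg, "kNearest must be >= 1")
  if (object@window < 1L) msg <- c(msg, "window must be positive")
  if (object@ldPad < 0L) msg <- c(msg, "ldPad must be non-negative")
  if (object@r2Threshold < 0 || object@r2Threshold > 1)
    msg <- c(msg, "r2Threshold must be in [0, 1]")
  if (!object@eqtlMode %in% c("prefiltered", "threshold"))
    msg <- c(msg, "eqtlMode must be 'prefiltered' or 'threshold'")
  if (!object@nearestDistance %in% c("body", "tss"))
    msg <- c(msg, "nearestDistance must be 'body' or 'tss'")
  if (!object@matchKey %in% c("symbol", "gene_id"))
    msg <- c(msg, "matchKey must be 'symbol' or 'gene_id'")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param kNearest number of nearest genes per sentinel (default 3).
#' @param window TSS flanking half-window in bases (default 500000).
#' @param r2Threshold inclusive proxy r-squared cutoff (default 0.8).
#' @param ldPad LD-range padding in bases (default 5000).
#' @param eqtlMode `"prefiltered"` or `"threshold"`.
#' @param eqtlThreshold p-value cutoff for `"threshold"` mode (default 0.05).
#' @param biotypeFilter biotypes kept in the gene model (default
#'   `"protein_coding"`); use `character(0)` (or `NULL`) to disable filtering.
#' @param includeSentinel include the sentinel position in the LD span
#'   (default `TRUE`).
#' @param nearestDistance `"body"` or `"tss"` (default `"body"`).
#' @param matchKey `"symbol"` or `"gene_id"` (default `"symbol"`).
#' @return a [QtlConfig-class] object.
#' @export
#' @examples
#' qtlConfig()
#' qtlConfig(window = 1e6, biotypeFilter = NULL)  # maximal-sensitivity settings
qtlConfig <- function(kNearest = 3L, window = 500000L, r2Threshold = 0.8,
                      ldPad = 5000L, eqtlMode = c("prefiltered", "threshold"),
                      eqtlThreshold = 0.05,
                      biotypeFilter = "protein_coding",
                      includeSentinel = TRUE,
                      nearestDistance = c("body", "tss"),
                      matchKey = c("symbol", "gene_id")) {
  new("QtlConfig",
      kNearest = as.integer(kNearest),
      window = as.integer(window),
      r2Threshold = as.numeric(r2Threshold),
      ldPad = as.integer(ldPad),
      eqtlMode = match.arg(eqtlMode),
      eqtlThreshold = as.numeric(eqtlThreshold),
      biotypeFilter = if (is.null(biotypeFilter)) character(0) else as.character(biotypeFilter),
      includeSentinel = isTRUE(includeSentinel),
      nearestDistance = match.arg(nearestDistance),
      matchKey = match.arg(matchKey))
}

setMethod("show", "QtlConfig", function(object) {
  cat("QtlConfig\n")
  cat("  kNearest:       ", object@kNearest, "\n")
  cat("  window:         +/-", object@window, "bp (TSS)\n")
  cat("  r2Threshold:    >=", object@r2Threshold, "\n")
  cat("  ldPad:          +/-", object@ldPad, "bp\n")
  cat("  eqtlMode:       ", object@eqtlMode,
      if (object@eqtlMode == "threshold") paste0("(p <= ", object@eqtlThreshold, ")") else "",
      "\n")
  cat("  biotypeFilter:  ",
      if (length(object@biotypeFilter)) paste(object@biotypeFilter, collapse = ", ")
      else "<none: all biotypes>", "\n")
  cat("  nearestDistance:", object@nearestDistance,
      " matchKey:", object@matchKey, "\n")
})

#' Per-locus candidate gene report
#'
#' The integrated output of the pipeline for one sentinel variant: the
#' bottom-up evidence table, the top-down evidence table, the concurrent gene
#' set (their intersection), the top-scoring top-down genes, and the single
#' nearest-concurrent assignment.
#'
#' @slot sentinel one-row data.frame: `rsid`, `chrom`, `pos`, `trait`.
#' @slot bottomUp data.frame, one row per bottom-up candidate with columns
#'   `gene_id`, `symbol`, `ld_overlap`, `nearest_rank`, `eqtl_sentinel_tissues`,
#'   `eqtl_proxy_tissues`, `impact_sentinel`, `impact_proxy`.
#' @slot topDown data.frame, one row per top-down candidate with columns
#'   `gene_id`, `symbol`, `sources`, `score`.
#' @slot concurrent character, gene_ids in both arms.
#' @slot topScoring character, gene_ids attaining the maximal top-down score.
#' @slot nearestConcurrent character scalar, the single per-locus assignment
#'   (`NA` when the locus failed).
#' @slot status `"ok"`, `"empty"` or `"error"`.
#' @slot message diagnostic message for non-ok loci.
#' @export
setClass("LocusReport", representation(
  sentinel = "data.frame",
  bottomUp = "data.frame",
  topDown = "data.frame",
  concurrent = "character",
  topScoring = "character",
  nearestConcurrent = "character",
  status = "character",
  message = "character"
))

setValidity("LocusReport", function(object) {
  msg <- character(0)
  if (nrow(object@sentinel) != 1L)
    msg <- c(msg, "sentinel must be a one-row data.frame")
  bu <- object@bottomUp$gene_id
  td <- object@topDown$gene_id
  if (!setequal(object@concurrent, intersect(bu, td)))
    msg <- c(msg, "concurrent must equal intersect(bottomUp, topDown)")
  if (length(object@concurrent) && object@status == "ok" &&
      !all(object@nearestConcurrent %in% object@concurrent) &&
      !is.na(object@nearestConcurrent))
    msg <- c(msg, "nearestConcurrent must be a concurrent gene when any exist")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocusReport", function(object) {
  s <- object@sentinel
  cat(sprintf("LocusReport for %s (%s:%s) [%s]\n", s$rsid, s$chrom,
              format(s$pos, big.mark = ","), object@status))
  cat(sprintf("  bottom-up: %d gene(s); top-down: %d gene(s)\n",
              nrow(object@bottomUp), nrow(object@topDown)))
  cat("  concurrent:        ",
      if (length(object@concurrent)) paste(sort(object@concurrent), collapse = ", ")
      else "<none>", "\n")
  cat("  nearest-concurrent:", object@nearestConcurrent, "\n")
})

#' List of per-locus reports
#'
#' A `SimpleList` of [LocusReport-class] objects, one per sentinel, carrying
#' the [QtlConfig-class] used to produce them in `metadata(x)$config`.
#' @importClassesFrom S4Vectors SimpleList
#' @export
setClass("LocusReportList", contains = "SimpleList",
         prototype = prototype(elementType = "LocusReport"))

#' @param reports list of `LocusReport`.
#' @param config the `QtlConfig` the reports were produced with.
#' @rdname LocusReportList-class
#' @export
LocusReportList <- function(reports = list(), config = qtlConfig()) {
  ans <- new("LocusReportList", S4Vectors::SimpleList(reports))
  names(ans) <- vapply(reports, function(r) r@sentinel$rsid, character(1))
  S4Vectors::metadata(ans)$config <- config
  ans
}

setMethod("show", "LocusReportList", function(object) {
  cat(sprintf("LocusReportList with %d locus report(s)\n", length(object)))
  st <- table(vapply(object, function(r) r@status, character(1)))
  cat("  status:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  if (length(object)) {
    nconc <- vapply(object, function(r) length(r@concurrent), integer(1))
    cat(sprintf("  concurrent genes per locus: median %g [%d, %d]\n",
                stats::median(nconc), min(nconc), max(nconc)))
  }
})
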