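#' Accessors for locus reports
#'
#' `bottomUp()`, `topDown()`, `concurrent()`, `topScoring()` and
#' `nearestConcurrent()` extract the corresponding evidence from a
#' [LocusReport-class] or, row-bound across loci with a `sentinel_rsid`
#' column, from a [LocusReportList-class].
#'
#' @param x a `LocusReport` or `LocusReportList`.
#' @return For a `LocusReport`: the slot content (data.frame or character
#'   vector). For a `LocusReportList`: a combined data.frame with a
#'   `sentinel_rsid` column.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("bottomUp", function(x) standardGeneric("bottomUp"))
#' @rdname report-accessors
#' @export
setGeneric("topDown", function(x) standardGeneric("topDown"))
#' @rdname report-accessors
#' @export
setGeneric("concurrent", function(x) standardGeneric("concurrent"))
#' @rdname report-accessors
#' @export
setGeneric("topScoring", function(x) standardGeneric("topScoring"))
#' @rdname report-accessors
#' @export
setGeneric("nearestConcurrent", function(x) standardGeneric("nearestConcurrent"))

#' @rdname report-accessors
#' @export
setMethod("bottomUp", "LocusReport", function(x) x@bottomUp)
#' @rdname report-accessors
#' @export
setMethod("topDown", "LocusReport", function(x) x@topDown)
#' @rdname report-accessors
#' @export
setMethod("concurrent", "LocusReport", function(x) x@concurrent)
#' @rdname report-accessors
#' @export
setMethod("topScoring", "LocusReport", function(x) x@topScoring)
#' @rdname report-accessors
#' @export
setMethod("nearestConcurrent", "LocusReport", function(x) x@nearestConcurrent)

.bindReports <- function(x, slotName) {
  parts <- lapply(seq_along(x), function(i) {
    r <- x[[i]]
    df <- slot(r, slotName)
    if (is.character(df))
      df <- if (length(df)) data.frame(gene_id = df) else
        data.frame(gene_id = character(0))
    if (!nrow(df)) return(NULL)
    cbind(sentinel_rsid = r@sentinel$rsid, df, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(sentinel_rsid = character(0), gene_id = character(0)))
  }
  ans <- do.call(rbind, parts)
  rownames(ans) <- NULL
  ans
}

#' @rdname report-accessors
#' @export
setMethod("bottomUp", "LocusReportList", function(x) .bindReports(x, "bottomUp"))
#' @rdname report-accessors
#' @export
setMethod("topDown", "LocusReportList", function(x) .bindReports(x, "topDown"))
#' @rdname report-accessors
#' @export
setMethod("concurrent", "LocusReportList", function(x) .bindReports(x, "concurrent"))
#' @rdname report-accessors
#' @export
setMethod("nearestConcurrent", "LocusReportList", function(x) {
  data.frame(
    sentinel_rsid = vapply(x, function(r) r@sentinel$rsid, character(1)),
    gene_id = vapply(x, function(r) r@nearestConcurrent, character(1)),
    row.names = NULL)
})
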