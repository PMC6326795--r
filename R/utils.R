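## Internal helpers shared across the package.

#' @importFrom methods is new validObject slot
#' @importFrom stats fisher.test runif rpois setNames
#' @importFrom utils read.delim write.table
NULL

IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

## Numeric severity; larger = more severe.
impactRank <- function(x) match(x, IMPACT_LEVELS)

#' Normalize a chromosome label
#'
#' Strips a leading "chr" prefix (any case) so that "chr1", "Chr1" and "1"
#' compare equal, and maps "MT"/"chrM" to "MT". Labels are otherwise kept
#' verbatim (autosomes, X, Y).
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalizeChrom(c("chr1", "1", "chrX"))
normalizeChrom <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x[x %in% c("M", "m")] <- "MT"
  x
}

## Case-insensitive key used when matching annotation-set members.
matchKeyNorm <- function(x, caseInsensitive = TRUE) {
  if (caseInsensitive) toupper(as.character(x)) else as.character(x)
}

## stopifnot with a formatted message
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.checkCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .fail("%s: missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

## Collapse a character vector into a single ';'-separated field (NA if empty)
.collapse <- function(x) {
  x <- unique(x[!is.na(x)])
  if (!length(x)) NA_character_ else paste(sort(x), collapse = ";")
}

.uncollapse <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}
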