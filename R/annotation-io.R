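## Readers and writers for all tabular inputs and the per-locus output tables.
## All intervals are 1-based inclusive (GTF convention); chromosome labels are
## normalized so that "chr1" and "1" compare equal. Every reader accepts
## plain or gzip-compressed files.

#' Read a gene model from a GTF file
#'
#' Parses an Ensembl-dialect GTF and returns one range per gene, optionally
#' restricted to a set of biotypes (default: protein-coding genes only, which
#' can be disabled for maximal sensitivity at the cost of more candidates).
#' When the file carries no `gene` features, gene ranges are derived as the
#' per-gene span of transcript/exon features.
#'
#' @param path GTF file (optionally gzipped).
#' @param biotypeFilter character vector of biotypes to keep, or `NULL` /
#'   `character(0)` to keep all genes.
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `symbol`, `biotype`; strand is `+` or `-`; the strand-aware TSS is
#'   available via [geneTSS()].
#' @export
#' @examples
#' gtf <- system.file("extdata", "toy_genes.gtf", package = "qtlCandidates")
#' readGeneModel(gtf)                       # protein-coding only
#' readGeneModel(gtf, biotypeFilter = NULL) # all biotypes
readGeneModel <- function(path, biotypeFilter = "protein_coding") {
  .checkGtfLines(path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) .fail("failed to parse GTF '%s': %s",
                                           path, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    genes <- gr[md$type == "gene"]
  } else {
    ## derive gene spans from sub-gene features
    if (!"gene_id" %in% names(md))
      .fail("GTF '%s' has neither gene features nor gene_id attributes", path)
    idx <- split(seq_along(gr), md$gene_id)
    st <- vapply(idx, function(i) min(GenomicRanges::start(gr)[i]), numeric(1))
    en <- vapply(idx, function(i) max(GenomicRanges::end(gr)[i]), numeric(1))
    first <- vapply(idx, `[[`, integer(1), 1L)
    genes <- GenomicRanges::GRanges(
      seqnames = as.character(GenomeInfoDb::seqnames(gr))[first],
      ranges = IRanges::IRanges(st, en),
      strand = as.character(GenomicRanges::strand(gr))[first])
    S4Vectors::mcols(genes)$gene_id <- names(idx)
    for (col in c("gene_name", "gene_biotype", "gene_type"))
      if (col %in% names(md))
        S4Vectors::mcols(genes)[[col]] <- md[[col]][first]
    names(genes) <- NULL
  }
  md <- S4Vectors::mcols(genes)
  symbol <- if ("gene_name" %in% names(md)) md$gene_name else md$gene_id
  biotype <- if ("gene_biotype" %in% names(md)) md$gene_biotype
             else if ("gene_type" %in% names(md)) md$gene_type
             else rep(NA_character_, length(genes))
  out <- GenomicRanges::GRanges(
    seqnames = normalizeChrom(as.character(GenomeInfoDb::seqnames(genes))),
    ranges = IRanges::ranges(genes),
    strand = GenomicRanges::strand(genes),
    gene_id = md$gene_id,
    symbol = ifelse(is.na(symbol), md$gene_id, symbol),
    biotype = biotype)
  if (anyDuplicated(out$gene_id))
    .fail("GTF '%s': duplicated gene_id(s): %s", path,
          paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  out <- filterBiotype(out, biotypeFilter)
  if (!length(out))
    .fail("GTF '%s': no genes left after biotype filter (%s)", path,
          paste(biotypeFilter, collapse = ", "))
  out
}

## Light pre-validation so malformed lines are reported with a line number
## (rtracklayer's parser errors do not carry one).
.checkGtfLines <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    chunk <- readLines(con, n = 5000L)
    if (!length(chunk)) break
    for (j in seq_along(chunk)) {
      i <- i + 1L
      ln <- chunk[j]
      if (!nzchar(ln) || startsWith(ln, "#")) next
      nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
      if (nf < 9L)
        .fail("GTF '%s': line %d has %d tab-separated fields (expected 9)",
              path, i, nf)
    }
  }
  invisible(TRUE)
}

#' Restrict a gene model to a set of biotypes
#'
#' @param genes gene model `GRanges` (as from [readGeneModel()]).
#' @param biotypeFilter biotypes to keep; `NULL` or `character(0)` keeps all.
#' @return the filtered `GRanges`.
#' @export
filterBiotype <- function(genes, biotypeFilter = "protein_coding") {
  if (is.null(biotypeFilter) || !length(biotypeFilter)) return(genes)
  genes[!is.na(genes$biotype) & genes$biotype %in% biotypeFilter]
}

#' Strand-aware transcription start sites
#'
#' The TSS is the 5' end of the gene on its strand: `start` for `+` genes,
#' `end` for `-` genes.
#'
#' @param genes gene model `GRanges`.
#' @return integer vector of TSS positions, parallel to `genes`.
#' @export
geneTSS <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Read sentinel variants
#'
#' @param path tab-delimited file with columns `rsid`, `chrom`, `pos` and
#'   optionally `trait`.
#' @return data.frame with columns `rsid`, `chrom` (normalized), `pos`
#'   (integer), `trait`.
#' @export
readSentinels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .checkCols(df, c("rsid", "chrom", "pos"), "sentinel table")
  if (!"trait" %in% names(df)) df$trait <- NA_character_
  if (anyDuplicated(df$rsid))
    .fail("sentinel table '%s': duplicate rsid(s): %s", path,
          paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "))
  if (any(df$pos < 1)) .fail("sentinel table '%s': positions must be >= 1", path)
  data.frame(rsid = as.character(df$rsid), chrom = normalizeChrom(df$chrom),
             pos = as.integer(df$pos), trait = as.character(df$trait))
}

#' Read LD proxies, filtering on r-squared
#'
#' Rows with `r2` below the threshold are dropped; the comparison is
#' inclusive, so a proxy at exactly the threshold (default r2 = 0.8) is kept.
#'
#' @param path tab-delimited file with columns `sentinel_rsid`, `rsid`,
#'   `chrom`, `pos`, `r2`.
#' @param r2Threshold inclusive lower bound on r2 (default 0.8).
#' @param sentinels optional sentinel data.frame; proxies referencing unknown
#'   sentinels trigger a warning but are kept (they drop out at join time).
#' @return data.frame of retained proxies with normalized chromosomes.
#' @export
readProxies <- function(path, r2Threshold = 0.8, sentinels = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(sentinel_rsid = character(0), rsid = character(0),
                      chrom = character(0), pos = integer(0), r2 = numeric(0)))
  }
  .checkCols(df, c("sentinel_rsid", "rsid", "chrom", "pos", "r2"), "proxy table")
  if (any(is.na(df$r2)) || any(df$r2 < 0 | df$r2 > 1))
    .fail("proxy table '%s': r2 values must lie in [0, 1]", path)
  if (!is.null(sentinels)) {
    unknown <- setdiff(df$sentinel_rsid, sentinels$rsid)
    if (length(unknown))
      warning(sprintf("proxy table '%s': %d row(s) reference unknown sentinel(s): %s",
                      path, sum(df$sentinel_rsid %in% unknown),
                      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  df <- df[df$r2 >= r2Threshold, , drop = FALSE]
  data.frame(sentinel_rsid = as.character(df$sentinel_rsid),
             rsid = as.character(df$rsid), chrom = normalizeChrom(df$chrom),
             pos = as.integer(df$pos), r2 = as.numeric(df$r2))
}

#' Read per-gene variant consequences
#'
#' Reads a VEP-style tabular file of per-gene consequences and keeps, for each
#' (variant, gene) pair, the single record with the most severe IMPACT
#' (HIGH > MODERATE > LOW > MODIFIER). Severity is taken from the IMPACT
#' column, never re-derived from consequence terms.
#'
#' @param path tab-delimited file with columns `variant_rsid`, `gene_id`,
#'   `consequence`, `impact`.
#' @return deduplicated data.frame, one row per (variant, gene).
#' @export
readConsequences <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(variant_rsid = character(0), gene_id = character(0),
                      consequence = character(0), impact = character(0)))
  }
  .checkCols(df, c("variant_rsid", "gene_id", "consequence", "impact"),
             "consequence table")
  bad <- setdiff(unique(df$impact), IMPACT_LEVELS)
  if (length(bad))
    .fail("consequence table '%s': invalid IMPACT value(s): %s (must be one of %s)",
          path, paste(bad, collapse = ", "), paste(IMPACT_LEVELS, collapse = ", "))
  ## keep the most severe record per (variant, gene); stable order tie-break
  ord <- order(df$variant_rsid, df$gene_id, -impactRank(df$impact))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df[c("variant_rsid", "gene_id")]), , drop = FALSE]
  rownames(df) <- NULL
  data.frame(variant_rsid = as.character(df$variant_rsid),
             gene_id = as.character(df$gene_id),
             consequence = as.character(df$consequence),
             impact = as.character(df$impact))
}

#' Read significant cis-eQTL variant-gene associations
#'
#' In `"prefiltered"` mode (the default; e.g. GTEx significant-pair files,
#' already filtered to beta-distribution-adjusted empirical p-values at
#' FDR 0.05) all rows are kept as significant. In `"threshold"` mode rows are
#' kept when `p_value <= threshold`.
#'
#' @param path tab-delimited file with columns `variant_rsid`, `gene_id` and
#'   (recommended) `tissue`; `"threshold"` mode also requires `p_value`.
#' @param mode `"prefiltered"` or `"threshold"`.
#' @param threshold p-value cutoff in `"threshold"` mode (default 0.05;
#'   inclusive).
#' @return data.frame with columns `variant_rsid`, `gene_id`, `tissue`.
#' @export
readEqtls <- function(path, mode = c("prefiltered", "threshold"),
                      threshold = 0.05) {
  mode <- match.arg(mode)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(variant_rsid = character(0), gene_id = character(0),
                      tissue = character(0)))
  }
  .checkCols(df, c("variant_rsid", "gene_id"), "eQTL table")
  if (!"tissue" %in% names(df)) {
    warning(sprintf("eQTL table '%s': no tissue column; using 'unspecified'",
                    path), call. = FALSE)
    df$tissue <- "unspecified"
  }
  if (mode == "threshold") {
    .checkCols(df, "p_value", "eQTL table (threshold mode)")
    df <- df[df$p_value <= threshold, , drop = FALSE]
  }
  data.frame(variant_rsid = as.character(df$variant_rsid),
             gene_id = as.character(df$gene_id),
             tissue = as.character(df$tissue))
}

#' Read annotation gene sets
#'
#' Loads the curated domain gene lists (e.g. metabolism-related genes from
#' GO, KEGG, MGI, Orphanet and Reactome) against which flanking genes are
#' scored. Accepts either a single two-column `source`/`gene` file or a named
#' vector of per-source files (one symbol per line). At most five sources are
#' allowed, bounding the top-down score at 5.
#'
#' @param path two-column tab-delimited file (`source`, `gene`), or a named
#'   character vector of file paths, one per source.
#' @return named list of character vectors, one per source, duplicates
#'   collapsed (case-insensitively).
#' @export
readAnnotationSets <- function(path) {
  if (length(path) > 1L || !is.null(names(path))) {
    if (is.null(names(path)) || any(!nzchar(names(path))))
      .fail("per-source annotation files must be named by source")
    sets <- lapply(path, function(p) {
      x <- readLines(p)
      x[nzchar(trimws(x))]
    })
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    .checkCols(df, c("source", "gene"), "annotation-set table")
    sets <- split(as.character(df$gene), as.character(df$source))
  }
  if (length(sets) > 5L)
    .fail("more than five annotation sources (%d); the score is bounded at 5",
          length(sets))
  if (!length(sets)) .fail("no annotation sources found")
  sets <- lapply(sets, function(x) {
    x <- trimws(x)
    x <- x[!is.na(x) & nzchar(x)]
    x[!duplicated(matchKeyNorm(x))]
  })
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0L]
  if (length(empty))
    .fail("annotation source(s) with no members: %s", paste(empty, collapse = ", "))
  sets
}

#' Read reference causal-gene assignments
#'
#' @param path tab-delimited file with columns `sentinel_rsid`, `causal_gene`
#'   (symbol or gene_id, matching the configured key).
#' @return data.frame with one assignment per sentinel.
#' @export
readReference <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) .fail("reference table '%s' is empty", path)
  .checkCols(df, c("sentinel_rsid", "causal_gene"), "reference table")
  if (anyDuplicated(df$sentinel_rsid))
    .fail("reference table '%s': more than one assignment for sentinel(s): %s",
          path, paste(unique(df$sentinel_rsid[duplicated(df$sentinel_rsid)]),
                      collapse = ", "))
  data.frame(sentinel_rsid = as.character(df$sentinel_rsid),
             causal_gene = as.character(df$causal_gene))
}

#' Write and re-read per-locus report tables
#'
#' `writeLocusReports()` writes four tab-delimited tables into `dir`:
#' `bottom_up.tsv`, `top_down.tsv`, `concurrent.tsv` and
#' `nearest_concurrent.tsv`. `readLocusReports()` reads them back as
#' data.frames; a written-then-read run reproduces the in-memory candidate
#' sets per locus exactly.
#'
#' @param reports a [LocusReportList-class].
#' @param dir output directory (created if needed).
#' @return `writeLocusReports()` returns the four file paths invisibly;
#'   `readLocusReports()` returns a named list of data.frames.
#' @export
writeLocusReports <- function(reports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(bottom_up = bottomUp(reports),
               top_down = topDown(reports),
               concurrent = concurrent(reports),
               nearest_concurrent = nearestConcurrent(reports))
  paths <- file.path(dir, paste0(names(tabs), ".tsv"))
  for (i in seq_along(tabs))
    write.table(tabs[[i]], paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  invisible(setNames(paths, names(tabs)))
}

#' @param dir directory previously written by `writeLocusReports()`.
#' @rdname writeLocusReports
#' @export
readLocusReports <- function(dir) {
  nm <- c("bottom_up", "top_down", "concurrent", "nearest_concurrent")
  out <- lapply(nm, function(n) {
    p <- file.path(dir, paste0(n, ".tsv"))
    if (!file.exists(p)) .fail("missing report table: %s", p)
    read.delim(p, stringsAsFactors = FALSE, na.strings = "")
  })
  setNames(out, nm)
}
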