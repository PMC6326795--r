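## Benchmarking machinery: per-locus TP/FP/FN classification, sensitivity,
## the two specificity definitions (local-gene and candidate-gene true
## negatives), criterion-stratified Fisher's exact enrichment with Bonferroni
## correction, and locus-subset filters.

#' Classify one locus against its reference causal gene
#'
#' With one reference gene per locus: a captured reference gene is the locus's
#' single true positive and every other candidate is a false positive; a
#' missed reference gene is the locus's false negative and all candidates are
#' false positives.
#'
#' @param candidates character vector of candidate gene_ids at the locus.
#' @param referenceGene the locus's reference causal gene_id.
#' @return list with elements `tp` (0/1), `fp` (count), `fn` (0/1).
#' @export
classifyLocus <- function(candidates, referenceGene) {
  candidates <- unique(candidates)
  if (referenceGene %in% candidates) {
    list(tp = 1L, fp = length(candidates) - 1L, fn = 0L)
  } else {
    list(tp = 0L, fp = length(candidates), fn = 1L)
  }
}

#' Benchmark sensitivity
#'
#' Sensitivity as a percentage of loci whose reference causal gene was
#' captured: `(100 / n) * TP`.
#'
#' @param n number of benchmarked loci (> 0).
#' @param tp number of true positives (0 <= tp <= n).
#' @return sensitivity in percent (not rounded; round to the nearest integer
#'   for reporting).
#' @export
#' @examples
#' qtlSensitivity(227, 223)  # 98.24..., reported as 98%
qtlSensitivity <- function(n, tp) {
  if (n <= 0) .fail("sensitivity undefined for n = %s", n)
  stopifnot(tp >= 0, tp <= n)
  (100 / n) * tp
}

#' Benchmark specificity
#'
#' Specificity is `TN / (TN + FP)` where the true negatives are the
#' non-candidate genes among a benchmark universe: either all local genes
#' (`TN = sum(LG) - (TP + FP) - FN`, used for the overall pipeline) or all
#' pipeline candidates (`TN = sum(PG) - (TP + FP) - FN`, used when comparing
#' the bottom-up, top-down and concurrent components).
#'
#' @param tp,fp,fn aggregate counts over loci.
#' @param totalGenes the universe size: `sum(LG)` (local protein-coding genes
#'   within the window of each sentinel, summed over loci) or `sum(PG)` (all
#'   candidate instances).
#' @return specificity in [0, 1]; `NA` with a warning when `TN + FP = 0`
#'   (undefined).
#' @export
#' @examples
#' qtlSpecificity(10, 30, 2, 100)  # TN = 58; 58/88
qtlSpecificity <- function(tp, fp, fn, totalGenes) {
  if (totalGenes < tp + fp + fn)
    .fail("totalGenes (%s) smaller than TP + FP + FN (%s)", totalGenes,
          tp + fp + fn)
  tn <- totalGenes - (tp + fp) - fn
  if (tn + fp == 0) {
    warning("specificity undefined: TN + FP = 0", call. = FALSE)
    return(NA_real_)
  }
  tn / (tn + fp)
}

## ---- criterion-stratified candidate instance sets ------------------------

.instanceDf <- function(rsid, geneIds) {
  if (!length(geneIds))
    return(data.frame(sentinel_rsid = character(0), gene_id = character(0)))
  data.frame(sentinel_rsid = rsid, gene_id = geneIds)
}

## Most severe sentinel-derived IMPACT at a locus (NA when none recorded).
.locusSentinelImpact <- function(report) {
  x <- report@bottomUp$impact_sentinel
  x <- x[!is.na(x)]
  if (!length(x)) NA_character_ else IMPACT_LEVELS[max(impactRank(x))]
}

## Instance sets for one report, as a named list of gene_id vectors.
.locusCriteria <- function(r) {
  bu <- r@bottomUp
  td <- r@topDown
  out <- list(
    bottom_up = bu$gene_id,
    top_down = td$gene_id,
    concurrent = r@concurrent,
    nearest_concurrent = r@nearestConcurrent[!is.na(r@nearestConcurrent)],
    nearest = bu$gene_id[!is.na(bu$nearest_rank) & bu$nearest_rank == 1L],
    three_nearest = bu$gene_id[!is.na(bu$nearest_rank)],
    ld_overlap = bu$gene_id[bu$ld_overlap],
    eqtl_sentinel = bu$gene_id[!is.na(bu$eqtl_sentinel_tissues)],
    eqtl_proxy = bu$gene_id[!is.na(bu$eqtl_proxy_tissues)],
    eqtl_any = bu$gene_id[!is.na(bu$eqtl_sentinel_tissues) |
                            !is.na(bu$eqtl_proxy_tissues)]
  )
  for (lev in c("HIGH", "MODERATE", "LOW")) {
    out[[paste0("impact_sentinel_", lev)]] <-
      bu$gene_id[!is.na(bu$impact_sentinel) & bu$impact_sentinel == lev]
    out[[paste0("impact_proxy_", lev)]] <-
      bu$gene_id[!is.na(bu$impact_proxy) & bu$impact_proxy == lev]
  }
  ## per-tissue eQTL sets
  tiss <- unique(unlist(lapply(
    c(bu$eqtl_sentinel_tissues, bu$eqtl_proxy_tissues),
    function(x) if (is.na(x)) character(0) else .uncollapse(x))))
  for (t in tiss) {
    hit <- vapply(seq_len(nrow(bu)), function(i) {
      t %in% c(.uncollapse(bu$eqtl_sentinel_tissues[i] %||% NA_character_),
               .uncollapse(bu$eqtl_proxy_tissues[i] %||% NA_character_))
    }, logical(1))
    out[[paste0("eqtl_tissue_", t)]] <- bu$gene_id[hit]
  }
  ## per-source and score-level top-down sets
  if (nrow(td)) {
    srcs <- unique(unlist(lapply(td$sources, .uncollapse)))
    for (s in srcs) {
      hit <- vapply(td$sources, function(x) s %in% .uncollapse(x), logical(1))
      out[[paste0("td_", s)]] <- td$gene_id[hit]
    }
    for (s in sort(unique(td$score)))
      out[[paste0("td_score_ge", s)]] <- td$gene_id[td$score >= s]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Criterion-stratified candidate instance sets
#'
#' Builds, for each annotation criterion, the set of (locus, gene) candidate
#' instances satisfying it: nearest / three-nearest / LD-overlap, eQTL by
#' source-variant class and by tissue, sentinel- and proxy-IMPACT classes,
#' per-database and score-level top-down sets, and the bottom-up / top-down /
#' concurrent / nearest-concurrent sets themselves. The unit is the
#' (locus, gene) instance, so one gene can contribute at multiple loci.
#'
#' @param reports a [LocusReportList-class].
#' @param criteria optional character vector selecting criteria by label; an
#'   unknown label is an error. `NULL` returns all criteria present.
#' @param locusFilter optional predicate `function(LocusReport) -> logical`;
#'   loci for which it returns `FALSE` are dropped before set construction
#'   (e.g. excluding loci tagged by a moderate-impact sentinel).
#' @return named list of data.frames with columns `sentinel_rsid`, `gene_id`.
#' @export
criterionSets <- function(reports, criteria = NULL, locusFilter = NULL) {
  keep <- if (is.null(locusFilter)) rep(TRUE, length(reports))
          else vapply(reports, locusFilter, logical(1))
  sets <- list()
  for (r in as.list(reports)[keep]) {
    loc <- .locusCriteria(r)
    for (nm in names(loc))
      sets[[nm]] <- rbind(sets[[nm]] %||% .instanceDf(character(0), character(0)),
                          .instanceDf(r@sentinel$rsid, loc[[nm]]))
  }
  if (!is.null(criteria)) {
    unknown <- setdiff(criteria, names(sets))
    if (length(unknown))
      .fail("unknown criterion label(s): %s", paste(unknown, collapse = ", "))
    sets <- sets[criteria]
  }
  sets
}

#' Convenience locus filter: exclude loci by sentinel IMPACT class
#'
#' Returns a predicate for [criterionSets()]/[benchmarkRun()] that drops every
#' locus whose most severe sentinel-derived IMPACT is one of `levels` — e.g.
#' re-running the nearest-gene enrichment after removing loci tagged by a
#' moderate-impact sentinel.
#'
#' @param levels IMPACT classes to exclude.
#' @return `function(LocusReport) -> logical` (TRUE keeps the locus).
#' @export
excludeSentinelImpact <- function(levels = "MODERATE") {
  force(levels)
  function(report) {
    imp <- .locusSentinelImpact(report)
    is.na(imp) || !(imp %in% levels)
  }
}

## ---- Fisher's exact enrichment -------------------------------------------

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test] returning the two-sided p-value,
#' the conditional maximum-likelihood odds ratio and its exact 95% CI. A
#' table with a zero row or column margin is degenerate: p = 1 and the odds
#' ratio is undefined (flagged in `note`).
#'
#' @param a,b,c,d the 2x2 counts, row-wise: `a` criterion-and-true,
#'   `b` criterion-and-false, `c` other-and-true, `d` other-and-false.
#' @param sampleOr also report the sample (cross-product) odds ratio.
#' @param conf compute the exact 95% CI (set `FALSE` to skip the root
#'   finding when only the p-value is needed, e.g. in large sweeps).
#' @return one-row data.frame: `p`, `odds_ratio`, `ci_low`, `ci_high`,
#'   (`sample_or`,) `note`.
#' @export
fisherExact2x2 <- function(a, b, c, d, sampleOr = FALSE, conf = TRUE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  if (degenerate) {
    out <- data.frame(p = 1, odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, note = "degenerate-margin")
  } else {
    ft <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L),
                             conf.int = conf)
    out <- data.frame(p = ft$p.value, odds_ratio = unname(ft$estimate),
                      ci_low = if (conf) ft$conf.int[1L] else NA_real_,
                      ci_high = if (conf) ft$conf.int[2L] else NA_real_,
                      note = "")
  }
  if (sampleOr) out$sample_or <- (a * d) / (b * c)
  out
}

#' Enrichment of a criterion set with true positive causal genes
#'
#' Tests whether candidate instances satisfying a criterion are enriched with
#' reference causal genes, relative to a background of all remaining
#' candidate instances, by a two-sided Fisher's exact test. Bonferroni
#' correction uses the caller-supplied family size.
#'
#' @param criterionSet data.frame (`sentinel_rsid`, `gene_id`) of instances
#'   satisfying the criterion.
#' @param background data.frame of all candidate instances (the criterion set
#'   is subtracted internally to form "all remaining candidates").
#' @param reference data.frame (`sentinel_rsid`, `causal_gene`), gene_ids.
#' @param nTests Bonferroni family size (default 1).
#' @param label criterion label carried into the result.
#' @return one-row data.frame: `criterion`, the four 2x2 counts
#'   (`tp_in`, `fp_in`, `tp_out`, `fp_out`), `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_bonferroni`, `n_tests`, `note`.
#' @export
fisherEnrichment <- function(criterionSet, background, reference, nTests = 1L,
                             label = "criterion") {
  key <- function(df) paste(df$sentinel_rsid, df$gene_id, sep = "\r")
  refKey <- paste(reference$sentinel_rsid, reference$causal_gene, sep = "\r")
  inKeys <- unique(key(criterionSet))
  outKeys <- setdiff(unique(key(background)), inKeys)
  a <- sum(inKeys %in% refKey); b <- length(inKeys) - a
  c_ <- sum(outKeys %in% refKey); d <- length(outKeys) - c_
  ft <- fisherExact2x2(a, b, c_, d)
  data.frame(criterion = label, tp_in = a, fp_in = b, tp_out = c_, fp_out = d,
             odds_ratio = ft$odds_ratio, ci_low = ft$ci_low,
             ci_high = ft$ci_high, p_raw = ft$p,
             p_bonferroni = min(1, ft$p * nTests),
             n_tests = as.integer(nTests), note = ft$note)
}

## ---- orchestration -------------------------------------------------------

## Translate reference causal_gene values (symbols or gene_ids) to gene_ids.
.referenceIds <- function(reference, genes) {
  ids <- reference$causal_gene
  miss <- !(ids %in% genes$gene_id)
  if (any(miss)) {
    bySym <- genes$gene_id[match(matchKeyNorm(ids[miss]),
                                 matchKeyNorm(genes$symbol))]
    ids[miss][!is.na(bySym)] <- bySym[!is.na(bySym)]
  }
  data.frame(sentinel_rsid = reference$sentinel_rsid, causal_gene = ids)
}

#' Run the full benchmark over a set of locus reports
#'
#' Computes, for each candidate-set definition (total, bottom-up, top-down,
#' concurrent, nearest-concurrent), the aggregate TP/FP/FN counts, the
#' sensitivity, and the specificity — using the local-gene universe
#' (`sum(LG)`: biotype-filtered genes whose body lies within the window
#' around each sentinel) for the total set and the candidate universe
#' (`sum(PG)`) for the component sets — plus the criterion-stratified
#' enrichment table.
#'
#' @param reports a [LocusReportList-class].
#' @param reference reference assignments (`sentinel_rsid`, `causal_gene`;
#'   symbols or gene_ids). Loci without a reference are excluded with a
#'   warning.
#' @param genes the gene model `GRanges` used for the run (biotype filter
#'   re-applied per the reports' config).
#' @param nTests Bonferroni family size for the enrichment table; defaults to
#'   the number of criteria tested.
#' @param locusFilter optional predicate over `LocusReport` applied to the
#'   enrichment analysis only (see [excludeSentinelImpact()]).
#' @return list with `summary` (one row per candidate-set definition) and
#'   `enrichment` (one row per criterion) data.frames.
#' @export
benchmarkRun <- function(reports, reference, genes, nTests = NULL,
                         locusFilter = NULL) {
  config <- S4Vectors::metadata(reports)$config %||% qtlConfig()
  genes <- filterBiotype(genes, config@biotypeFilter)
  reference <- .referenceIds(reference, genes)

  have <- names(reports) %in% reference$sentinel_rsid
  if (!all(have)) {
    warning(sprintf("%d locus/loci without a reference assignment excluded: %s",
                    sum(!have), paste(names(reports)[!have], collapse = ", ")),
            call. = FALSE)
    reports <- LocusReportList(as.list(reports)[have], config = config)
  }
  n <- length(reports)
  if (!n) .fail("no benchmarkable loci (no reference assignments matched)")
  refGene <- setNames(reference$causal_gene, reference$sentinel_rsid)

  perLocusSets <- lapply(reports, function(r) list(
    total = union(r@bottomUp$gene_id, r@topDown$gene_id),
    bottom_up = r@bottomUp$gene_id,
    top_down = r@topDown$gene_id,
    concurrent = r@concurrent,
    nearest_concurrent = r@nearestConcurrent[!is.na(r@nearestConcurrent)]))

  ## universes for the two TN definitions
  sumLG <- sum(vapply(reports, function(r) {
    s <- r@sentinel
    sum(as.character(GenomeInfoDb::seqnames(genes)) == normalizeChrom(s$chrom) &
          GenomicRanges::start(genes) <= s$pos + config@window &
          GenomicRanges::end(genes) >= s$pos - config@window)
  }, numeric(1)))
  sumPG <- sum(vapply(perLocusSets, function(x) length(x$total), numeric(1)))

  summary <- do.call(rbind, lapply(
    c("total", "bottom_up", "top_down", "concurrent", "nearest_concurrent"),
    function(setName) {
      cls <- lapply(names(reports), function(rs)
        classifyLocus(perLocusSets[[rs]][[setName]], refGene[[rs]]))
      tp <- sum(vapply(cls, `[[`, integer(1), "tp"))
      fp <- sum(vapply(cls, `[[`, integer(1), "fp"))
      fn <- sum(vapply(cls, `[[`, integer(1), "fn"))
      mode <- if (setName == "total") "lg" else "pg"
      universe <- if (mode == "lg") max(sumLG, tp + fp + fn) else
        max(sumPG, tp + fp + fn)
      data.frame(set = setName, n = n, tp = tp, fp = fp, fn = fn,
                 mode = mode, universe = universe,
                 sensitivity = qtlSensitivity(n, tp),
                 specificity = suppressWarnings(
                   qtlSpecificity(tp, fp, fn, universe)))
    }))

  sets <- criterionSets(reports, locusFilter = locusFilter)
  keepLoci <- if (is.null(locusFilter)) names(reports) else
    names(reports)[vapply(reports, locusFilter, logical(1))]
  background <- do.call(rbind, lapply(keepLoci, function(rs)
    .instanceDf(rs, perLocusSets[[rs]]$total)))
  refDf <- data.frame(sentinel_rsid = keepLoci,
                      causal_gene = unname(refGene[keepLoci]))
  if (is.null(nTests)) nTests <- length(sets)
  enrichment <- do.call(rbind, lapply(names(sets), function(nm)
    fisherEnrichment(sets[[nm]], background, refDf, nTests = nTests,
                     label = nm)))
  rownames(summary) <- rownames(enrichment) <- NULL
  list(summary = summary, enrichment = enrichment)
}
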