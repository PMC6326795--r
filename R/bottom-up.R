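## Variant-centric ("bottom-up") candidate generation: LD-range overlap,
## k-nearest genes, cis-eQTL targets and coding-impact flags.

#' Build the LD range of a sentinel variant
#'
#' The LD range spans the left- and right-most positions of the sentinel's
#' proxies, padded by `pad` bases on each side and clipped at 1. The sentinel
#' position itself participates in the span by default (it is its own r2 = 1
#' proxy), which makes the no-proxy case — sentinel position +/- `pad` — a
#' special case of the general rule.
#'
#' @param sentinel one-row data.frame with `rsid`, `chrom`, `pos`.
#' @param proxies data.frame of this sentinel's proxies (may have zero rows).
#' @param pad padding in bases (default 5000).
#' @param includeSentinel include the sentinel position in the span
#'   (default `TRUE`).
#' @return one-row data.frame: `sentinel_rsid`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' s <- data.frame(rsid = "rs1", chrom = "1", pos = 1e6)
#' p <- data.frame(sentinel_rsid = "rs1", rsid = c("p1", "p2"), chrom = "1",
#'                 pos = c(990000, 1020000), r2 = c(0.9, 0.85))
#' buildLdRange(s, p)  # [985000, 1025000]
buildLdRange <- function(sentinel, proxies, pad = 5000L, includeSentinel = TRUE) {
  stopifnot(nrow(sentinel) == 1L)
  proxies <- proxies[proxies$sentinel_rsid == sentinel$rsid, , drop = FALSE]
  if (nrow(proxies)) {
    off <- which(normalizeChrom(proxies$chrom) != normalizeChrom(sentinel$chrom))
    if (length(off))
      .fail("sentinel %s: proxy(ies) %s on a different chromosome",
            sentinel$rsid, paste(proxies$rsid[off], collapse = ", "))
  }
  pos <- proxies$pos
  if (includeSentinel || !length(pos)) pos <- c(pos, sentinel$pos)
  data.frame(sentinel_rsid = sentinel$rsid,
             chrom = normalizeChrom(sentinel$chrom),
             start = max(1L, as.integer(min(pos) - pad)),
             end = as.integer(max(pos) + pad))
}

## Distance from a position to each gene; 0 inside the closed gene interval.
.geneDistance <- function(pos, genes, distanceTo = "body") {
  st <- GenomicRanges::start(genes)
  en <- GenomicRanges::end(genes)
  if (distanceTo == "tss") {
    abs(pos - geneTSS(genes))
  } else {
    ifelse(pos >= st & pos <= en, 0L, pmin(abs(pos - st), abs(pos - en)))
  }
}

## Genes on the sentinel's chromosome, ordered by (distance, start, gene_id).
.rankedGenes <- function(sentinel, genes, distanceTo = "body") {
  onchr <- genes[as.character(GenomeInfoDb::seqnames(genes)) ==
                   normalizeChrom(sentinel$chrom)]
  if (!length(onchr)) return(NULL)
  d <- .geneDistance(sentinel$pos, onchr, distanceTo)
  ord <- order(d, GenomicRanges::start(onchr), onchr$gene_id)
  list(genes = onchr[ord], distance = as.integer(d[ord]))
}

#' k nearest genes to a sentinel variant
#'
#' Distance is 0 when the sentinel lies inside the closed gene interval,
#' otherwise the distance to the closer gene edge (or, with
#' `distanceTo = "tss"`, to the strand-aware TSS). Ties are broken
#' deterministically by (distance, gene start, gene_id).
#'
#' @param sentinel one-row data.frame with `rsid`, `chrom`, `pos`.
#' @param genes gene model `GRanges`, already biotype-filtered.
#' @param k number of genes to report (default 3); fewer are returned when the
#'   chromosome holds fewer genes.
#' @param distanceTo `"body"` (default) or `"tss"`.
#' @return data.frame `gene_id`, `symbol`, `distance`, `rank` ordered by rank;
#'   zero rows (with a warning) when no gene shares the chromosome.
#' @export
nearestGenes <- function(sentinel, genes, k = 3L, distanceTo = "body") {
  stopifnot(k >= 1L)
  rk <- .rankedGenes(sentinel, genes, distanceTo)
  if (is.null(rk)) {
    warning(sprintf("sentinel %s: no genes on chromosome %s", sentinel$rsid,
                    sentinel$chrom), call. = FALSE)
    return(data.frame(gene_id = character(0), symbol = character(0),
                      distance = integer(0), rank = integer(0)))
  }
  n <- min(k, length(rk$genes))
  data.frame(gene_id = rk$genes$gene_id[seq_len(n)],
             symbol = rk$genes$symbol[seq_len(n)],
             distance = rk$distance[seq_len(n)],
             rank = seq_len(n))
}

#' Genes overlapping an LD range
#'
#' Intervals are closed on both sides; a single shared base suffices for
#' overlap.
#'
#' @param ldRange one-row data.frame from [buildLdRange()].
#' @param genes gene model `GRanges`.
#' @return `GRanges` subset of overlapping genes.
#' @export
ldOverlappingGenes <- function(ldRange, genes) {
  stopifnot(ldRange$start <= ldRange$end)
  hit <- as.character(GenomeInfoDb::seqnames(genes)) == ldRange$chrom &
    GenomicRanges::start(genes) <= ldRange$end &
    GenomicRanges::end(genes) >= ldRange$start
  genes[hit]
}

#' cis-eQTL target genes of a sentinel and its proxies
#'
#' Takes the union of significant eQTL target genes over the sentinel and all
#' of its proxies, across all tissues, recording per gene whether the
#' association came from the sentinel itself or a proxy, and in which tissues.
#'
#' @param sentinel one-row sentinel data.frame.
#' @param proxies proxy data.frame (any sentinels; filtered internally).
#' @param eqtls significance-filtered eQTL data.frame
#'   (`variant_rsid`, `gene_id`, `tissue`).
#' @return data.frame `gene_id`, `sentinel_tissues`, `proxy_tissues`
#'   (';'-separated, `NA` when absent), one row per target gene.
#' @export
eqtlTargetGenes <- function(sentinel, proxies, eqtls) {
  proxyIds <- proxies$rsid[proxies$sentinel_rsid == sentinel$rsid]
  hits <- eqtls[eqtls$variant_rsid %in% c(sentinel$rsid, proxyIds), , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(0), sentinel_tissues = character(0),
                      proxy_tissues = character(0)))
  }
  hits$fromSentinel <- hits$variant_rsid == sentinel$rsid
  out <- do.call(rbind, lapply(split(hits, hits$gene_id), function(h) {
    data.frame(gene_id = h$gene_id[1L],
               sentinel_tissues = .collapse(h$tissue[h$fromSentinel]),
               proxy_tissues = .collapse(h$tissue[!h$fromSentinel]))
  }))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Per-gene coding-impact flags
#'
#' For each gene with consequence records, reports the most severe IMPACT
#' among records from the sentinel and, separately, among records from any
#' proxy (HIGH > MODERATE > LOW > MODIFIER).
#'
#' @param sentinel one-row sentinel data.frame.
#' @param proxies proxy data.frame.
#' @param consequences deduplicated consequence data.frame
#'   (see [readConsequences()]).
#' @return data.frame `gene_id`, `impact_sentinel`, `impact_proxy`
#'   (`NA` where no record exists).
#' @export
impactFlags <- function(sentinel, proxies, consequences) {
  proxyIds <- proxies$rsid[proxies$sentinel_rsid == sentinel$rsid]
  cc <- consequences[consequences$variant_rsid %in% c(sentinel$rsid, proxyIds), ,
                     drop = FALSE]
  if (!nrow(cc)) {
    return(data.frame(gene_id = character(0), impact_sentinel = character(0),
                      impact_proxy = character(0)))
  }
  cc$fromSentinel <- cc$variant_rsid == sentinel$rsid
  worst <- function(x) if (length(x)) IMPACT_LEVELS[max(impactRank(x))] else NA_character_
  out <- do.call(rbind, lapply(split(cc, cc$gene_id), function(h) {
    data.frame(gene_id = h$gene_id[1L],
               impact_sentinel = worst(h$impact[h$fromSentinel]),
               impact_proxy = worst(h$impact[!h$fromSentinel]))
  }))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Assemble the bottom-up candidate set for one sentinel
#'
#' A gene is a bottom-up candidate when it meets at least one of three
#' criteria: it overlaps the sentinel's LD range, it is among the k nearest
#' genes, or it is a significant cis-eQTL target of the sentinel or a proxy.
#' Coding-impact flags are attached to members of the set.
#'
#' @param sentinel one-row sentinel data.frame.
#' @param genes biotype-filtered gene model `GRanges`.
#' @param proxies proxy data.frame.
#' @param eqtls significance-filtered eQTL data.frame.
#' @param consequences deduplicated consequence data.frame.
#' @param config a [QtlConfig-class].
#' @return data.frame with one row per candidate: `gene_id`, `symbol`,
#'   `ld_overlap`, `nearest_rank`, `eqtl_sentinel_tissues`,
#'   `eqtl_proxy_tissues`, `impact_sentinel`, `impact_proxy`.
#' @export
assembleBottomUp <- function(sentinel, genes, proxies, eqtls, consequences,
                             config = qtlConfig()) {
  rng <- buildLdRange(sentinel, proxies, pad = config@ldPad,
                      includeSentinel = config@includeSentinel)
  ldg <- ldOverlappingGenes(rng, genes)
  nst <- suppressWarnings(
    nearestGenes(sentinel, genes, k = config@kNearest,
                 distanceTo = config@nearestDistance))
  eqt <- eqtlTargetGenes(sentinel, proxies, eqtls)

  ids <- sort(unique(c(ldg$gene_id, nst$gene_id, eqt$gene_id)))
  if (!length(ids)) {
    return(data.frame(gene_id = character(0), symbol = character(0),
                      ld_overlap = logical(0), nearest_rank = integer(0),
                      eqtl_sentinel_tissues = character(0),
                      eqtl_proxy_tissues = character(0),
                      impact_sentinel = character(0),
                      impact_proxy = character(0)))
  }
  sym <- genes$symbol[match(ids, genes$gene_id)]
  sym[is.na(sym)] <- ids[is.na(sym)]   # eQTL targets outside the gene model
  imp <- impactFlags(sentinel, proxies, consequences)
  data.frame(
    gene_id = ids,
    symbol = sym,
    ld_overlap = ids %in% ldg$gene_id,
    nearest_rank = nst$rank[match(ids, nst$gene_id)],
    eqtl_sentinel_tissues = eqt$sentinel_tissues[match(ids, eqt$gene_id)],
    eqtl_proxy_tissues = eqt$proxy_tissues[match(ids, eqt$gene_id)],
    impact_sentinel = imp$impact_sentinel[match(ids, imp$gene_id)],
    impact_proxy = imp$impact_proxy[match(ids, imp$gene_id)])
}
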