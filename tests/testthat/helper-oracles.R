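# Independent oracles used to cross-check the implementation.

# exhaustive nearest-gene scan: distance to closed gene body, ties broken by
# (distance, start, gene_id)
bruteNearest <- function(pos, genes, k) {
  st <- GenomicRanges::start(genes)
  en <- GenomicRanges::end(genes)
  d <- integer(length(genes))
  for (i in seq_along(genes)) {
    d[i] <- if (pos >= st[i] && pos <= en[i]) 0L else
      min(abs(pos - st[i]), abs(pos - en[i]))
  }
  ord <- order(d, st, genes$gene_id)
  head(genes$gene_id[ord], k)
}

# exhaustive closed-interval overlap scan
bruteOverlap <- function(rstart, rend, genes) {
  keep <- logical(length(genes))
  for (i in seq_along(genes)) {
    keep[i] <- GenomicRanges::start(genes)[i] <= rend &&
      GenomicRanges::end(genes)[i] >= rstart
  }
  sort(genes$gene_id[keep])
}

# two-sided Fisher p-value by exhaustive enumeration over all tables with the
# observed margins, using raw binomial coefficients
fisherOracleP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pObs <- pr[xs == a]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
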