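# Small in-code fixtures shared across test files.

# GRanges gene model from a compact data.frame spec
makeGenes <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = if ("strand" %in% names(df)) df$strand else "+",
    gene_id = df$gene_id,
    symbol = if ("symbol" %in% names(df)) df$symbol else df$gene_id,
    biotype = if ("biotype" %in% names(df)) df$biotype else "protein_coding")
}

makeSentinel <- function(rsid = "rs1", chrom = "1", pos = 1000L,
                         trait = "met") {
  data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos), trait = trait)
}

noProxies <- function() {
  data.frame(sentinel_rsid = character(0), rsid = character(0),
             chrom = character(0), pos = integer(0), r2 = numeric(0))
}

noEqtls <- function() {
  data.frame(variant_rsid = character(0), gene_id = character(0),
             tissue = character(0))
}

noConsequences <- function() {
  data.frame(variant_rsid = character(0), gene_id = character(0),
             consequence = character(0), impact = character(0))
}

# random non-overlapping gene model laid out left to right on one chromosome
randomGeneModel <- function(n, chrom = "1", seed = 1) {
  set.seed(seed)
  gaps <- sample(1:5000, n, replace = TRUE)
  lens <- sample(100:20000, n, replace = TRUE)
  starts <- cumsum(gaps + c(0, head(lens, -1)))
  makeGenes(data.frame(
    chrom = chrom, start = starts, end = starts + lens - 1,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = sprintf("G%04d", seq_len(n))))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
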