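## Three bundled worked-example metabolite QTL loci, built entirely in code.
## Gene symbols are real (MTHFR, AOC1, G6PD neighbourhoods) but coordinates
## are synthetic, chosen to satisfy the documented nearest / LD-overlap /
## flanking relationships at each locus; gene_id equals symbol in this
## fixture. Useful as a worked example and as a deterministic regression
## fixture for the whole pipeline.

.exGene <- function(chrom, start, end, strand, symbol) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = symbol, symbol = symbol, biotype = "protein_coding")
}

#' Three worked-example mQTL loci
#'
#' Returns a complete in-memory dataset for three illustrative metabolite
#' QTLs:
#' * `rs1801133` (chr1, homocysteine): a missense sentinel in `MTHFR`;
#'   the pipeline recovers `MTHFR` as the sole concurrent candidate with
#'   top-down score 4.
#' * `rs1005390` (chr7, an N-acetylated amine metabolite): an intronic
#'   sentinel with 26 proxies inside `AOC1`; `AOC1` is the sole concurrent
#'   candidate and ties `NOS3` for the top score (3).
#' * `rs766420` (chrX, bilirubin): an intronic sentinel in `TKTL1` whose
#'   causal gene `G6PD` (~200 kb away, top-down score 3) is *not* concurrent
#'   — the concurrent set is {DNASE1L1, RPL10, TAZ, TKTL1} — illustrating why
#'   non-concurrent candidates should not be discounted automatically.
#'
#' @return list with the same shape as [simulateDataset()]: `genes`,
#'   `sentinels`, `proxies`, `proxiesAll`, `consequences`, `eqtls`,
#'   `annotationSets`, `reference`, `truth`.
#' @export
#' @examples
#' loci <- exampleLoci()
#' reports <- runPipeline(loci$sentinels, loci$genes, loci$proxies,
#'                        loci$consequences, loci$eqtls, loci$annotationSets)
#' reports[["rs766420"]]
exampleLoci <- function() {
  gdf <- rbind(
    ## chr1 neighbourhood of rs1801133 (pos 11,856,378)
    .exGene("1", 11845000, 11866000, "-", "MTHFR"),     # hosts the sentinel
    .exGene("1", 11822000, 11847000, "+", "C1orf167"),  # 2nd nearest
    .exGene("1", 11867500, 11877000, "+", "CLCN6"),     # 3rd nearest
    .exGene("1", 11905000, 11908000, "-", "NPPA"),
    .exGene("1", 12000000, 12040000, "+", "PTCHD2"),
    .exGene("1", 11734000, 11751000, "+", "MAD2L2"),
    .exGene("1", 12057000, 12090000, "+", "MFN2"),
    ## chr7 neighbourhood of rs1005390 (pos 150,543,721)
    .exGene("7", 150520000, 150558000, "+", "AOC1"),      # hosts sentinel + proxies
    .exGene("7", 150560000, 150575000, "+", "TMEM179A"),  # 2nd nearest
    .exGene("7", 150500000, 150516000, "-", "TMEM179B"),  # 3rd nearest
    .exGene("7", 150650000, 150660000, "+", "CHPF2"),
    .exGene("7", 150690000, 150710000, "+", "NOS3"),
    .exGene("7", 150930000, 150974000, "+", "SMARCD3"),
    ## chrX neighbourhood of rs766420 (pos 153,554,404)
    .exGene("X", 153545000, 153579000, "+", "TKTL1"),   # hosts the sentinel
    .exGene("X", 153580000, 153606000, "+", "FLNA"),    # 2nd nearest
    .exGene("X", 153510000, 153521000, "+", "TEX28"))   # 3rd nearest
  ## distal chrX cluster: all TSS within +/- 500 kb of the sentinel; G6PD
  ## placed > 200 kb downstream of the sentinel
  distal <- c("BRCC3", "DNASE1L1", "F8A1", "FAM3A", "FAM50A", "GDI1",
              "IRAK1", "LAGE3", "PLXNA3", "G6PD", "RPL10", "TAZ",
              "TMEM187", "MECP2", "MPP1", "RENBP", "ATP6AP1", "IDH3G",
              "DKC1", "IKBKG", "HCFC1", "SSR4")
  for (i in seq_along(distal)) {
    st <- 153620000 + (i - 1L) * 15000
    gdf <- rbind(gdf, .exGene("X", st, st + 9999, "+", distal[i]))
  }
  genes <- GenomicRanges::GRanges(
    seqnames = gdf$chrom, ranges = IRanges::IRanges(gdf$start, gdf$end),
    strand = gdf$strand, gene_id = gdf$gene_id, symbol = gdf$symbol,
    biotype = gdf$biotype)

  sentinels <- data.frame(
    rsid = c("rs1801133", "rs1005390", "rs766420"),
    chrom = c("1", "7", "X"),
    pos = c(11856378L, 150543721L, 153554404L),
    trait = c("homocysteine", "X-03056", "bilirubin"))

  ## 26 proxies for rs1005390 spanning [150,530,000, 150,550,000], all inside
  ## AOC1; the r2 grid includes the inclusive 0.8 boundary
  proxies <- data.frame(
    sentinel_rsid = "rs1005390",
    rsid = sprintf("rs1005390_p%02d", 1:26),
    chrom = "7",
    pos = as.integer(round(seq(150530000, 150550000, length.out = 26))),
    r2 = round(seq(0.80, 0.99, length.out = 26), 3))

  consequences <- data.frame(
    variant_rsid = c("rs1801133", "rs1005390", "rs766420"),
    gene_id = c("MTHFR", "AOC1", "TKTL1"),
    consequence = c("missense_variant", "intron_variant", "intron_variant"),
    impact = c("MODERATE", "MODIFIER", "MODIFIER"))

  eqtls <- rbind(
    data.frame(variant_rsid = "rs1801133", gene_id = c("MFN2", "MTHFR"),
               tissue = "whole_blood"),
    data.frame(variant_rsid = c("rs1005390", "rs1005390_p01", "rs1005390"),
               gene_id = c("AOC1", "TMEM179A", "TMEM179B"),
               tissue = c("liver", "whole_blood", "liver")),
    data.frame(variant_rsid = "rs766420",
               gene_id = c("BRCC3", "DNASE1L1", "F8A1", "FAM3A", "FAM50A",
                           "GDI1", "IRAK1", "LAGE3", "PLXNA3", "RPL10",
                           "TAZ", "TMEM187"),
               tissue = "whole_blood"))

  annotationSets <- list(
    GO = c("MTHFR", "NPPA", "PTCHD2", "AOC1", "SMARCD3", "DNASE1L1", "G6PD",
           "IDH3G", "MECP2", "MPP1", "RENBP", "TKTL1"),
    KEGG = c("MTHFR", "AOC1", "CHPF2", "NOS3", "ATP6AP1", "G6PD", "IDH3G",
             "TKTL1"),
    MGI = c("MAD2L2", "NPPA", "NOS3", "DKC1", "IKBKG"),
    Orphanet = c("MTHFR", "HCFC1", "SSR4", "TAZ"),
    Reactome = c("MTHFR", "AOC1", "CHPF2", "NOS3", "SMARCD3", "G6PD", "IDH3G",
                 "RPL10", "TAZ"))

  reference <- data.frame(
    sentinel_rsid = c("rs1801133", "rs1005390", "rs766420"),
    causal_gene = c("MTHFR", "AOC1", "G6PD"))

  truth <- cbind(reference,
                 is_far = FALSE,
                 causal_is_nearest = c(TRUE, TRUE, FALSE),
                 causal_coding = c(TRUE, FALSE, FALSE),
                 causal_eqtl = c(TRUE, TRUE, FALSE),
                 planted_n_databases = c(4L, 3L, 3L),
                 realized_n_databases = c(4L, 3L, 3L))

  list(genes = genes, sentinels = sentinels, proxies = proxies,
       proxiesAll = proxies, consequences = consequences, eqtls = eqtls,
       annotationSets = annotationSets, reference = reference, truth = truth)
}
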