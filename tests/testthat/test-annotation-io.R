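test_that("gene model reading honours the biotype filter and strand-aware TSS", {
  gtf <- system.file("extdata", "toy_genes.gtf", package = "qtlCandidates")
  pc <- readGeneModel(gtf)
  expect_equal(length(pc), 1L)
  expect_equal(pc$gene_id, "G1")
  expect_equal(pc$symbol, "ALPHA")
  all <- readGeneModel(gtf, biotypeFilter = NULL)
  expect_equal(length(all), 2L)
  # minus-strand gene [100, 500]: TSS is the end coordinate
  expect_equal(geneTSS(all[all$gene_id == "G1"]), 500)
  expect_equal(geneTSS(all[all$gene_id == "G2"]), 1000)
})

test_that("malformed GTF lines fail hard with a line number, empty filters fail", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    '1\ttoy\tgene\t100\t500\t.\t+\t.\tgene_id "G1"; gene_biotype "protein_coding";',
    "this line is not gtf"), bad)
  expect_error(readGeneModel(bad), "line 2")
  gtf <- system.file("extdata", "toy_genes.gtf", package = "qtlCandidates")
  expect_error(readGeneModel(gtf, biotypeFilter = "lincRNA"), "no genes left")
})

test_that("gene spans are derived from transcripts when gene features are absent", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    '1\ttoy\ttranscript\t100\t300\t.\t+\t.\tgene_id "G1"; gene_name "A"; gene_biotype "protein_coding";',
    '1\ttoy\ttranscript\t250\t900\t.\t+\t.\tgene_id "G1"; gene_name "A"; gene_biotype "protein_coding";'),
    gtf)
  g <- readGeneModel(gtf)
  expect_equal(GenomicRanges::start(g), 100)
  expect_equal(GenomicRanges::end(g), 900)
})

test_that("proxy reading filters on r2 inclusively and validates", {
  df <- data.frame(sentinel_rsid = "rs1", rsid = c("p1", "p2", "p3"),
                   chrom = "chr1", pos = c(10L, 20L, 30L),
                   r2 = c(0.80, 0.79, 0.95))
  p <- readProxies(writeTsv(df))
  expect_setequal(p$rsid, c("p1", "p3"))   # 0.80 retained, 0.79 dropped
  expect_equal(unique(p$chrom), "1")       # chr prefix normalized

  # idempotence: re-filtering at the same threshold changes nothing
  p2 <- readProxies(writeTsv(p), r2Threshold = 0.8)
  expect_equal(p2[order(p2$rsid), ], p[order(p$rsid), ], ignore_attr = TRUE)

  empty <- writeTsv(df[0, ])
  expect_equal(nrow(readProxies(empty)), 0L)

  df$r2[1] <- 1.2
  expect_error(readProxies(writeTsv(df)), "\\[0, 1\\]")

  df$r2[1] <- 0.9
  expect_warning(
    readProxies(writeTsv(df), sentinels = makeSentinel("rsX")),
    "unknown sentinel")
})

test_that("consequence reading keeps one most-severe record per variant-gene pair", {
  df <- data.frame(
    variant_rsid = c("rs1", "rs1", "rs1", "rs2"),
    gene_id = c("geneA", "geneA", "geneB", "geneA"),
    consequence = c("missense_variant", "synonymous_variant",
                    "intron_variant", "frameshift_variant"),
    impact = c("MODERATE", "LOW", "MODIFIER", "HIGH"))
  cc <- readConsequences(writeTsv(df))
  expect_equal(nrow(cc), 3L)
  expect_false(any(duplicated(cc[c("variant_rsid", "gene_id")])))
  a <- cc[cc$variant_rsid == "rs1" & cc$gene_id == "geneA", ]
  expect_equal(a$impact, "MODERATE")       # missense outranks synonymous
  expect_equal(a$consequence, "missense_variant")
  expect_equal(cc$impact[cc$variant_rsid == "rs2"], "HIGH")  # frameshift

  df$impact[1] <- "SEVERE"
  expect_error(readConsequences(writeTsv(df)), "invalid IMPACT")
})

test_that("eQTL reading supports pre-filtered and threshold modes", {
  df <- data.frame(variant_rsid = c("rs1", "rs1", "rs2"),
                   gene_id = c("G1", "G1", "G2"),
                   tissue = c("liver", "blood", "liver"))
  e <- readEqtls(writeTsv(df))
  expect_equal(nrow(e), 3L)  # tissue-resolved: same pair in 2 tissues = 2 rows
  expect_equal(sum(e$gene_id == "G1"), 2L)

  df$p_value <- c(0.01, 0.06, 0.05)
  e2 <- readEqtls(writeTsv(df), mode = "threshold", threshold = 0.05)
  expect_equal(nrow(e2), 2L)  # 0.06 dropped, boundary 0.05 kept

  df$tissue <- NULL
  expect_warning(e3 <- readEqtls(writeTsv(df)), "tissue")
  expect_equal(unique(e3$tissue), "unspecified")
})

test_that("annotation sets load from long format with case-insensitive dedup", {
  df <- data.frame(source = c("GO", "GO", "GO", "KEGG"),
                   gene = c("A", "B", "b", "A"))
  sets <- readAnnotationSets(writeTsv(df))
  expect_named(sets, c("GO", "KEGG"))
  expect_equal(length(sets$GO), 2L)   # "B" and "b" collapse
  expect_equal(sets$KEGG, "A")

  six <- data.frame(source = paste0("S", 1:6), gene = "A")
  expect_error(readAnnotationSets(writeTsv(six)), "five")

  empty <- data.frame(source = c("GO", "KEGG"), gene = c("A", ""))
  expect_error(readAnnotationSets(writeTsv(empty)), "no members")
})

test_that("annotation sets load from per-source files", {
  f1 <- tempfile(); writeLines(c("A", "B"), f1)
  f2 <- tempfile(); writeLines("A", f2)
  sets <- readAnnotationSets(c(GO = f1, KEGG = f2))
  expect_equal(sets$GO, c("A", "B"))
  expect_error(readAnnotationSets(c(f1, f2)), "named")
})

test_that("sentinel and reference readers validate uniqueness and non-emptiness", {
  s <- data.frame(rsid = c("rs1", "rs1"), chrom = "1", pos = c(10L, 20L))
  expect_error(readSentinels(writeTsv(s)), "duplicate")
  s2 <- readSentinels(writeTsv(data.frame(rsid = "rs1", chrom = "chr2", pos = 5L)))
  expect_equal(s2$chrom, "2")

  r <- data.frame(sentinel_rsid = c("rs1", "rs1"), causal_gene = c("A", "B"))
  expect_error(readReference(writeTsv(r)), "more than one")
  expect_error(readReference(writeTsv(r[0, ])), "empty")
})

test_that("readers accept gzip-compressed files", {
  df <- makeSentinel()
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "w")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  expect_equal(readSentinels(path)$rsid, "rs1")
})

test_that("locus reports round-trip through the four output tables", {
  loci <- exampleLoci()
  reports <- runPipeline(loci$sentinels, loci$genes, loci$proxies,
                         loci$consequences, loci$eqtls, loci$annotationSets)
  dir <- tempfile()
  writeLocusReports(reports, dir)
  back <- readLocusReports(dir)
  for (rs in names(reports)) {
    r <- reports[[rs]]
    expect_setequal(back$bottom_up$gene_id[back$bottom_up$sentinel_rsid == rs],
                    bottomUp(r)$gene_id)
    expect_setequal(back$top_down$gene_id[back$top_down$sentinel_rsid == rs],
                    topDown(r)$gene_id)
    expect_setequal(back$concurrent$gene_id[back$concurrent$sentinel_rsid == rs],
                    concurrent(r))
    expect_equal(
      back$nearest_concurrent$gene_id[back$nearest_concurrent$sentinel_rsid == rs],
      nearestConcurrent(r))
  }
  # scores survive the round trip too
  td <- topDown(reports)
  expect_equal(back$top_down$score[match(paste(td$sentinel_rsid, td$gene_id),
                                         paste(back$top_down$sentinel_rsid,
                                               back$top_down$gene_id))],
               td$score)
})
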