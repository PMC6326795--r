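test_that("LD range spans sentinel and proxies with padding, clipped at 1", {
  s <- makeSentinel("rs1", "1", 1000000L)
  p <- data.frame(sentinel_rsid = "rs1", rsid = c("p1", "p2"), chrom = "1",
                  pos = c(990000L, 1020000L), r2 = c(0.9, 0.85))
  r <- buildLdRange(s, p)
  expect_equal(c(r$start, r$end), c(985000L, 1025000L))

  # no proxies: sentinel position +/- pad
  r2 <- buildLdRange(makeSentinel("rs1801133", "1", 11856378L), noProxies())
  expect_equal(c(r2$start, r2$end), c(11851378L, 11861378L))

  # clipping at the chromosome start
  r3 <- buildLdRange(makeSentinel("rs3", "1", 3000L), noProxies())
  expect_equal(c(r3$start, r3$end), c(1L, 8000L))

  pbad <- data.frame(sentinel_rsid = "rs1", rsid = "p9", chrom = "2",
                     pos = 5L, r2 = 0.9)
  expect_error(buildLdRange(s, pbad), "different chromosome")
})

test_that("nearest genes use body distance with deterministic tie-breaks", {
  g <- makeGenes(data.frame(chrom = "1", start = c(100, 300), end = c(200, 400),
                            gene_id = c("A", "B")))
  # sentinel inside a gene body: that gene is rank 1 at distance 0
  inA <- nearestGenes(makeSentinel(pos = 150L), g, k = 1)
  expect_equal(inA$gene_id, "A")
  expect_equal(inA$distance, 0L)

  # equidistant tie at pos 250 (both at distance 50): smaller start wins
  tie <- nearestGenes(makeSentinel(pos = 250L), g, k = 2)
  expect_equal(tie$gene_id, c("A", "B"))
  expect_equal(tie$distance, c(50L, 50L))

  # k larger than the chromosome's gene count
  expect_equal(nrow(nearestGenes(makeSentinel(pos = 250L), g, k = 3)), 2L)

  # no genes on the chromosome: empty with a warning
  expect_warning(none <- nearestGenes(makeSentinel(chrom = "9"), g, k = 3),
                 "no genes")
  expect_equal(nrow(none), 0L)
})

test_that("nearest genes agree with an exhaustive brute-force scan", {
  g <- randomGeneModel(500, seed = 11)
  span <- max(GenomicRanges::end(g))
  set.seed(12)
  for (pos in sample(span, 40)) {
    s <- makeSentinel(pos = pos)
    expect_equal(nearestGenes(s, g, k = 3)$gene_id, bruteNearest(pos, g, 3))
  }
})

test_that("LD overlap uses closed intervals (one shared base suffices)", {
  g <- makeGenes(data.frame(chrom = "1", start = c(100, 100), end = c(200, 199),
                            gene_id = c("touch", "miss")))
  rng <- data.frame(sentinel_rsid = "rs1", chrom = "1", start = 200L, end = 300L)
  expect_equal(ldOverlappingGenes(rng, g)$gene_id, "touch")

  gm <- randomGeneModel(300, seed = 13)
  set.seed(14)
  for (i in 1:20) {
    st <- sample(max(GenomicRanges::end(gm)), 1)
    en <- st + sample(50000, 1)
    rng <- data.frame(sentinel_rsid = "rs1", chrom = "1", start = st, end = en)
    expect_equal(sort(ldOverlappingGenes(rng, gm)$gene_id),
                 bruteOverlap(st, en, gm))
  }
})

test_that("eQTL targets pool sentinel and proxy hits with tissue provenance", {
  s <- makeSentinel("rsS")
  p <- data.frame(sentinel_rsid = "rsS", rsid = "p1", chrom = "1",
                  pos = 5L, r2 = 0.9)
  e <- data.frame(variant_rsid = c("rsS", "p1", "rsS", "rsS"),
                  gene_id = c("G1", "G2", "G3", "G3"),
                  tissue = c("liver", "blood", "liver", "lung"))
  tg <- eqtlTargetGenes(s, p, e)
  expect_setequal(tg$gene_id, c("G1", "G2", "G3"))
  expect_equal(tg$sentinel_tissues[tg$gene_id == "G1"], "liver")
  expect_true(is.na(tg$proxy_tissues[tg$gene_id == "G1"]))
  expect_equal(tg$proxy_tissues[tg$gene_id == "G2"], "blood")
  # one gene, two tissues, collapsed into one row
  expect_equal(tg$sentinel_tissues[tg$gene_id == "G3"], "liver;lung")

  expect_equal(nrow(eqtlTargetGenes(makeSentinel("rsNone"), p, e)), 0L)
})

test_that("impact flags report the most severe class per source-variant class", {
  s <- makeSentinel("rsS")
  p <- data.frame(sentinel_rsid = "rsS", rsid = "p1", chrom = "1",
                  pos = 5L, r2 = 0.9)
  cc <- data.frame(variant_rsid = c("rsS", "p1"), gene_id = "geneA",
                   consequence = c("synonymous_variant", "missense_variant"),
                   impact = c("LOW", "MODERATE"))
  fl <- impactFlags(s, p, cc)
  expect_equal(fl$impact_sentinel, "LOW")
  expect_equal(fl$impact_proxy, "MODERATE")

  # missense sentinel alone
  fl2 <- impactFlags(s, noProxies(),
                     data.frame(variant_rsid = "rsS", gene_id = "geneA",
                                consequence = "missense_variant",
                                impact = "MODERATE"))
  expect_equal(fl2$impact_sentinel, "MODERATE")
  expect_true(is.na(fl2$impact_proxy))

  expect_equal(nrow(impactFlags(s, p, noConsequences())), 0L)
})

test_that("assembled bottom-up set is the union of the three criteria", {
  g <- makeGenes(data.frame(chrom = "1",
                            start = c(900, 3000, 6000, 900000),
                            end = c(1200, 4000, 7000, 901000),
                            gene_id = c("IN", "NEAR1", "NEAR2", "FAR")))
  s <- makeSentinel(pos = 1000L)
  e <- data.frame(variant_rsid = "rs1", gene_id = c("IN", "FAR"),
                  tissue = "liver")
  cc <- data.frame(variant_rsid = "rs1", gene_id = "IN",
                   consequence = "missense_variant", impact = "MODERATE")
  bu <- assembleBottomUp(s, g, noProxies(), e, cc)
  # IN satisfies all three criteria but appears once, with all flags set
  expect_equal(sum(bu$gene_id == "IN"), 1L)
  row <- bu[bu$gene_id == "IN", ]
  expect_true(row$ld_overlap)
  expect_equal(row$nearest_rank, 1L)
  expect_equal(row$eqtl_sentinel_tissues, "liver")
  expect_equal(row$impact_sentinel, "MODERATE")
  # FAR enters through eQTL evidence only
  expect_true("FAR" %in% bu$gene_id)
  expect_false(bu$ld_overlap[bu$gene_id == "FAR"])

  # all criteria empty -> empty evidence
  empty <- assembleBottomUp(makeSentinel(chrom = "22"), g, noProxies(),
                            noEqtls(), noConsequences())
  expect_equal(nrow(empty), 0L)
})

test_that("bottom-up sets nest and grow monotonically in k and pad", {
  sim <- simulateDataset(simulationConfig(nLoci = 6, seed = 101))
  for (i in seq_len(nrow(sim$sentinels))) {
    s <- sim$sentinels[i, ]
    pc <- filterBiotype(sim$genes)
    n1 <- nearestGenes(s, pc, k = 1)$gene_id
    n3 <- nearestGenes(s, pc, k = 3)$gene_id
    bu3 <- assembleBottomUp(s, pc, sim$proxies, sim$eqtls, sim$consequences,
                            qtlConfig(kNearest = 3))
    bu5 <- assembleBottomUp(s, pc, sim$proxies, sim$eqtls, sim$consequences,
                            qtlConfig(kNearest = 5))
    buPad <- assembleBottomUp(s, pc, sim$proxies, sim$eqtls, sim$consequences,
                              qtlConfig(ldPad = 50000))
    expect_true(all(n1 %in% n3))
    expect_true(all(n3 %in% bu3$gene_id))
    expect_true(all(bu3$gene_id %in% bu5$gene_id))
    expect_true(all(bu3$gene_id %in% buPad$gene_id))
    # every ld_overlap flag is re-checkable against the locus LD range
    rng <- buildLdRange(s, sim$proxies)
    expect_setequal(bu3$gene_id[bu3$ld_overlap],
                    intersect(bu3$gene_id, ldOverlappingGenes(rng, pc)$gene_id))
  }
})
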