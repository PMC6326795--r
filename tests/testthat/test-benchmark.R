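test_that("per-locus classification decomposes into TP/FP/FN", {
  expect_equal(classifyLocus(c("A", "B", "C"), "A"), list(tp = 1L, fp = 2L, fn = 0L))
  expect_equal(classifyLocus(c("B", "C"), "A"), list(tp = 0L, fp = 2L, fn = 1L))
  expect_equal(classifyLocus(character(0), "A"), list(tp = 0L, fp = 0L, fn = 1L))
})

test_that("sensitivity is (100/n) * TP", {
  expect_equal(qtlSensitivity(227, 223), 100 / 227 * 223)
  expect_equal(round(qtlSensitivity(218, 201)), 92)
  expect_equal(qtlSensitivity(50, 0), 0)
  expect_error(qtlSensitivity(0, 0), "undefined")
})

test_that("specificity follows TN = universe - (TP + FP) - FN", {
  # sum(LG) = 100, TP = 10, FP = 30, FN = 2 -> TN = 58, 58/88
  expect_equal(qtlSpecificity(10, 30, 2, 100), 58 / 88)
  # no false positives: maximal specificity
  expect_equal(qtlSpecificity(10, 0, 2, 100), 1)
  # universe exactly exhausted by candidates: TN = 0
  expect_equal(qtlSpecificity(10, 30, 2, 42), 0)
  expect_warning(und <- qtlSpecificity(10, 0, 2, 12), "undefined")
  expect_true(is.na(und))
  expect_error(qtlSpecificity(10, 30, 2, 10), "smaller")
})

test_that("Fisher 2x2 matches exhaustive hypergeometric enumeration", {
  ft <- fisherExact2x2(3, 1, 1, 3)
  expect_equal(ft$p, fisherOracleP(3, 1, 1, 3))
  expect_true(ft$ci_low <= ft$odds_ratio && ft$odds_ratio <= ft$ci_high)

  # identical proportions in both rows: OR 1, p 1
  flat <- fisherExact2x2(2, 4, 3, 6)
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1, tolerance = 1e-6)

  # degenerate margins are flagged, p = 1, OR undefined
  dg <- fisherExact2x2(0, 0, 2, 3)
  expect_equal(dg$p, 1)
  expect_true(is.na(dg$odds_ratio))
  expect_equal(dg$note, "degenerate-margin")

  # random spot checks against the enumeration oracle
  set.seed(42)
  for (i in 1:25) {
    tab <- rpois(4, 4)
    expect_equal(fisherExact2x2(tab[1], tab[2], tab[3], tab[4])$p,
                 fisherOracleP(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("enrichment builds the 2x2 from criterion vs remaining candidates", {
  # 4 loci; criterion captures the truth at 3 of them plus 1 false instance
  crit <- data.frame(sentinel_rsid = c("s1", "s2", "s3", "s4"),
                     gene_id = c("T1", "T2", "T3", "X1"))
  bg <- rbind(crit, data.frame(sentinel_rsid = c("s1", "s2", "s4"),
                               gene_id = c("X2", "X3", "T4")))
  ref <- data.frame(sentinel_rsid = paste0("s", 1:4),
                    causal_gene = paste0("T", 1:4))
  er <- fisherEnrichment(crit, bg, ref, nTests = 26, label = "demo")
  expect_equal(c(er$tp_in, er$fp_in, er$tp_out, er$fp_out), c(3, 1, 1, 2))
  expect_equal(er$p_raw, fisherOracleP(3, 1, 1, 2))
  expect_equal(er$p_bonferroni, min(1, er$p_raw * 26))
  expect_equal(er$n_tests, 26L)

  # Bonferroni arithmetic: p = 0.01 with 26 tests -> 0.26
  expect_equal(min(1, 0.01 * 26), 0.26)
})

test_that("criterion sets stratify instances and honour locus filters", {
  loci <- exampleLoci()
  reports <- runPipeline(loci$sentinels, loci$genes, loci$proxies,
                         loci$consequences, loci$eqtls, loci$annotationSets)
  sets <- criterionSets(reports)
  # nearest criterion: one rank-1 instance per locus
  expect_equal(nrow(sets$nearest), 3L)
  expect_setequal(sets$nearest$gene_id, c("MTHFR", "AOC1", "TKTL1"))
  # concurrent instances all satisfy the concurrency definition
  for (i in seq_len(nrow(sets$concurrent))) {
    r <- reports[[sets$concurrent$sentinel_rsid[i]]]
    expect_true(sets$concurrent$gene_id[i] %in%
                  intersect(bottomUp(r)$gene_id, topDown(r)$gene_id))
  }
  # the moderate-impact sentinel locus (rs1801133) is dropped by the filter
  filt <- criterionSets(reports, locusFilter = excludeSentinelImpact("MODERATE"))
  expect_setequal(unique(filt$nearest$sentinel_rsid),
                  c("rs1005390", "rs766420"))
  expect_error(criterionSets(reports, criteria = "no_such_criterion"),
               "unknown criterion")
})

test_that("benchmark aggregates respect TP + FN = n for every set definition", {
  sim <- simulateDataset(simulationConfig(nLoci = 25, seed = 21))
  reports <- runPipeline(sim$sentinels, sim$genes, sim$proxies,
                         sim$consequences, sim$eqtls, sim$annotationSets)
  bm <- benchmarkRun(reports, sim$reference, sim$genes)
  expect_equal(bm$summary$tp + bm$summary$fn, rep(25L, nrow(bm$summary)))
  # nearest-concurrent assigns exactly one gene per locus
  nc <- bm$summary[bm$summary$set == "nearest_concurrent", ]
  expect_equal(nc$tp + nc$fp, 25L)
  expect_true(all(bm$summary$sensitivity >= 0 & bm$summary$sensitivity <= 100))
  expect_true(all(is.na(bm$summary$specificity) |
                    (bm$summary$specificity >= 0 & bm$summary$specificity <= 1)))
})

test_that("a fully concurrent fixture gives 100% sensitivity; one miss gives 75%", {
  sim <- simulateDataset(simulationConfig(
    nLoci = 4, pCausalIsNearest = 1, pCausalEqtl = 1,
    pCausalDatabases = c(0, 0, 0, 0, 0, 1), pDecoyEqtl = 0,
    pDecoyInDatabase = 0, seed = 8))
  reports <- runPipeline(sim$sentinels, sim$genes, sim$proxies,
                         sim$consequences, sim$eqtls, sim$annotationSets)
  bm <- benchmarkRun(reports, sim$reference, sim$genes)
  conc <- bm$summary[bm$summary$set == "concurrent", ]
  expect_equal(conc$sensitivity, 100)
  expect_equal(conc$fn, 0L)

  # corrupt one reference assignment: 3 of 4 captured
  ref <- sim$reference
  ref$causal_gene[1] <- "NOT_A_GENE"
  bm2 <- benchmarkRun(reports, ref, sim$genes)
  expect_equal(bm2$summary$sensitivity[bm2$summary$set == "total"], 75)
})

test_that("loci without a reference assignment are excluded with a warning", {
  loci <- exampleLoci()
  reports <- runPipeline(loci$sentinels, loci$genes, loci$proxies,
                         loci$consequences, loci$eqtls, loci$annotationSets)
  expect_warning(bm <- benchmarkRun(reports, loci$reference[1:2, ], loci$genes),
                 "without a reference")
  expect_equal(unique(bm$summary$n), 2L)
})

test_that("concurrent specificity dominates bottom-up on nested captures", {
  sim <- simulateDataset(simulationConfig(nLoci = 30, seed = 77))
  reports <- runPipeline(sim$sentinels, sim$genes, sim$proxies,
                         sim$consequences, sim$eqtls, sim$annotationSets)
  bm <- benchmarkRun(reports, sim$reference, sim$genes)
  s <- bm$summary
  conc <- s[s$set == "concurrent", ]
  bu <- s[s$set == "bottom_up", ]
  # concurrent is a subset of bottom-up, so it can only trade captures for
  # fewer false positives
  expect_lte(conc$tp, bu$tp)
  expect_lte(conc$fp, bu$fp)
  # same TP with fewer FP implies higher specificity under the shared
  # candidate universe
  if (conc$tp == bu$tp)
    expect_gte(conc$specificity, bu$specificity)
})
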