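test_that("enrichment test matches first-principles chi-square and Fisher", {
  # equal fractions: ratio 1, chi-square ~ 0
  et <- enrichment_test(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 200))
  expect_equal(et$ratio, 1)
  expect_lt(et$chisq, 1e-10)
  expect_equal(et$direction, "none")
  # table (30,70,10,90) against enumeration oracles
  x <- rep(c(TRUE, FALSE), c(30, 70))
  y <- rep(c(TRUE, FALSE), c(10, 90))
  et2 <- enrichment_test(x, y)
  tab <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  expect_equal(et2$chisq, oracle_chisq(tab), tolerance = 1e-10)
  expect_equal(et2$p_fisher, oracle_fisher(tab), tolerance = 1e-8)
  expect_false(et2$fisher_used)   # all expected cells >= 5
  expect_equal(et2$ratio, 3)
  expect_equal(et2$direction, "enriched")
  # small table triggers the Fisher substitution
  et3 <- enrichment_test(rep(c(TRUE, FALSE), c(3, 4)),
                         rep(c(TRUE, FALSE), c(1, 9)))
  expect_true(et3$fisher_used)
  expect_equal(et3$p, et3$p_fisher)
  # transposition symmetry of chi-square
  et4 <- enrichment_test(y, x)
  expect_equal(et4$chisq, et2$chisq, tolerance = 1e-12)
  # zero background fraction
  et5 <- enrichment_test(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(et5$ratio, Inf)
  # NA sites excluded symmetrically
  et6 <- enrichment_test(c(x, NA), c(y, NA))
  expect_equal(et6$chisq, et2$chisq)
})

test_that("composite caller applies strict thresholds and the k-of-3 rule", {
  rec <- data.frame(pos = 1:6,
                    daf = c(0.6, 0.5, 0.7, NA, 0.9, 0.2),
                    fst = c(0.35, 0.3, 0.1, 0.5, NA, 0.31),
                    ihs = c(1.5, 2.0, -2.5, 2.5, 2.1, 0))
  calls <- call_selection(rec)
  # DAF=0.6, FST=0.35, |iHS|=1.5: two criteria met -> called
  expect_true(calls$called[1])
  # exact boundaries (0.5, 0.3, 2) are NOT met
  expect_equal(calls$n_criteria_met[2], 0)
  expect_false(calls$called[2])
  # negative iHS counts by magnitude
  expect_true(calls$crit_ihs[3])
  # undefined statistic never satisfies its criterion
  expect_false(calls$crit_daf[4])
  expect_false(calls$crit_fst[5])
  # monotone in k
  k1 <- call_selection(rec, k = 1)$called
  k2 <- call_selection(rec, k = 2)$called
  k3 <- call_selection(rec, k = 3)$called
  expect_true(all(k2 <= k1) && all(k3 <= k2))
})

test_that("caller equals brute-force enumeration on random records", {
  set.seed(14)
  rec <- data.frame(pos = seq_len(1000),
                    daf = ifelse(runif(1000) < 0.1, NA, runif(1000)),
                    fst = ifelse(runif(1000) < 0.1, NA, runif(1000)),
                    ihs = ifelse(runif(1000) < 0.1, NA, rnorm(1000, 0, 2)))
  calls <- call_selection(rec)
  brute <- logical(1000)
  for (i in seq_len(1000)) {
    m <- 0
    if (!is.na(rec$daf[i]) && rec$daf[i] > 0.5) m <- m + 1
    if (!is.na(rec$fst[i]) && rec$fst[i] > 0.3) m <- m + 1
    if (!is.na(rec$ihs[i]) && abs(rec$ihs[i]) > 2) m <- m + 1
    brute[i] <- m >= 2
  }
  expect_identical(calls$called, brute)
})

test_that("top-quantile thresholding includes ties above the cut", {
  v <- c(rep(1, 90), rep(9, 10))
  thr <- top_quantile_threshold(v, q = 0.1)
  expect_true(sum(v >= thr) >= 10)
})

test_that("gene annotation honours the half-open 5 kb flank", {
  genes <- gene_track(data.frame(chrom = "chr1", start = 10000,
                                 end = 12000, gene = "g1"))
  calls <- data.frame(pos = c(11000, 7000, 4999, 5000, 16999, 17000))
  ann <- annotate_genes(calls, genes)
  expect_equal(ann$genes, c("g1", "g1", "", "g1", "g1", ""))
  # multiple genes sorted by distance then name
  g2 <- gene_track(data.frame(chrom = "chr1", start = c(16000, 11200),
                              end = c(16500, 11400),
                              gene = c("away", "inA")))
  ann2 <- annotate_genes(data.frame(pos = 11300), g2)
  expect_equal(ann2$genes, "inA,away")
  # random placements match a brute-force interval scan
  set.seed(2)
  gs <- sort(sample.int(90000, 5))
  gt <- gene_track(data.frame(chrom = "chr1", start = gs, end = gs + 2000,
                              gene = paste0("g", 1:5)))
  pts <- data.frame(pos = sample.int(100000, 200))
  ann3 <- annotate_genes(pts, gt)
  for (i in seq_len(200)) {
    hit <- pts$pos[i] >= gt$start - 5000 & pts$pos[i] < gt$end + 5000
    expect_equal(ann3$genes[i] != "", any(hit))
  }
})

test_that("risk-derived DAF profile separates constructed contrasts", {
  set.seed(9)
  risk <- data.frame(daf = c(rbeta(300, 0.5, 5), rbeta(300, 2, 2)),
                     risk_is_derived = rep(c(TRUE, FALSE), each = 300))
  prof <- gwas_daf_profile(risk)
  expect_equal(sum(prof$risk_derived), 300L)
  expect_equal(sum(prof$non_risk_derived), 300L)
  # low-DAF bin enriched for the risk-derived group
  expect_lt(prof$p_fisher[1], 0.01)
  expect_gt(prof$risk_derived[1] / 300, prof$non_risk_derived[1] / 300)
  # identical groups: all P near 1
  same <- data.frame(daf = rep(seq(0.05, 0.95, by = 0.1), 2),
                     risk_is_derived = rep(c(TRUE, FALSE), each = 10))
  expect_true(all(gwas_daf_profile(same)$p_fisher > 0.9))
  expect_error(gwas_daf_profile(data.frame(daf = 0.1,
                                           risk_is_derived = TRUE)),
               "non-empty")
})
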