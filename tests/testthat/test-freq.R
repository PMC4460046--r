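make_two_pop <- function(m1, m2, pos = NULL) {
  m <- rbind(m1, m2)
  ids <- c(paste0("a", rep(1:(nrow(m1) / 2), each = 2), "_h", 1:2),
           paste0("b", rep(1:(nrow(m2) / 2), each = 2), "_h", 1:2))
  panel <- population_panel(data.frame(
    sample_id = unique(sub("_h[12]$", "", ids)),
    population = c(rep("P1", nrow(m1) / 2), rep("P2", nrow(m2) / 2)),
    superpopulation = c(rep("S1", nrow(m1) / 2), rep("S2", nrow(m2) / 2))))
  if (is.null(pos)) pos <- seq_len(ncol(m)) - 1
  list(block = haplotype_block(m, pos, sample_ids = ids), panel = panel)
}

test_that("Weir-Cockerham limits behave as constructed", {
  # identical frequencies: s2 = 0, theta <= 0 (not clamped)
  tp <- make_two_pop(matrix(c(1, 1, 0, 0), 4, 1),
                     matrix(c(1, 1, 0, 0), 4, 1))
  f <- weir_cockerham_fst(tp$block, tp$panel)
  expect_lte(f$per_site$theta[1], 0)
  # fixed difference with large equal n: theta -> 1
  tp2 <- make_two_pop(matrix(1L, 40, 1), matrix(0L, 40, 1))
  f2 <- weir_cockerham_fst(tp2$block, tp2$panel)
  expect_gt(f2$per_site$theta[1], 0.97)
  # monomorphic across all: undefined
  tp3 <- make_two_pop(matrix(1L, 4, 1), matrix(1L, 4, 1))
  f3 <- weir_cockerham_fst(tp3$block, tp3$panel)
  expect_false(f3$per_site$defined[1])
  expect_true(is.na(f3$per_site$theta[1]))
})

test_that("per-site theta matches the naive component transcription", {
  set.seed(21)
  sim <- simulate_island(sim_config(n_haplotypes = 14, theta = 15,
                                    demes = 3, migration = 1, seed = 31))
  f <- weir_cockerham_fst(sim$block, sim$panel)
  gp <- haplotype_populations(sim$block, sim$panel)
  sizes <- as.numeric(table(gp)[f$pops])
  for (j in which(f$per_site$defined)) {
    cts <- as.numeric(tapply(sim$block$alleles[, j], gp, sum)[f$pops])
    o <- oracle_wc_site(cts, sizes)
    expect_equal(f$per_site$theta[j], unname(o["theta"]), tolerance = 1e-10)
    expect_equal(f$per_site$a[j], unname(o["a"]), tolerance = 1e-10)
  }
  # allele-label swap leaves theta unchanged
  flip <- sim$block
  flip$alleles <- 1L - flip$alleles
  f_flip <- weir_cockerham_fst(flip, sim$panel)
  expect_equal(f_flip$per_site$theta, f$per_site$theta, tolerance = 1e-12)
})

test_that("global and pairwise F_ST respect pooling and symmetry", {
  set.seed(6)
  sim <- simulate_island(sim_config(n_haplotypes = 10, theta = 10,
                                    demes = 3, migration = 1, seed = 61))
  gpf <- global_and_pairwise_fst(sim$block, sim$panel)
  expect_equal(length(gpf$pairwise), 3)
  expect_true(all(c("pop1-pop2", "pop1-pop3", "pop2-pop3") %in%
                    names(gpf$pairwise)))
  # three identical-frequency populations: global theta <= 0
  m <- matrix(c(1, 1, 0, 0), 4, 3)
  tp <- make_two_pop(m, m)
  # add a third identical population by relabelling superpops
  f <- weir_cockerham_fst(tp$block, tp$panel)
  expect_lte(f$mean_theta, 0)
  expect_error(weir_cockerham_fst(sim$block, sim$panel,
                                  pops = c("pop1", "nope")), "absent")
})

test_that("MAF/DAF contract and spectrum binning", {
  b <- haplotype_block(matrix(c(rep(1L, 8), rep(0L, 2)), 10, 1), 0,
                       ancestral_known = TRUE)
  md <- maf_daf(b)
  expect_equal(md$daf, 0.8)
  expect_equal(md$maf, 0.2)
  # boundary: value exactly at an edge goes right
  bs <- bin_spectrum(c(0.05, 0.049, NA), edges = c(0, 0.05, 0.1))
  expect_equal(unname(bs$counts), c(1L, 1L))
  expect_equal(bs$n_undefined, 1L)
  expect_error(bin_spectrum(1.2, c(0, 1)), "0, 1")
  expect_error(bin_spectrum(0.5, c(0.5, 0.2)), "increasing")
  # counts sum to defined values; matches brute-force loop
  set.seed(3)
  v <- runif(500)
  edges <- seq(0, 1, by = 0.1)
  bs2 <- bin_spectrum(v, edges)
  expect_equal(sum(bs2$counts), 500L)
  brute <- integer(10)
  for (x in v) {
    k <- findInterval(x, edges, rightmost.closed = TRUE)
    brute[k] <- brute[k] + 1L
  }
  expect_equal(unname(bs2$counts), brute)
})

test_that("neutral spectrum matches the 1/i expectation", {
  # E[xi_i] = theta/i; sites within a replicate share a genealogy, so
  # the comparison uses replicate-level means with empirical SEs
  n <- 20; theta <- 10; reps <- 2000
  xi <- matrix(0, reps, n - 1)
  for (i in seq_len(reps)) {
    b <- simulate_neutral(sim_config(n_haplotypes = n, theta = theta,
                                     seed = derive_seed(71, i)))
    xi[i, ] <- tabulate(derived_counts(b), nbins = n - 1)
  }
  z <- (colMeans(xi) - theta / seq_len(n - 1)) /
    (apply(xi, 2, sd) / sqrt(reps))
  expect_lt(max(abs(z)), 4.5)
})

test_that("conservation classification is inclusive and monotone", {
  ct <- conservation_track(data.frame(
    chrom = "chr1", start = c(0, 10), end = c(10, 20),
    score = c(2.0, 3.5)))
  cc <- classify_conservation(c(5, 15), ct)
  # score exactly 2.0 is conserved at threshold >= 2
  expect_true(cc$conserved_ge_2[1])
  expect_false(cc$conserved_ge_3[1])
  # conserved-at-3 subset of conserved-at-2
  expect_true(all(!cc$conserved_ge_3 | cc$conserved_ge_2))
})

test_that("element conserved fractions match per-base construction", {
  el <- element_track(data.frame(chrom = "chr1", start = 0, end = 1000,
                                 class = "CNC"))
  ct <- conservation_track(data.frame(
    chrom = "chr1", start = c(0, 400), end = c(400, 1000),
    score = c(3, 1)))
  fr <- element_conserved_fraction(el, ct, 2)
  expect_equal(fr$fraction, 0.4)
  # brute-force per-base scan
  base_scores <- site_scores(0:999, ct)
  expect_equal(mean(!is.na(base_scores) & base_scores >= 2), 0.4)
  # low-DAF fraction helper
  fl <- fraction_low_daf(c(0.01, 0.05, 0.5, NA))
  expect_equal(fl$fraction, 2 / 3)
  expect_equal(fl$n_defined, 3L)
})
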