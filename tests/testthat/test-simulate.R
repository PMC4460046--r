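test_that("neutral coalescent matches closed-form expectations", {
  # E[S] = theta * a1 with a1(4) = 11/6; E[pi] = theta
  reps <- 1500
  S <- numeric(reps); pi2 <- numeric(reps)
  for (i in seq_len(reps)) {
    b4 <- simulate_neutral(sim_config(n_haplotypes = 4, theta = 2,
                                      seed = derive_seed(10, i)))
    S[i] <- n_sites(b4)
    b2 <- simulate_neutral(sim_config(n_haplotypes = 2, theta = 1,
                                      seed = derive_seed(20, i)))
    pi2[i] <- pi_total(b2)
  }
  expect_lt(abs(mean(S) - 2 * 11 / 6), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi2) - 1), 3 * sd(pi2) / sqrt(reps))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_haplotypes = 10, theta = 5, seed = 77)
  expect_identical(simulate_neutral(cfg), simulate_neutral(cfg))
  cfg2 <- sim_config(n_haplotypes = 8, theta = 5, demes = 2,
                     migration = 1, seed = 78)
  expect_identical(simulate_island(cfg2), simulate_island(cfg2))
  cfg3 <- sim_config(n_haplotypes = 10, theta = 5, locus_bp = 50000,
                     seed = 79)
  expect_identical(simulate_sweep(cfg3), simulate_sweep(cfg3))
  expect_error(simulate_neutral(sim_config(n_haplotypes = 1)), ">= 2")
})

test_that("island model requires migration or a split time and labels demes", {
  expect_error(simulate_island(sim_config(demes = 2, migration = 0)),
               "split_time")
  sim <- simulate_island(sim_config(n_haplotypes = 6, theta = 3,
                                    demes = 3, migration = 1, seed = 4))
  gp <- haplotype_populations(sim$block, sim$panel)
  expect_equal(as.vector(table(gp)), c(6, 6, 6))
  # split-time mode works
  sim2 <- simulate_island(sim_config(n_haplotypes = 6, theta = 3,
                                     demes = 2, migration = 0,
                                     split_time = 0.5, seed = 5))
  expect_s3_class(sim2$block, "haplotype_block")
})

test_that("strong migration drives F_ST to zero", {
  th <- numeric(40)
  for (i in seq_len(40)) {
    sim <- simulate_island(sim_config(n_haplotypes = 20, theta = 10,
                                      demes = 2, migration = 200,
                                      seed = derive_seed(55, i)))
    th[i] <- weir_cockerham_fst(sim$block, sim$panel)$mean_theta
  }
  expect_lt(abs(mean(th)), 0.02)
})

test_that("degenerate sweep gives EHH identically 1 on the derived background", {
  sw <- simulate_sweep(sim_config(n_haplotypes = 20, theta = 10,
                                  locus_bp = 50000, crossover = 0,
                                  sweep_freq = 0.5, seed = 3))
  ci <- attr(sw, "core_index")
  expect_equal(min(ehh(sw, ci, 1, "right")$ehh), 1)
  expect_equal(min(ehh(sw, ci, 1, "left")$ehh), 1)
  # carrier count equals the rounded target frequency
  expect_equal(sum(sw$alleles[, ci]), 10L)
})

test_that("skew_sfs lowers Tajima's D and raises the rare-DAF fraction", {
  elem <- data.frame(chrom = "chr1", start = 0, end = 10000, class = "CNC")
  d1 <- d2 <- f1 <- f2 <- numeric(30)
  for (i in seq_len(30)) {
    b <- simulate_neutral(sim_config(n_haplotypes = 50, theta = 10,
                                     seed = derive_seed(600, i)))
    set.seed(derive_seed(601, i))
    s1 <- skew_sfs(b, elem, beta = 1)
    s2 <- skew_sfs(b, elem, beta = 2)
    d1[i] <- tajimas_d(s1)$D; d2[i] <- tajimas_d(s2)$D
    f1[i] <- fraction_low_daf(maf_daf(s1)$daf)$fraction
    f2[i] <- fraction_low_daf(maf_daf(s2)$daf)$fraction
  }
  expect_lt(mean(d2), mean(d1) - 0.5)
  expect_gt(mean(f2), mean(f1))
  # beta = 1 leaves the SFS unchanged in distribution: compare pooled
  # derived-count spectra of original and beta = 1 resample
  ks <- kd <- integer(0)
  for (i in 1:30) {
    b <- simulate_neutral(sim_config(n_haplotypes = 20, theta = 10,
                                     seed = derive_seed(700, i)))
    ks <- c(ks, derived_counts(b))
    set.seed(derive_seed(701, i))
    kd <- c(kd, derived_counts(skew_sfs(b, elem, beta = 1)))
  }
  expect_gt(suppressWarnings(ks.test(ks, kd)$p.value), 0.01)
  # sites outside elements untouched
  b <- simulate_neutral(sim_config(n_haplotypes = 10, theta = 10, seed = 9))
  out <- skew_sfs(b, data.frame(chrom = "chr1", start = 0, end = 2000,
                                class = "CNC"), beta = 2)
  outside <- b$positions >= 2000
  expect_identical(out$alleles[, outside], b$alleles[, outside])
})

test_that("make_tracks recovers class lengths and conservation probability", {
  set.seed(12)
  tr <- make_tracks(chrom_len = 200000,
                    class_lengths = c(CDS = 20000, intron = 50000),
                    constrained_classes = "CDS", p_conserved = 1,
                    n_genes = 3)
  lens <- tapply(tr$elements$end - tr$elements$start, tr$elements$class, sum)
  expect_equal(as.vector(lens[c("CDS", "intron")]), c(20000, 50000))
  fr <- element_conserved_fraction(tr$elements, tr$conservation, 2)
  expect_equal(fr$fraction[fr$class == "CDS"], 1)
  expect_equal(fr$fraction[fr$class == "intron"], 0)
  expect_error(make_tracks(1000, c(a = 2000)), "exceed")
})
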