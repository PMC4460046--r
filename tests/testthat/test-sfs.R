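test_that("haplotype_block validates its invariants", {
  expect_error(haplotype_block(matrix(c(0, 2), 1), c(0, 5)), "0/1")
  expect_error(haplotype_block(matrix(0L, 2, 2), c(5, 5)), "increasing")
  b <- haplotype_block(matrix(c(0L, 1L, 1L, 0L), 2), c(0, 10))
  expect_equal(n_haplotypes(b), 2)
  expect_equal(n_sites(b), 2)
  expect_equal(derived_counts(b), c(1L, 1L))
})

test_that("pi matches hand enumeration and the frequency-form identity", {
  # haplotypes {00, 01, 11}: pairwise diffs 1+2+1 over 3 pairs = 4/3
  b <- haplotype_block(rbind(c(0, 0), c(0, 1), c(1, 1)), c(0, 1),
                       length_bp = 2)
  expect_equal(pi_total(b), 4 / 3)
  expect_equal(nucleotide_diversity(b, L = 2), 2 / 3)
  expect_equal(nucleotide_diversity(b), 2 / 3)  # length_bp default
  expect_error(nucleotide_diversity(b, L = 0), "L must be > 0")
  # identical haplotypes
  expect_equal(pi_total(haplotype_block(rbind(c(1, 0), c(1, 0)), c(0, 1))), 0)
  # frequency form == pairwise loop on random matrices
  for (s in 1:20) {
    b <- random_block(n = sample(3:10, 1), S = sample(2:15, 1), seed = s)
    expect_equal(pi_total(b), oracle_sfs(b$alleles)$pi_total,
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D reproduces the hand-worked n=4 instance", {
  b <- haplotype_block(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1),
                             c(1, 1, 1)), c(0, 5, 9), length_bp = 10)
  td <- tajimas_d(b)
  expect_equal(td$S, 3L)
  expect_equal(td$theta_w, 18 / 11)
  expect_equal(td$pi_total, 5 / 3)
  expect_equal(td$pi_total - td$theta_w, 1 / 33)
  cst <- sfs_constants(4)
  expect_equal(td$D, (1 / 33) / sqrt(cst$e1 * 3 + cst$e2 * 3 * 2))
})

test_that("variance machinery reproduces Tajima's published constants", {
  for (n in c(4, 7, 25, 50, 100)) {
    cst <- sfs_constants(n)
    expect_equal(cst$taj_alpha, cst$c1, tolerance = 1e-12)
    expect_equal(cst$taj_beta, cst$c2, tolerance = 1e-12)
  }
  expect_equal(sfs_constants(4)$a1, 11 / 6)
})

test_that("SFS second moments match Monte-Carlo coalescent covariances", {
  # direct check of the sigma matrix driving the D*/F* constants:
  # simulate many neutral genealogies and compare Var(xi_i) with
  # theta/i + sigma_ii * theta^2 at n = 6
  n <- 6; theta <- 3
  sig <- fu1995_sigma(n)
  reps <- 4000
  xi <- matrix(0, reps, n - 1)
  for (r in seq_len(reps)) {
    b <- simulate_neutral(sim_config(n_haplotypes = n, theta = theta,
                                     locus_bp = 5000,
                                     seed = derive_seed(321, r)))
    k <- derived_counts(b)
    xi[r, ] <- tabulate(k[k > 0 & k < n], nbins = n - 1)
  }
  i <- seq_len(n - 1)
  expected_var <- theta / i + diag(sig) * theta^2
  observed_var <- apply(xi, 2, var)
  # Monte-Carlo tolerance: 15% relative
  expect_lt(max(abs(observed_var - expected_var) / expected_var), 0.15)
})

test_that("undefined statistics are flagged, never zero-coerced", {
  b <- haplotype_block(matrix(0L, 5, 0), numeric(0), length_bp = 100)
  td <- tajimas_d(b)
  expect_false(td$defined)
  expect_true(is.na(td$D))
  fl <- fu_li_star(b)
  expect_false(fl$defined)
  fw <- fay_wu_h(b)
  expect_false(fw$defined)
  # n < 4 for starred statistics
  b3 <- haplotype_block(rbind(c(0, 1), c(1, 0), c(1, 1)), c(0, 1))
  expect_false(fu_li_star(b3)$defined)
})

test_that("Fu & Li D* numerator is positive when no singletons exist", {
  # n=6, all sites at derived count 3: eta_s = 0
  m <- matrix(0L, 6, 4)
  for (j in 1:4) m[sample.int(6, 3), j] <- 1L
  b <- haplotype_block(m, 0:3, length_bp = 10)
  fl <- fu_li_star(b)
  n <- 6; cst <- sfs_constants(6)
  num <- (n / (n - 1)) * fl$S - cst$a1 * fl$eta_s
  expect_equal(fl$eta_s, 0L)
  expect_gt(num, 0)
  expect_gt(fl$D_star, 0)
})

test_that("Fay & Wu's H matches hand computation and excludes unpolarized sites", {
  # one site at derived count 3, n=4: theta_H = 1.5, pi = 0.5, H = -1
  b <- haplotype_block(matrix(c(1, 1, 1, 0), 4, 1), 0, length_bp = 10)
  expect_equal(fay_wu_h(b)$H, -1)
  # n=2: pi == theta_H identically, so H = 0
  b2 <- haplotype_block(rbind(c(0, 1), c(1, 0)), c(0, 1))
  expect_equal(fay_wu_h(b2)$H, 0)
  # unknown-ancestral sites are excluded and counted
  b3 <- haplotype_block(rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0)),
                        c(0, 1), ancestral_known = c(FALSE, TRUE))
  fw <- fay_wu_h(b3)
  expect_equal(fw$n_excluded, 1L)
  ks <- 1  # only the polarized site (count 1)
  expect_equal(fw$theta_H, 2 * ks^2 / (4 * 3))
})

test_that("statistics are invariant under haplotype and site reordering", {
  b <- random_block(8, 12, seed = 99)
  perm_h <- sample.int(8)
  perm_s <- sample.int(12)
  b2 <- haplotype_block(b$alleles[perm_h, perm_s],
                        sort(b$positions[perm_s]),
                        length_bp = b$length_bp)
  # site positions change but the SFS does not
  expect_equal(tajimas_d(b)$D, tajimas_d(b2)$D)
  expect_equal(fu_li_star(b)$D_star, fu_li_star(b2)$D_star)
  expect_equal(fay_wu_h(b)$H, fay_wu_h(b2)$H)
  expect_equal(pi_total(b), pi_total(b2))
})

test_that("observed heterozygosity matches per-genotype enumeration", {
  # all homozygous
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(observed_heterozygosity(haplotype_block(m, c(0, 1))), 0)
  # one site, half the samples heterozygous
  m2 <- matrix(c(0, 1, 0, 0), 4, 1)
  expect_equal(observed_heterozygosity(haplotype_block(m2, 0)), 0.5)
  expect_error(observed_heterozygosity(
    haplotype_block(matrix(0L, 3, 1), 0)), "even")
  # random matrix vs direct loop
  b <- random_block(10, 20, seed = 7)
  ho <- 0
  for (s in seq_len(20)) {
    het <- 0
    for (d in seq(1, 9, by = 2))
      if (b$alleles[d, s] != b$alleles[d + 1, s]) het <- het + 1
    ho <- ho + het / 5
  }
  expect_equal(observed_heterozygosity(b), ho / 20)
})
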