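# Independent brute-force oracles. These deliberately share no code with
# the package internals: pairwise loops and direct enumeration only.

# Pairwise-loop SFS statistics from a raw 0/1 matrix (rows = haplotypes).
oracle_sfs <- function(m) {
  n <- nrow(m)
  k <- colSums(m)
  seg <- k > 0 & k < n
  S <- sum(seg)
  pi_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pi_tot <- pi_tot + sum(m[i, ] != m[j, ])
  pi_tot <- pi_tot / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  ks <- k[seg]
  theta_h <- sum(2 * ks^2) / (n * (n - 1))
  list(n = n, S = S, pi_total = pi_tot, theta_w = S / a1,
       d_num = pi_tot - S / a1, theta_h = theta_h, h = pi_tot - theta_h)
}

# Naive transcription of the haploid Weir-Cockerham (1984) components
# for one site, from per-population derived counts and sizes.
oracle_wc_site <- function(counts, sizes) {
  r <- length(sizes)
  p <- counts / sizes
  nbar <- mean(sizes)
  nc <- (r * nbar - sum(sizes^2) / (r * nbar)) / (r - 1)
  pbar <- sum(sizes * p) / (r * nbar)
  s2 <- sum(sizes * (p - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2)
  c(a = a, b = b, theta = a / (a + b))
}

# EHH by its definition: probability two random distinct carriers are
# identical at every site from the core through x.
oracle_ehh <- function(alleles, core, allele, to) {
  carriers <- which(alleles[, core] == allele)
  span <- if (to >= core) core:to else to:core
  same <- 0; tot <- 0
  for (i in seq_along(carriers)[-length(carriers)])
    for (j in (i + 1):length(carriers)) {
      tot <- tot + 1
      if (all(alleles[carriers[i], span] == alleles[carriers[j], span]))
        same <- same + 1
    }
  same / tot
}

# Random segregating haplotype matrix: n haplotypes, S sites, every
# column polymorphic.
random_block <- function(n, S, seed) {
  set.seed(seed)
  m <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    k <- sample(seq_len(n - 1), 1)
    m[sample.int(n, k), j] <- 1L
  }
  haplotype_block(m, sort(sample.int(S * 50, S)) - 1, length_bp = S * 50)
}

# Pearson chi-square (1 d.f., no correction) from first principles.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Fisher exact two-sided P by hypergeometric enumeration.
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n2):min(kk, m)
  probs <- stats::dhyper(support, m, n2, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
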