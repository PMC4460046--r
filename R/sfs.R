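# Harmonic sums a_n = sum_{k<n} 1/k and b_n = sum_{k<n} 1/k^2
harmonic1 <- function(n) if (n <= 1) 0 else sum(1 / seq_len(n - 1L))
harmonic2 <- function(n) if (n <= 1) 0 else sum(1 / seq_len(n - 1L)^2)

# cache of per-n constant sets (they depend only on n and are needed per
# window, so recomputation would dominate window scans)
.sfs_cache <- new.env(parent = emptyenv())

#' Sample-size constants for SFS neutrality tests
#'
#' All quantities that depend only on the number of haplotypes `n`:
#' the harmonic sums `a1`, `a2`, Tajima's `b1,b2,c1,c2,e1,e2`, and the
#' variance coefficients `(alpha, beta)` of the Tajima, Fu & Li D* and
#' F* test numerators, such that `Var(numerator) = alpha*theta +
#' beta*theta^2` under the standard neutral coalescent. The `alpha/beta`
#' pairs are computed exactly from the second moments of the unfolded
#' site-frequency spectrum (Fu 1995) rather than transcribed from
#' printed constant tables; for Tajima's D this construction reproduces
#' `c1`/`c2` identically, which is asserted in the test suite.
#'
#' @param n number of haplotypes (>= 2; D*/F* constants need n >= 4).
#' @return a list of constants for sample size `n`.
#' @export
sfs_constants <- function(n) {
  key <- as.character(n)
  if (!is.null(.sfs_cache[[key]])) return(.sfs_cache[[key]])
  if (n < 2) stop("n must be >= 2")
  a1 <- harmonic1(n)
  a2 <- harmonic2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)

  out <- list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
              c1 = c1, c2 = c2, e1 = e1, e2 = e2)

  if (n >= 3) {
    sig <- fu1995_sigma(n)
    i <- seq_len(n - 1L)
    # Tajima numerator: pi_total - S/a1
    c_taj <- i * (n - i) / choose(n, 2) - 1 / a1
    out$taj_alpha <- sum(c_taj^2 / i)
    out$taj_beta <- as.numeric(t(c_taj) %*% sig %*% c_taj)
    # Fu & Li D* numerator: (n/(n-1)) * S - a1 * eta_s
    # (eta_s = minor-allele singletons: derived count 1 or n-1)
    singleton <- as.numeric(i == 1L | i == (n - 1L))
    c_dstar <- n / (n - 1) - a1 * singleton
    out$dstar_alpha <- sum(c_dstar^2 / i)
    out$dstar_beta <- as.numeric(t(c_dstar) %*% sig %*% c_dstar)
    # Fu & Li F* numerator: pi_total - ((n-1)/n) * eta_s
    c_fstar <- i * (n - i) / choose(n, 2) - ((n - 1) / n) * singleton
    out$fstar_alpha <- sum(c_fstar^2 / i)
    out$fstar_beta <- as.numeric(t(c_fstar) %*% sig %*% c_fstar)
  }
  .sfs_cache[[key]] <- out
  out
}

#' Second moments of the unfolded SFS under the neutral coalescent
#'
#' Returns the (n-1) x (n-1) matrix `sigma` with
#' `Cov(xi_i, xi_j) = (theta/i) * [i==j] + sigma[i,j] * theta^2`,
#' where `xi_i` is the number of segregating sites with derived-allele
#' count `i` (Fu 1995). Used to build exact variance constants for
#' linear SFS statistics.
#'
#' @param n number of haplotypes (>= 3).
#' @return numeric matrix of theta^2 covariance coefficients.
#' @export
fu1995_sigma <- function(n) {
  an1 <- harmonic1(n + 1L)              # sum_{k=1}^{n} 1/k
  an <- harmonic1(n)
  ai <- c(0, cumsum(1 / seq_len(n)))    # ai[k] = a_k = sum_{j<k} 1/j
  a_of <- function(k) ai[k]             # a_k for k >= 1
  beta_n <- function(i) {
    2 * n * (an1 - a_of(i)) / ((n - i + 1) * (n - i)) - 2 / (n - i)
  }
  m <- n - 1L
  sig <- matrix(0, m, m)
  for (i in seq_len(m)) {
    if (2 * i < n) {
      sig[i, i] <- beta_n(i + 1L)
    } else if (2 * i == n) {
      sig[i, i] <- 2 * (an - a_of(i)) / (n - i) - 1 / i^2
    } else {
      sig[i, i] <- beta_n(i) - 1 / i^2
    }
  }
  if (m >= 2) {
    for (i in 2:m) {
      for (j in 1:(i - 1L)) {            # i > j
        v <- if (i + j < n) {
          (beta_n(i + 1L) - beta_n(i)) / 2
        } else if (i + j == n) {
          (an - a_of(i)) / (n - i) + (an - a_of(j)) / (n - j) -
            (beta_n(i) + beta_n(j + 1L)) / 2 - 1 / (i * j)
        } else {
          (beta_n(j) - beta_n(j + 1L)) / 2 - 1 / (i * j)
        }
        sig[i, j] <- v
        sig[j, i] <- v
      }
    }
  }
  sig
}

# Segregating-site derived counts of a block: counts k with 0 < k < n.
# Returns list(n, counts, known) where `known` flags polarized sites.
.seg_counts <- function(block) {
  n <- n_haplotypes(block)
  k <- derived_counts(block)
  seg <- k > 0L & k < n
  list(n = n, counts = k[seg], known = block$ancestral_known[seg])
}

#' Per-site nucleotide diversity
#'
#' Mean number of pairwise allele differences between two haplotypes,
#' divided by the sequence length `L`.
#'
#' @param block a `haplotype_block`.
#' @param L sequence length in bp (> 0); defaults to the block's
#'   `length_bp`.
#' @return per-site pi (numeric scalar).
#' @export
nucleotide_diversity <- function(block, L = block$length_bp) {
  if (is.null(L) || L <= 0) stop("L must be > 0")
  if (n_haplotypes(block) < 2) stop("need at least 2 haplotypes")
  pi_total(block) / L
}

#' Mean pairwise differences (unscaled pi)
#'
#' Sum over sites of `2 p (1-p) n/(n-1)` — equivalently the average
#' allele mismatch count over all haplotype pairs.
#'
#' @param block a `haplotype_block`.
#' @return mean pairwise difference count (numeric scalar).
#' @export
pi_total <- function(block) {
  n <- n_haplotypes(block)
  if (n < 2) stop("need at least 2 haplotypes")
  k <- derived_counts(block)
  sum(k * (n - k)) / choose(n, 2)
}

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Undefined (NA with
#' `defined = FALSE`) when there are no segregating sites; an undefined
#' value is never coerced to zero.
#'
#' @param block a `haplotype_block`.
#' @return list with `D`, `defined`, `S`, `pi_total`, `theta_w`.
#' @export
tajimas_d <- function(block) {
  n <- n_haplotypes(block)
  if (n < 2) stop("need at least 2 haplotypes")
  sc <- .seg_counts(block)
  S <- length(sc$counts)
  cst <- sfs_constants(n)
  pt <- sum(sc$counts * (n - sc$counts)) / choose(n, 2)
  theta_w <- S / cst$a1
  if (S == 0L)
    return(list(D = NA_real_, defined = FALSE, S = 0L, pi_total = 0,
                theta_w = 0))
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  D <- if (v > 0) (pt - theta_w) / sqrt(v) else NA_real_
  list(D = D, defined = is.finite(D), S = S, pi_total = pt,
       theta_w = theta_w)
}

#' Fu and Li's D* and F* (outgroup-free star statistics)
#'
#' Star variants use minor-allele singletons (derived count 1 or n-1),
#' so no ancestral polarization is needed:
#' `D* = ((n/(n-1))*S - a1*eta_s) / sqrt(var)`,
#' `F* = (pi_total - ((n-1)/n)*eta_s) / sqrt(var)`,
#' with each variance estimated as `alpha*theta_hat + beta*theta2_hat`
#' where `theta_hat = S/a1`, `theta2_hat = S(S-1)/(a1^2+a2)` and
#' `(alpha, beta)` are the exact neutral-coalescent variance
#' coefficients of the numerator (see [sfs_constants()]).
#'
#' @param block a `haplotype_block`.
#' @return list with `D_star`, `F_star`, `defined`, `S`, `eta_s`.
#' @export
fu_li_star <- function(block) {
  n <- n_haplotypes(block)
  if (n < 4)
    return(list(D_star = NA_real_, F_star = NA_real_, defined = FALSE,
                S = NA_integer_, eta_s = NA_integer_))
  sc <- .seg_counts(block)
  S <- length(sc$counts)
  if (S == 0L)
    return(list(D_star = NA_real_, F_star = NA_real_, defined = FALSE,
                S = 0L, eta_s = 0L))
  cst <- sfs_constants(n)
  eta_s <- sum(sc$counts == 1L | sc$counts == (n - 1L))
  theta_hat <- S / cst$a1
  theta2_hat <- S * (S - 1) / (cst$a1^2 + cst$a2)
  pt <- sum(sc$counts * (n - sc$counts)) / choose(n, 2)

  num_d <- (n / (n - 1)) * S - cst$a1 * eta_s
  var_d <- cst$dstar_alpha * theta_hat + cst$dstar_beta * theta2_hat
  num_f <- pt - ((n - 1) / n) * eta_s
  var_f <- cst$fstar_alpha * theta_hat + cst$fstar_beta * theta2_hat

  D_star <- if (var_d > 0) num_d / sqrt(var_d) else NA_real_
  F_star <- if (var_f > 0) num_f / sqrt(var_f) else NA_real_
  list(D_star = D_star, F_star = F_star,
       defined = is.finite(D_star) && is.finite(F_star),
       S = S, eta_s = eta_s)
}

#' Fay and Wu's H (unnormalized)
#'
#' `H = pi_total - theta_H` with `theta_H = sum_i 2 i^2 xi_i / (n(n-1))`,
#' computed over polarized segregating sites only (derived counts are
#' meaningless where the ancestral state is unknown; such sites are
#' excluded and counted).
#'
#' @param block a `haplotype_block`.
#' @return list with `H`, `defined`, `theta_H`, `pi_polarized`,
#'   `n_excluded` (segregating sites skipped for unknown ancestral state).
#' @export
fay_wu_h <- function(block) {
  n <- n_haplotypes(block)
  if (n < 2) stop("need at least 2 haplotypes")
  sc <- .seg_counts(block)
  excl <- sum(!sc$known)
  k <- sc$counts[sc$known]
  if (length(k) == 0L) {
    return(list(H = NA_real_, defined = FALSE, theta_H = NA_real_,
                pi_polarized = NA_real_, n_excluded = excl))
  }
  denom <- n * (n - 1)
  theta_H <- sum(2 * k^2) / denom
  pi_pol <- sum(2 * k * (n - k)) / denom
  list(H = pi_pol - theta_H, defined = TRUE, theta_H = theta_H,
       pi_polarized = pi_pol, n_excluded = excl)
}

#' Observed heterozygosity over diploid samples
#'
#' Pairs consecutive haplotype rows (1,2), (3,4), ... into diploid
#' samples and returns the mean over sites of the fraction of samples
#' whose two haplotypes carry different alleles.
#'
#' @param block a `haplotype_block` with an even number of haplotypes.
#' @return mean observed heterozygosity (0 when the block has no sites).
#' @export
observed_heterozygosity <- function(block) {
  n <- n_haplotypes(block)
  if (n %% 2L != 0L) stop("observed heterozygosity needs an even number of haplotypes (diploid pairing)")
  if (n_sites(block) == 0L) return(0)
  h1 <- block$alleles[seq(1L, n, by = 2L), , drop = FALSE]
  h2 <- block$alleles[seq(2L, n, by = 2L), , drop = FALSE]
  mean(colMeans(h1 != h2))
}

#' Full SFS summary of a haplotype block
#'
#' One row of windowed output: haplotype count, segregating sites,
#' singletons, pairwise diversity (total and per site), Watterson's
#' theta, Tajima's D, Fu & Li's D*/F*, and Fay & Wu's H, with
#' definedness flags. Statistics undefined at `S = 0` (or `n < 4` for
#' the starred tests) are NA and flagged, never zero.
#'
#' @param block a `haplotype_block`.
#' @param L sequence length for per-site scaling; defaults to the
#'   block's `length_bp`.
#' @return a one-row `data.frame`.
#' @export
sfs_summary <- function(block, L = block$length_bp) {
  n <- n_haplotypes(block)
  sc <- .seg_counts(block)
  S <- length(sc$counts)
  cst <- sfs_constants(n)
  pt <- sum(sc$counts * (n - sc$counts)) / choose(n, 2)
  td <- tajimas_d(block)
  fl <- fu_li_star(block)
  fw <- fay_wu_h(block)
  eta_s <- if (S) sum(sc$counts == 1L | sc$counts == (n - 1L)) else 0L
  data.frame(
    n = n, S = S, eta_s = eta_s,
    pi_total = pt, pi_site = pt / L, theta_w = S / cst$a1, L = L,
    D = td$D, D_defined = td$defined,
    D_star = fl$D_star, F_star = fl$F_star, star_defined = fl$defined,
    H = fw$H, H_defined = fw$defined, H_excluded = fw$n_excluded,
    stringsAsFactors = FALSE)
}
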