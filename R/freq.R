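#' Weir-Cockerham F_ST from phased haplotypes
#'
#' Haploid reduction of the Weir & Cockerham (1984) estimator, with
#' haplotypes as the sampling units (the within-individual
#' heterozygosity component vanishes). For each site, with `r`
#' populations of sizes `n_i` and derived-allele frequencies `p_i`:
#' \deqn{\bar n = \sum n_i / r,\quad
#'   n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1),\quad
#'   \bar p = \sum n_i p_i/(r\bar n),\quad
#'   s^2 = \sum n_i (p_i-\bar p)^2/((r-1)\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r} s^2\right)\right],\quad
#'   b = \frac{\bar n}{\bar n - 1}\left[\bar p (1-\bar p) -
#'   \frac{r-1}{r} s^2\right],\quad \hat\theta = a/(a+b)}
#' Sites monomorphic across the pooled sample are flagged undefined.
#' Negative per-site estimates are retained (not clamped), and both
#' multi-locus aggregates are reported: the mean of per-site
#' \eqn{\hat\theta} and the ratio of sums \eqn{\sum a / \sum(a+b)}.
#'
#' @param block a `haplotype_block`.
#' @param panel a `population_panel`.
#' @param pops populations to include (default: all in the panel that
#'   occur in the block).
#' @param level `"population"` or `"superpopulation"` grouping.
#' @return list with `per_site` data.frame (`pos, a, b, theta, defined`)
#'   and aggregates `mean_theta`, `ratio_of_sums`.
#' @export
weir_cockerham_fst <- function(block, panel, pops = NULL,
                               level = "population") {
  gp <- haplotype_populations(block, panel, level = level)
  if (is.null(pops)) pops <- sort(unique(gp))
  missing_pops <- setdiff(pops, unique(gp))
  if (length(missing_pops))
    stop(sprintf("population(s) absent from block: %s",
                 paste(missing_pops, collapse = ", ")))
  r <- length(pops)
  if (r < 2) stop("need at least 2 populations")
  rows <- lapply(pops, function(p) block$alleles[gp == p, , drop = FALSE])
  ni <- vapply(rows, nrow, 1L)
  counts <- vapply(rows, colSums, numeric(n_sites(block)))
  if (n_sites(block) == 1L) counts <- matrix(counts, nrow = 1L)
  pmat <- sweep(counts, 2L, ni, "/")          # sites x pops
  nbar <- sum(ni) / r
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- as.vector(pmat %*% ni) / (r * nbar)
  s2 <- as.vector(((pmat - pbar)^2) %*% ni) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2)
  pooled <- rowSums(sweep(pmat, 2L, ni, "*"))
  defined <- pooled > 0 & pooled < sum(ni)
  theta <- ifelse(defined & (a + b) != 0, a / (a + b), NA_real_)
  a[!defined] <- NA_real_
  b[!defined] <- NA_real_
  per_site <- data.frame(pos = block$positions, a = a, b = b,
                         theta = theta, defined = defined & !is.na(theta))
  ok <- per_site$defined
  list(per_site = per_site,
       mean_theta = if (any(ok)) mean(theta[ok]) else NA_real_,
       ratio_of_sums = if (any(ok)) sum(a[ok]) / sum(a[ok] + b[ok]) else NA_real_,
       pops = pops, n_per_pop = stats::setNames(ni, pops))
}

#' Global and pairwise F_ST per site
#'
#' Global F_ST is the multi-population Weir-Cockerham estimate over a
#' stated population triple (or any set); pairwise F_ST is the
#' two-population estimate over pooled superpopulation groups.
#'
#' @param block a `haplotype_block`.
#' @param panel a `population_panel`.
#' @param global_pops populations for the global estimate (default: all
#'   populations).
#' @param pairwise_level grouping level for pairwise comparisons
#'   (default `"superpopulation"`).
#' @return list with `global` (per-site data.frame plus aggregates) and
#'   `pairwise` (named list of [weir_cockerham_fst()] results, names
#'   `"A-B"`).
#' @export
global_and_pairwise_fst <- function(block, panel, global_pops = NULL,
                                    pairwise_level = "superpopulation") {
  glob <- weir_cockerham_fst(block, panel, pops = global_pops)
  sp <- sort(unique(haplotype_populations(block, panel,
                                          level = pairwise_level)))
  pairs <- if (length(sp) >= 2) utils::combn(sp, 2, simplify = FALSE) else list()
  pw <- lapply(pairs, function(pr)
    weir_cockerham_fst(block, panel, pops = pr, level = pairwise_level))
  names(pw) <- vapply(pairs, paste, character(1), collapse = "-")
  list(global = glob, pairwise = pw)
}

#' Per-site minor and derived allele frequencies
#'
#' MAF is `min(p, 1-p)` of the pooled (or per-population) frequency and
#' is always defined; DAF is the derived-allele frequency and is
#' undefined (NA) at sites whose ancestral state is unknown.
#'
#' @param block a `haplotype_block`.
#' @param panel optional `population_panel`; when given, per-population
#'   frequencies are appended as `daf_<pop>` columns.
#' @return data.frame with `pos`, `maf`, `daf`, `ancestral_known`, and
#'   optional per-population DAF columns.
#' @export
maf_daf <- function(block, panel = NULL) {
  n <- n_haplotypes(block)
  p <- derived_counts(block) / n
  out <- data.frame(pos = block$positions,
                    maf = pmin(p, 1 - p),
                    daf = ifelse(block$ancestral_known, p, NA_real_),
                    ancestral_known = block$ancestral_known)
  if (!is.null(panel)) {
    gp <- haplotype_populations(block, panel)
    for (pop in sort(unique(gp))) {
      sub <- block$alleles[gp == pop, , drop = FALSE]
      pp <- colSums(sub) / nrow(sub)
      out[[paste0("daf_", pop)]] <- ifelse(block$ancestral_known, pp, NA_real_)
    }
  }
  out
}

#' Bin allele-frequency values into a spectrum
#'
#' Half-open, left-closed bins `[e_k, e_{k+1})`; a value exactly on an
#' interior edge belongs to the right-hand bin. The final bin is closed
#' on the right so a value equal to the last edge is counted. Undefined
#' (NA) values are excluded and counted separately.
#'
#' @param values numeric values in `[0, 1]` (NA allowed).
#' @param edges strictly increasing bin edges.
#' @return list with `counts` (named by `[a,b)`), `n_undefined`.
#' @export
bin_spectrum <- function(values, edges) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  defined <- values[!is.na(values)]
  if (any(defined < 0 | defined > 1)) stop("values must lie in [0, 1]")
  counts <- integer(length(edges) - 1L)
  for (k in seq_along(counts)) {
    hi_ok <- if (k == length(counts)) defined <= edges[k + 1L] else defined < edges[k + 1L]
    counts[k] <- sum(defined >= edges[k] & hi_ok)
  }
  names(counts) <- paste0("[", edges[-length(edges)], ",", edges[-1],
                          ifelse(seq_along(counts) == length(counts), "]", ")"))
  list(counts = counts, n_undefined = sum(is.na(values)))
}

#' Score sites against a conservation track
#'
#' Per-site score lookup: a site outside every run has an undefined
#' score and is non-conserved at any threshold.
#'
#' @param positions 0-based site positions.
#' @param track a `conservation_track`.
#' @param chrom chromosome of the positions.
#' @return numeric vector of scores (NA where uncovered).
#' @export
site_scores <- function(positions, track, chrom = "chr1") {
  d <- track[track$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, length(positions))
  if (nrow(d) == 0) return(out)
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(start = positions + 1, width = 1L),
    IRanges::IRanges(start = d$start + 1, end = d$end))
  out[S4Vectors::queryHits(ov)] <- d$score[S4Vectors::subjectHits(ov)]
  out
}

#' Classify sites as conserved at one or more score thresholds
#'
#' Inclusive on the conserved side (score >= threshold); missing scores
#' are non-conserved at every threshold, so conserved-at-3 is always a
#' subset of conserved-at-2.
#'
#' @param positions 0-based site positions.
#' @param track a `conservation_track`.
#' @param thresholds numeric thresholds (default `c(2, 3)`).
#' @param chrom chromosome of the positions.
#' @return data.frame with `pos`, `score`, and one logical
#'   `conserved_ge_<t>` column per threshold.
#' @export
classify_conservation <- function(positions, track, thresholds = c(2, 3),
                                  chrom = "chr1") {
  sc <- site_scores(positions, track, chrom = chrom)
  out <- data.frame(pos = positions, score = sc)
  for (t in thresholds)
    out[[paste0("conserved_ge_", t)]] <- !is.na(sc) & sc >= t
  out
}

#' Fraction of element length with score at or above a threshold
#'
#' Per element class: the proportion of bases covered by score runs
#' with `score >= threshold`. Uncovered bases count as below threshold.
#'
#' @param elements an `element_track`.
#' @param track a `conservation_track`.
#' @param threshold score threshold.
#' @return data.frame with `class`, `total_length`, `conserved_length`,
#'   `fraction`.
#' @export
element_conserved_fraction <- function(elements, track, threshold) {
  hi <- track[track$score >= threshold, , drop = FALSE]
  res <- lapply(split(as.data.frame(elements), elements$class), function(d) {
    total <- sum(d$end - d$start)
    cons <- 0
    for (ch in unique(d$chrom)) {
      e <- d[d$chrom == ch, , drop = FALSE]
      h <- hi[hi$chrom == ch, , drop = FALSE]
      if (nrow(h) == 0) next
      ir_e <- IRanges::IRanges(start = e$start + 1, end = e$end)
      ir_h <- IRanges::reduce(IRanges::IRanges(start = h$start + 1, end = h$end))
      cons <- cons + sum(IRanges::width(IRanges::intersect(ir_e, ir_h)))
    }
    data.frame(class = d$class[1], total_length = total,
               conserved_length = cons, fraction = cons / total)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of sites with low derived-allele frequency
#'
#' Proportion of defined-DAF sites with `DAF <= cutoff` (the rare-
#' variant excess that purifying selection produces). Sites with
#' undefined DAF are excluded from the denominator.
#'
#' @param daf numeric DAF values (NA allowed).
#' @param cutoff inclusive upper bound (default 0.05).
#' @return list with `fraction`, `n_low`, `n_defined`.
#' @export
fraction_low_daf <- function(daf, cutoff = 0.05) {
  d <- daf[!is.na(daf)]
  list(fraction = if (length(d)) mean(d <= cutoff) else NA_real_,
       n_low = sum(d <= cutoff), n_defined = length(d))
}
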