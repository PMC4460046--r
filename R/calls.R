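#' Enrichment of a predicate in an element versus the background
#'
#' Builds the 2x2 table (element/background x predicate yes/no), tests
#' it with Pearson's chi-square (1 d.f., no continuity correction by
#' default; Yates behind a flag), substitutes Fisher's exact test when
#' any expected cell is below 5, and reports the observed/expected
#' enrichment ratio `P_O / P_E` = (element fraction) / (background
#' fraction). Sites where the predicate is undefined (NA) are excluded
#' from both groups symmetrically.
#'
#' @param element_values,background_values logical vectors (predicate
#'   evaluated per site; NA = undefined).
#' @param yates apply Yates continuity correction to the chi-square.
#' @return data.frame: counts, `chisq`, `p_chisq`, `fisher_used`,
#'   `p` (the reported P: Fisher when substituted), `ratio`,
#'   `direction` (`"enriched"`/`"depleted"`/`"none"`).
#' @export
enrichment_test <- function(element_values, background_values,
                            yates = FALSE) {
  x <- element_values[!is.na(element_values)]
  y <- background_values[!is.na(background_values)]
  if (length(x) == 0 || length(y) == 0)
    stop("both element and background must have defined values")
  tab <- matrix(c(sum(x), sum(!x), sum(y), sum(!y)), 2, byrow = TRUE,
                dimnames = list(c("element", "background"),
                                c("yes", "no")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  fisher_used <- any(expected < 5)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  pf <- stats::fisher.test(tab)$p.value
  fe <- mean(x); fb <- mean(y)
  ratio <- if (fb == 0) {
    if (fe > 0) Inf else NA_real_
  } else fe / fb
  direction <- if (is.na(ratio) || ratio == 1) "none"
  else if (ratio > 1) "enriched" else "depleted"
  data.frame(element_yes = sum(x), element_no = sum(!x),
             background_yes = sum(y), background_no = sum(!y),
             chisq = unname(cs$statistic), p_chisq = cs$p.value,
             p_fisher = pf, fisher_used = fisher_used,
             p = if (fisher_used) pf else cs$p.value,
             ratio = ratio, direction = direction,
             stringsAsFactors = FALSE)
}

#' Empirical top-quantile threshold
#'
#' The cutoff for "top `q` fraction" selection: the `(1-q)` empirical
#' quantile over defined values; values tied with the cutoff are
#' included above it (callers use `>=` on this threshold).
#'
#' @param values numeric vector (NA dropped).
#' @param q tail fraction (default 0.01 for top 1%).
#' @return the threshold value.
#' @export
top_quantile_threshold <- function(values, q = 0.01) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no defined values")
  stats::quantile(v, probs = 1 - q, names = FALSE, type = 7)
}

#' Composite positive-selection caller
#'
#' Applies the three criteria `DAF > daf_min`, `F_ST > fst_min`,
#' `|iHS| > ihs_min` (strict inequalities; an undefined statistic never
#' satisfies its criterion) and calls a site when at least `k` criteria
#' are met. Thresholds are recorded with every row.
#'
#' @param records data.frame with columns `daf`, `fst`, `ihs`
#'   (standardized iHS; sign retained, magnitude compared) and
#'   optionally `pos`/`chrom`/other columns carried through.
#' @param daf_min,fst_min,ihs_min criterion thresholds
#'   (defaults 0.5, 0.3, 2).
#' @param k minimum criteria met for a call (default 2).
#' @return `records` with logical `crit_daf`, `crit_fst`, `crit_ihs`,
#'   integer `n_criteria_met`, logical `called`, and the thresholds.
#' @export
call_selection <- function(records, daf_min = 0.5, fst_min = 0.3,
                           ihs_min = 2, k = 2) {
  records <- as.data.frame(records)
  records$crit_daf <- !is.na(records$daf) & records$daf > daf_min
  records$crit_fst <- !is.na(records$fst) & records$fst > fst_min
  records$crit_ihs <- !is.na(records$ihs) & abs(records$ihs) > ihs_min
  records$n_criteria_met <- records$crit_daf + records$crit_fst +
    records$crit_ihs
  records$called <- records$n_criteria_met >= k
  records$daf_min <- daf_min
  records$fst_min <- fst_min
  records$ihs_min <- ihs_min
  records$k <- k
  records
}

#' Annotate calls with overlapping or 5 kb flanking genes
#'
#' A gene is attached to a call iff the call position lies within
#' `[start - flank, end + flank)` of the gene (half-open on the right,
#' so a position exactly `flank` bp beyond the end — or exactly
#' `flank` bp before the start — is not attached). Multiple genes are
#' all attached, sorted by distance (0 inside the gene) then name.
#'
#' @param calls data.frame with `pos` (and optionally `chrom`).
#' @param genes a `gene_track`.
#' @param flank flank size in bp (default 5000).
#' @return `calls` with a `genes` character column
#'   (comma-separated, `""` when none).
#' @export
annotate_genes <- function(calls, genes, flank = 5000) {
  calls <- as.data.frame(calls)
  chrom <- if (!is.null(calls$chrom)) calls$chrom else
    rep(genes$chrom[1] %||% "chr1", nrow(calls))
  ann <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    p <- calls$pos[i]
    hit <- p >= g$start - flank & p < g$end + flank
    if (!any(hit)) { ann[i] <- ""; next }
    g <- g[hit, , drop = FALSE]
    dist <- pmax(0, pmax(g$start - p, p - (g$end - 1)))
    ord <- order(dist, g$gene)
    ann[i] <- paste(g$gene[ord], collapse = ",")
  }
  calls$genes <- ann
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DAF spectrum of risk-derived versus non-risk-derived variants
#'
#' Bins the derived-allele frequencies of two variant groups — those
#' whose risk allele is the derived allele and those whose is not —
#' and tests each bin's 2x2 table (group x in-bin/out-of-bin) with
#' Fisher's exact test. This is the machinery behind comparing the
#' frequency spectra of risk-derived and non-risk-derived variants.
#'
#' @param risk_table data.frame with `daf` and logical `risk_is_derived`.
#' @param edges DAF bin edges (default 0 to 1 by 0.1).
#' @return data.frame per bin: counts in each group, Fisher P.
#' @export
gwas_daf_profile <- function(risk_table, edges = seq(0, 1, by = 0.1)) {
  g1 <- risk_table$daf[risk_table$risk_is_derived]
  g2 <- risk_table$daf[!risk_table$risk_is_derived]
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) == 0 || length(g2) == 0)
    stop("both groups must be non-empty")
  c1 <- bin_spectrum(g1, edges)$counts
  c2 <- bin_spectrum(g2, edges)$counts
  p <- vapply(seq_along(c1), function(k) {
    tab <- matrix(c(c1[k], length(g1) - c1[k],
                    c2[k], length(g2) - c2[k]), 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(bin = names(c1), risk_derived = as.integer(c1),
             non_risk_derived = as.integer(c2), p_fisher = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Thin wrapper over `p.adjust(method = "BH")`, provided for FDR
#' control over families of enrichment tests.
#'
#' @param p numeric vector of P-values.
#' @return adjusted P-values.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")
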