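#' Extended haplotype homozygosity from a core site
#'
#' Among carriers of the given allele at the core site, walks marker by
#' marker in one direction; at marker `x`,
#' `EHH(x) = sum_h C(c_h,2) / C(c,2)` where `c` is the carrier count
#' and `c_h` the number of carriers sharing extended haplotype `h` from
#' the core through `x` (alleles compared at every intervening
#' polymorphic site). `EHH(core) = 1` and the curve is non-increasing.
#'
#' @param block a `haplotype_block`.
#' @param core_index column index of the core site.
#' @param allele 0 (ancestral) or 1 (derived) core allele.
#' @param direction `"right"` (increasing positions) or `"left"`.
#' @param stop_below stop extending once EHH falls below this level
#'   (0 = walk until EHH reaches 0 or the data end). Integration with a
#'   cutoff only needs the first point below the cutoff.
#' @return data.frame with `pos` and `ehh`, first row at the core.
#' @export
ehh <- function(block, core_index, allele,
                direction = c("right", "left"), stop_below = 0) {
  direction <- match.arg(direction)
  carriers <- which(block$alleles[, core_index] == allele)
  c0 <- length(carriers)
  if (c0 < 2) stop("EHH needs at least 2 carriers of the core allele")
  idx <- if (direction == "right") {
    seq(core_index, n_sites(block))
  } else {
    seq(core_index, 1L)
  }
  denom <- choose(c0, 2)
  grp <- rep(1L, c0)
  pos <- numeric(length(idx))
  val <- numeric(length(idx))
  pos[1L] <- block$positions[core_index]
  val[1L] <- 1
  k <- 1L
  for (j in idx[-1L]) {
    key <- grp * 2L + block$alleles[carriers, j]
    grp <- match(key, unique(key))
    k <- k + 1L
    pos[k] <- block$positions[j]
    cnt <- tabulate(grp)
    val[k] <- sum(cnt * (cnt - 1L) / 2) / denom
    if (val[k] == 0 || val[k] < stop_below) break
  }
  data.frame(pos = pos[seq_len(k)], ehh = val[seq_len(k)])
}

#' Integrated EHH (one direction)
#'
#' Trapezoidal integral of an EHH curve over physical distance,
#' truncated where the curve falls below `cutoff` (the final segment is
#' integrated to the linearly interpolated crossing point). Extension
#' also stops, with a QC flag, at inter-marker gaps larger than
#' `max_gap` or at the end of the data (edge truncation).
#'
#' @param curve data.frame from [ehh()] (`pos`, `ehh`), first row the
#'   core with `ehh = 1`.
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap largest allowed inter-marker gap in bp.
#' @return list with `ihh` (bp x EHH units), `truncated_by_edge`,
#'   `truncated_by_gap`.
#' @export
ihh <- function(curve, cutoff = 0.05, max_gap = 200000) {
  if (nrow(curve) == 0 || curve$ehh[1] != 1)
    stop("EHH curve must start at 1 at the core")
  area <- 0
  edge <- TRUE
  gap <- FALSE
  if (nrow(curve) >= 2) {
    for (k in seq_len(nrow(curve) - 1L)) {
      x0 <- curve$pos[k]; x1 <- curve$pos[k + 1L]
      e0 <- curve$ehh[k]; e1 <- curve$ehh[k + 1L]
      w <- abs(x1 - x0)
      if (w > max_gap) { gap <- TRUE; edge <- FALSE; break }
      if (e1 < cutoff) {
        xc <- w * (e0 - cutoff) / (e0 - e1)
        area <- area + (e0 + cutoff) / 2 * xc
        edge <- FALSE
        break
      }
      area <- area + (e0 + e1) / 2 * w
    }
  }
  list(ihh = area, truncated_by_edge = edge, truncated_by_gap = gap)
}

# iHH for one allele at one core: both directions summed.
.ihh_allele <- function(block, core_index, allele, cutoff, max_gap) {
  r <- ihh(ehh(block, core_index, allele, "right", stop_below = cutoff),
           cutoff, max_gap)
  l <- ihh(ehh(block, core_index, allele, "left", stop_below = cutoff),
           cutoff, max_gap)
  list(ihh = r$ihh + l$ihh,
       truncated_by_edge = r$truncated_by_edge || l$truncated_by_edge,
       truncated_by_gap = r$truncated_by_gap || l$truncated_by_gap)
}

#' iHS scan over core sites
#'
#' For every site with known ancestral state and MAF at or above
#' `min_maf`, computes integrated EHH for the ancestral and derived
#' backgrounds and the unstandardized score
#' `iHS = ln(iHH_A / iHH_D)`. Scores are then standardized within
#' derived-allele-frequency bins (subtract bin mean, divide by bin SD),
#' either against the scan's own scores or against reference bin
#' statistics from [ihs_bin_stats()] (e.g. a neutral genome-wide scan,
#' the usual standardization background). Bins holding fewer than two
#' scores leave their scores unstandardized and flagged.
#'
#' @param block a `haplotype_block`.
#' @param min_maf minimum minor-allele frequency of a core site.
#' @param cutoff EHH truncation level.
#' @param max_gap largest allowed inter-marker gap (bp).
#' @param bin_width derived-frequency bin width for standardization.
#' @param ref_stats optional data.frame from [ihs_bin_stats()] used as
#'   the standardization reference.
#' @param core_indices optional subset of site columns to scan.
#' @return data.frame: `core_index`, `pos`, `daf`, `ihh_a`, `ihh_d`,
#'   `ihs_uns`, `ihs_std`, `standardized`, `truncated_by_edge`,
#'   `truncated_by_gap`, `skipped` (low MAF / undefined iHH).
#' @export
ihs_scan <- function(block, min_maf = 0.05, cutoff = 0.05,
                     max_gap = 200000, bin_width = 0.05,
                     ref_stats = NULL, core_indices = NULL) {
  n <- n_haplotypes(block)
  k <- derived_counts(block)
  p <- k / n
  maf <- pmin(p, 1 - p)
  if (is.null(core_indices)) core_indices <- seq_len(n_sites(block))
  m <- length(core_indices)
  daf <- ihh_a <- ihh_d <- ihs_uns <- rep(NA_real_, m)
  tedge <- tgap <- rep(FALSE, m)
  skipped <- rep(TRUE, m)
  for (u in seq_len(m)) {
    j <- core_indices[u]
    if (!block$ancestral_known[j] || maf[j] < min_maf) next
    if (min(k[j], n - k[j]) < 2L) next  # EHH undefined with < 2 carriers
    daf[u] <- p[j]
    a <- .ihh_allele(block, j, 0L, cutoff, max_gap)
    d <- .ihh_allele(block, j, 1L, cutoff, max_gap)
    ihh_a[u] <- a$ihh; ihh_d[u] <- d$ihh
    tedge[u] <- a$truncated_by_edge || d$truncated_by_edge
    tgap[u] <- a$truncated_by_gap || d$truncated_by_gap
    if (a$ihh > 0 && d$ihh > 0) {
      ihs_uns[u] <- log(a$ihh / d$ihh)
      skipped[u] <- FALSE
    }
  }
  scan <- data.frame(core_index = core_indices,
                     pos = block$positions[core_indices],
                     daf = daf, ihh_a = ihh_a, ihh_d = ihh_d,
                     ihs_uns = ihs_uns, truncated_by_edge = tedge,
                     truncated_by_gap = tgap, skipped = skipped)
  standardize_ihs(scan, bin_width = bin_width, ref_stats = ref_stats)
}

# frequency-bin assignment robust to floating point at exact multiples
.daf_bin <- function(daf, bin_width) {
  floor(daf / bin_width + 1e-9) * bin_width
}

#' Per-bin mean and SD of unstandardized iHS
#'
#' @param scan data.frame with `daf` and `ihs_uns` columns (typically a
#'   pooled neutral reference scan).
#' @param bin_width derived-frequency bin width.
#' @return data.frame `bin` (left edge), `mean`, `sd`, `n`.
#' @export
ihs_bin_stats <- function(scan, bin_width = 0.05) {
  ok <- !is.na(scan$ihs_uns)
  bin <- .daf_bin(scan$daf[ok], bin_width)
  agg <- lapply(split(scan$ihs_uns[ok], bin), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- do.call(rbind, agg)
  out$bin <- as.numeric(rownames(out))
  rownames(out) <- NULL
  out[, c("bin", "mean", "sd", "n")]
}

#' Standardize iHS scores within derived-frequency bins
#'
#' @param scan data.frame with `daf` and `ihs_uns` columns.
#' @param bin_width derived-frequency bin width.
#' @param ref_stats optional [ihs_bin_stats()] reference; default uses
#'   the scan's own scores.
#' @return `scan` with `ihs_std` and `standardized` columns appended.
#' @export
standardize_ihs <- function(scan, bin_width = 0.05, ref_stats = NULL) {
  if (is.null(ref_stats)) ref_stats <- ihs_bin_stats(scan, bin_width)
  bin <- .daf_bin(scan$daf, bin_width)
  idx <- match(round(bin, 10), round(ref_stats$bin, 10))
  m <- ref_stats$mean[idx]
  s <- ref_stats$sd[idx]
  nref <- ref_stats$n[idx]
  usable <- !is.na(scan$ihs_uns) & !is.na(s) & nref >= 2 & s > 0
  scan$ihs_std <- ifelse(usable, (scan$ihs_uns - m) / s, scan$ihs_uns)
  scan$standardized <- usable
  scan
}
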