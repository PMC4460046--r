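#' Phased haplotype block
#'
#' The central container of the package: a matrix of phased biallelic
#' alleles over haplotypes (rows) and polymorphic sites (columns), with
#' physical positions and per-site ancestral-state annotation. Alleles are
#' coded 0 = ancestral, 1 = derived at sites where the ancestral allele is
#' known; at sites where it is not (`ancestral_known = FALSE`) the coding
#' is an arbitrary but consistent 0/1 labelling (e.g. ALT count from a
#' VCF) and any statistic requiring polarization must skip the site.
#'
#' Positions are 0-based and refer to the half-open coordinate system used
#' throughout the package; VCF input/output converts at the boundary.
#'
#' @param alleles integer/numeric matrix, n_haplotypes x n_sites, entries 0/1.
#' @param positions 0-based physical positions, strictly increasing,
#'   one per site.
#' @param chrom chromosome name (single string).
#' @param ancestral_known logical vector, one per site; defaults to all TRUE.
#' @param sample_ids haplotype labels; defaults to `hap1..hapN`. Diploid
#'   pairing (for observed heterozygosity) takes rows (1,2), (3,4), ...
#' @param length_bp total locus length in bp spanned by the block
#'   (used as the default denominator for per-site statistics); defaults
#'   to `max(positions) + 1`.
#' @return an object of class `haplotype_block`.
#' @export
haplotype_block <- function(alleles, positions, chrom = "chr1",
                            ancestral_known = NULL, sample_ids = NULL,
                            length_bp = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles))
    stop("positions length must equal number of allele columns")
  positions <- as.numeric(positions)
  if (ncol(alleles) > 0L) {
    if (any(is.na(alleles)) || !all(alleles %in% c(0L, 1L)))
      stop("alleles must be 0/1 with no missing values")
    if (any(diff(positions) <= 0))
      stop("positions must be strictly increasing")
  }
  if (is.null(ancestral_known)) ancestral_known <- rep(TRUE, ncol(alleles))
  if (length(ancestral_known) != ncol(alleles))
    stop("ancestral_known length must equal number of sites")
  if (is.null(sample_ids)) sample_ids <- paste0("hap", seq_len(nrow(alleles)))
  if (length(sample_ids) != nrow(alleles))
    stop("sample_ids length must equal number of haplotypes")
  if (is.null(length_bp))
    length_bp <- if (length(positions)) max(positions) + 1 else 0
  structure(
    list(chrom = as.character(chrom)[1],
         positions = positions,
         alleles = alleles,
         ancestral_known = as.logical(ancestral_known),
         sample_ids = as.character(sample_ids),
         length_bp = as.numeric(length_bp)),
    class = "haplotype_block")
}

#' @method print haplotype_block
#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("<haplotype_block> %s: %d haplotypes x %d sites, %s bp\n",
              x$chrom, nrow(x$alleles), ncol(x$alleles),
              format(x$length_bp, big.mark = ",")))
  if (any(!x$ancestral_known))
    cat(sprintf("  %d site(s) with unknown ancestral state\n",
                sum(!x$ancestral_known)))
  invisible(x)
}

#' Number of haplotypes in a block
#' @param block a `haplotype_block`.
#' @return integer haplotype count.
#' @export
n_haplotypes <- function(block) nrow(block$alleles)

#' Number of sites in a block
#' @param block a `haplotype_block`.
#' @return integer site count.
#' @export
n_sites <- function(block) ncol(block$alleles)

#' Restrict a block to a subset of sites
#'
#' @param block a `haplotype_block`.
#' @param idx integer or logical index over sites (columns).
#' @param positions optional replacement positions (used when re-addressing
#'   onto a concatenated axis); must be strictly increasing.
#' @param length_bp optional replacement locus length.
#' @return a `haplotype_block` over the selected sites.
#' @export
subset_sites <- function(block, idx, positions = NULL, length_bp = NULL) {
  if (is.logical(idx)) idx <- which(idx)
  haplotype_block(
    alleles = block$alleles[, idx, drop = FALSE],
    positions = if (is.null(positions)) block$positions[idx] else positions,
    chrom = block$chrom,
    ancestral_known = block$ancestral_known[idx],
    sample_ids = block$sample_ids,
    length_bp = if (is.null(length_bp)) block$length_bp else length_bp)
}

#' Restrict a block to a subset of haplotypes
#'
#' @param block a `haplotype_block`.
#' @param idx integer or logical index over haplotypes (rows).
#' @return a `haplotype_block` over the selected haplotypes.
#' @export
subset_haplotypes <- function(block, idx) {
  haplotype_block(
    alleles = block$alleles[idx, , drop = FALSE],
    positions = block$positions,
    chrom = block$chrom,
    ancestral_known = block$ancestral_known,
    sample_ids = block$sample_ids[idx],
    length_bp = block$length_bp)
}

#' Per-site derived-allele counts
#'
#' Counts of the allele coded 1 at each site. Interpretable as derived
#' counts only where `ancestral_known` is TRUE.
#'
#' @param block a `haplotype_block`.
#' @return integer vector, one count per site.
#' @export
derived_counts <- function(block) {
  if (ncol(block$alleles) == 0L) return(integer(0))
  as.integer(colSums(block$alleles))
}
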