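# All interval containers use 0-based half-open coordinates (BED-native);
# VCF positions are converted on ingest and egress.

.as_granges <- function(df, chrom_sizes = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if (!is.null(chrom_sizes))
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  gr
}

.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Labelled genomic element intervals
#'
#' Validates and normalizes `(chrom, start, end, class)` intervals:
#' `start < end` required; overlapping or bookended intervals of the
#' same class are merged; intervals sorted by chromosome and start.
#'
#' @param df data.frame with columns `chrom, start, end, class`
#'   (0-based half-open).
#' @return a normalized data.frame of class `element_track`.
#' @export
element_track <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(df)))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("interval with start >= end at row %d (%s:%s-%s)",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  parts <- lapply(split(df, df$class), function(d) {
    gr <- GenomicRanges::reduce(.as_granges(d))
    out <- .from_granges(gr)
    out$class <- d$class[1]
    out
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("element_track", "data.frame")
  out
}

#' Gene intervals
#' @param df data.frame with columns `chrom, start, end, gene`
#'   (0-based half-open).
#' @return a data.frame of class `gene_track`.
#' @export
gene_track <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(df)))
  if (any(df$start >= df$end)) stop("gene interval with start >= end")
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("gene_track", "data.frame")
  df
}

#' Per-base conservation score runs
#'
#' `(chrom, start, end, score)` runs, half-open, non-overlapping. Bases
#' not covered by any run have no score and classify as non-conserved
#' at every threshold.
#'
#' @param df data.frame with columns `chrom, start, end, score`.
#' @return a data.frame of class `conservation_track`.
#' @export
conservation_track <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(df)))
  if (any(df$start >= df$end)) stop("score run with start >= end")
  if (any(!is.finite(df$score))) stop("scores must be finite")
  df <- df[order(df$chrom, df$start), ]
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop(sprintf("overlapping score runs on %s", ch))
  }
  rownames(df) <- NULL
  class(df) <- c("conservation_track", "data.frame")
  df
}

#' Sample-to-population panel
#'
#' @param df data.frame with columns
#'   `sample_id, population, superpopulation`.
#' @return a data.frame of class `population_panel`.
#' @export
population_panel <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("sample_id", "population", "superpopulation") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in panel")
  rownames(df) <- NULL
  class(df) <- c("population_panel", "data.frame")
  df
}

#' Population label of each haplotype in a block
#'
#' Haplotype ids carry their sample of origin as `<sample>_h1/_h2`; the
#' suffix is stripped and looked up in the panel. Every haplotype must
#' map to exactly one population.
#'
#' @param block a `haplotype_block`.
#' @param panel a `population_panel`.
#' @param level `"population"` or `"superpopulation"`.
#' @return character vector of population codes, one per haplotype.
#' @export
haplotype_populations <- function(block, panel,
                                  level = c("population", "superpopulation")) {
  level <- match.arg(level)
  samples <- sub("_h[12]$", "", block$sample_ids)
  idx <- match(samples, panel$sample_id)
  if (anyNA(idx))
    stop(sprintf("haplotype sample(s) missing from panel: %s",
                 paste(utils::head(unique(samples[is.na(idx)]), 3), collapse = ", ")))
  panel[[level]][idx]
}

#' Read phased biallelic SNPs from a VCF into a haplotype block
#'
#' Keeps biallelic SNPs only (multiallelic and indel records are skipped
#' with a message). Alleles are polarized to ancestral/derived using the
#' `AA` INFO tag when it matches REF or ALT case-insensitively (only the
#' first `|`-separated field of extended encodings is used); sites where
#' AA is missing or matches neither allele are kept with
#' `ancestral_known = FALSE` and coded by ALT count. Unphased genotypes
#' are an error: every statistic downstream assumes phased haplotypes.
#'
#' @param path VCF file (plain text or gzipped).
#' @param region optional `c(start, end)` filter on 0-based positions.
#' @return a `haplotype_block`.
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", sum(!snp)))
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  pos0 <- as.numeric(fix$POS) - 1
  if (!is.null(region)) {
    keep <- pos0 >= region[1] & pos0 < region[2]
    fix <- fix[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
    pos0 <- pos0[keep]
  }
  gtf <- sub(":.*$", "", gt)
  if (any(grepl("/", gtf, fixed = TRUE)))
    stop("unphased genotype found; phased (|) genotypes are required")
  a1 <- substr(gtf, 1L, 1L)
  a2 <- substr(gtf, 3L, 3L)
  nsamp <- ncol(gt)
  nh <- 2L * nsamp
  S <- nrow(fix)
  alleles <- matrix(0L, nh, S)
  if (S > 0) {
    alleles[seq(1L, nh, 2L), ] <- t(matrix(as.integer(a1), S, nsamp))
    alleles[seq(2L, nh, 2L), ] <- t(matrix(as.integer(a2), S, nsamp))
  }
  aa <- rep(NA_character_, S)
  m <- regmatches(fix$INFO, regexpr("(?:^|;)AA=([^;|]+)", fix$INFO, perl = TRUE))
  has <- grepl("(?:^|;)AA=", fix$INFO, perl = TRUE)
  aa[has] <- toupper(sub("^;?AA=", "", m))
  ancestral_known <- !is.na(aa) & (aa == toupper(fix$REF) | aa == toupper(fix$ALT))
  flip <- ancestral_known & aa == toupper(fix$ALT)
  if (any(flip)) alleles[, flip] <- 1L - alleles[, flip]
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(nsamp))
  ids <- paste0(rep(samples, each = 2L), "_h", rep(1:2, nsamp))
  blk <- haplotype_block(alleles, pos0,
                         chrom = if (S) fix$CHROM[1] else "chr1",
                         ancestral_known = ancestral_known,
                         sample_ids = ids)
  attr(blk, "ref") <- fix$REF
  attr(blk, "alt") <- fix$ALT
  attr(blk, "flipped") <- flip
  blk
}

#' Write a haplotype block as a phased VCF
#'
#' Emits one biallelic SNP per site with phased GT over diploid samples
#' (consecutive haplotype pairs) and an `AA` INFO tag at sites with
#' known ancestral state. REF carries the ancestral allele (arbitrary
#' A/G coding unless the block stores REF/ALT from ingest), so a
#' read-back reproduces the allele matrix exactly.
#'
#' @param block a `haplotype_block` with an even number of haplotypes.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(block, path) {
  n <- n_haplotypes(block)
  if (n %% 2L) stop("VCF output needs an even number of haplotypes")
  S <- n_sites(block)
  ref <- attr(block, "ref"); alt <- attr(block, "alt")
  if (is.null(ref) || length(ref) != S) { ref <- rep("A", S); alt <- rep("G", S) }
  samples <- unique(sub("_h[12]$", "", block$sample_ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (S > 0) {
    h1 <- block$alleles[seq(1L, n, 2L), , drop = FALSE]
    h2 <- block$alleles[seq(2L, n, 2L), , drop = FALSE]
    info <- ifelse(block$ancestral_known, paste0("AA=", ref), ".")
    lines <- vapply(seq_len(S), function(j) {
      gts <- paste0(h1[, j], "|", h2[, j])
      paste(c(block$chrom, format(block$positions[j] + 1, scientific = FALSE),
              ".", ref[j], alt[j], ".", "PASS", info[j], "GT", gts),
            collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' @param path BED file (0-based half-open).
#' @param as `"element"` (name column = element class) or `"gene"`.
#' @return an `element_track` or `gene_track`.
#' @export
read_bed <- function(path, as = c("element", "gene")) {
  as <- match.arg(as)
  gr <- rtracklayer::import(path, format = "BED")
  df <- .from_granges(gr)
  bad <- which(df$start >= df$end)
  if (length(bad)) stop(sprintf("BED line %d has start >= end", bad[1]))
  name <- if (!is.null(gr$name)) gr$name else rep("region", nrow(df))
  if (as == "element") {
    df$class <- name
    element_track(df)
  } else {
    df$gene <- name
    gene_track(df)
  }
}

#' Write an element or gene track as BED4
#' @param track an `element_track` or `gene_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  name <- if (!is.null(track$class)) track$class else track$gene
  df <- data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph conservation-score track
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @return a `conservation_track`.
#' @export
read_score_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- .from_granges(gr)
  df$score <- gr$score
  conservation_track(df)
}

#' Write a conservation track as bedGraph
#' @param track a `conservation_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  df <- data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE), track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample panel TSV (`sample<TAB>pop<TAB>superpop`)
#' @param path TSV path, no header or with header
#'   `sample_id/population/superpopulation`.
#' @return a `population_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "sample_id")) {
    names(df) <- df[1, ]; df <- df[-1, , drop = FALSE]
  }
  names(df)[1:3] <- c("sample_id", "population", "superpopulation")
  population_panel(df[, 1:3])
}

#' Write a sample panel TSV
#' @param panel a `population_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Derive the intergenic track
#'
#' Returns the intervals lying at least `flank` bp (default 10 kb) from
#' every annotated element, labelled `"intergenic"`. When a
#' `haplotype_block` is supplied, intergenic stretches longer than
#' `flank` that contain no variant are removed. With `tile = TRUE`,
#' stretches are additionally cut into `flank`-sized tiles (remainder
#' dropped) — an alternative reading of the derivation rule exposed
#' behind a flag.
#'
#' @param elements an `element_track` of all annotated classes.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param block optional `haplotype_block` for the no-variant filter.
#' @param flank distance from any element (bp).
#' @param tile cut stretches into `flank`-sized tiles.
#' @return an `element_track` with class `"intergenic"`.
#' @export
derive_intergenic <- function(elements, chrom_sizes, block = NULL,
                              flank = 10000, tile = FALSE) {
  if (is.null(chrom_sizes) || is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    d <- elements[elements$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) {
      iv <- data.frame(start = 0, end = len)
    } else {
      dil <- IRanges::reduce(IRanges::IRanges(
        start = pmax(1, d$start + 1 - flank),
        end = pmin(len, d$end + flank)))
      gap <- IRanges::gaps(dil, start = 1, end = len)
      iv <- data.frame(start = IRanges::start(gap) - 1,
                       end = IRanges::end(gap))
    }
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    if (nrow(iv)) { iv$chrom <- ch; out[[ch]] <- iv }
  }
  if (length(out) == 0 || sum(vapply(out, nrow, 1L)) == 0)
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), class = character(0)),
                     class = c("element_track", "data.frame")))
  iv <- do.call(rbind, out)
  if (tile) {
    tiles <- list()
    for (r in seq_len(nrow(iv))) {
      s <- seq(iv$start[r], iv$end[r] - flank, by = flank)
      if (iv$end[r] - iv$start[r] >= flank && length(s))
        tiles[[length(tiles) + 1L]] <- data.frame(
          chrom = iv$chrom[r], start = s, end = s + flank)
    }
    if (!length(tiles))
      return(structure(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), class = character(0)),
                       class = c("element_track", "data.frame")))
    iv <- do.call(rbind, tiles)
  }
  if (!is.null(block)) {
    keep <- vapply(seq_len(nrow(iv)), function(r) {
      if (iv$end[r] - iv$start[r] <= flank) return(TRUE)
      iv$chrom[r] != block$chrom ||
        any(block$positions >= iv$start[r] & block$positions < iv$end[r])
    }, logical(1))
    iv <- iv[keep, , drop = FALSE]
  }
  if (nrow(iv) == 0)
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), class = character(0)),
                     class = c("element_track", "data.frame")))
  iv$class <- "intergenic"
  iv <- iv[, c("chrom", "start", "end", "class")]
  if (tile) {
    # keep tiles as-is: normalization would merge bookended tiles back
    iv <- iv[order(iv$chrom, iv$start), ]
    rownames(iv) <- NULL
    class(iv) <- c("element_track", "data.frame")
    return(iv)
  }
  element_track(iv)
}
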