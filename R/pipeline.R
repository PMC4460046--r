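#' Simulate a full multi-element study genome
#'
#' Builds a single synthetic chromosome from consecutive island-model
#' loci with the structure the downstream scans look for: a neutral
#' background (intron / intergenic-like), constrained element classes
#' with a purifying-selection-skewed SFS (CDS, CNC), and one locus
#' carrying a selective sweep private to the first population (long
#' shared haplotypes, high differentiation). Element, conservation, and
#' gene tracks are generated to match: constrained classes receive high
#' conservation scores with stated probability, and genes are placed
#' inside, within 5 kb of, and far from the sweep core.
#'
#' @param seed RNG seed (the function is deterministic given the seed).
#' @param n_loci number of consecutive loci.
#' @param locus_bp length of each locus (bp).
#' @param n_haplotypes haplotypes per population (even).
#' @param demes number of populations.
#' @param migration scaled migration rate between demes.
#' @param theta per-locus 4*N*mu.
#' @param beta SFS skew exponent inside constrained elements.
#' @param sweep_freq derived-core frequency within the swept population.
#' @param out_prefix if non-NULL, writes `<prefix>.vcf`,
#'   `<prefix>_elements.bed`, `<prefix>_conservation.bedGraph`,
#'   `<prefix>_genes.bed`, `<prefix>_panel.tsv`.
#' @return list with `block`, `panel`, `elements`, `conservation`,
#'   `genes`, `sweep_core_pos`, `chrom_len`, and (when written) `files`.
#' @export
simulate_study <- function(seed, n_loci = 18, locus_bp = 25000,
                           n_haplotypes = 32, demes = 3, migration = 2,
                           theta = 25, beta = 2, sweep_freq = 0.8,
                           out_prefix = NULL) {
  set.seed(seed)
  classes <- rep(c("intron", "CDS", "intron", "CNC", "intron", "intron"),
                 length.out = n_loci)
  sweep_locus <- which(classes == "intron")[2]
  classes[sweep_locus] <- "lincRNA"
  constrained <- c("CDS", "CNC")

  blocks <- vector("list", n_loci)
  elem_rows <- list()
  cons_rows <- list()
  sweep_core_pos <- NA_real_
  panel <- NULL
  for (i in seq_len(n_loci)) {
    offset <- (i - 1) * locus_bp
    cfg <- sim_config(n_haplotypes = n_haplotypes, theta = theta,
                      locus_bp = locus_bp, demes = demes,
                      migration = migration,
                      seed = derive_seed(seed, i))
    sim <- simulate_island(cfg)
    blk <- sim$block
    if (is.null(panel)) panel <- sim$panel
    # element interval occupies the interior of the locus
    e_start <- offset + 2000; e_end <- offset + locus_bp - 2000
    elem_rows[[i]] <- data.frame(chrom = "chr1", start = e_start,
                                 end = e_end, class = classes[i],
                                 stringsAsFactors = FALSE)
    local_elem <- data.frame(chrom = "chr1", start = 2000,
                             end = locus_bp - 2000, class = classes[i])
    if (classes[i] %in% constrained)
      blk <- skew_sfs(blk, local_elem, beta = beta)
    if (i == sweep_locus) {
      blk <- .deme_sweep(blk, sim$panel, pop = "pop1",
                         core_pos = floor(locus_bp / 2),
                         freq = sweep_freq, crossover = 2e-5)
      sweep_core_pos <- attr(blk, "core_pos") + offset
    }
    # high conservation over constrained elements, low elsewhere
    hi <- classes[i] %in% constrained
    chunk <- seq(e_start, e_end, length.out = 11)
    cons_rows[[i]] <- data.frame(
      chrom = "chr1", start = floor(chunk[-11]), end = floor(chunk[-1]),
      score = ifelse(hi & stats::runif(10) < 0.9, 4, 0))
    blk$positions <- blk$positions + offset
    blocks[[i]] <- blk
  }
  chrom_len <- n_loci * locus_bp
  block <- haplotype_block(
    do.call(cbind, lapply(blocks, function(b) b$alleles)),
    unlist(lapply(blocks, function(b) b$positions)),
    chrom = "chr1", sample_ids = blocks[[1]]$sample_ids,
    length_bp = chrom_len)
  elements <- element_track(do.call(rbind, elem_rows))
  conservation <- conservation_track(do.call(rbind, cons_rows))
  genes <- gene_track(data.frame(
    chrom = "chr1",
    start = c(sweep_core_pos - 1000,            # overlaps the core
              sweep_core_pos + 3000,            # within 5 kb
              min(chrom_len - 3000, sweep_core_pos + 60000)),  # far
    end = c(sweep_core_pos + 1000, sweep_core_pos + 5000,
            min(chrom_len - 1000, sweep_core_pos + 62000)),
    gene = c("coreGene", "nearGene", "farGene"),
    stringsAsFactors = FALSE))
  out <- list(block = block, panel = panel, elements = elements,
              conservation = conservation, genes = genes,
              sweep_core_pos = sweep_core_pos, chrom_len = chrom_len)
  if (!is.null(out_prefix)) {
    files <- list(vcf = paste0(out_prefix, ".vcf"),
                  elements = paste0(out_prefix, "_elements.bed"),
                  conservation = paste0(out_prefix, "_conservation.bedGraph"),
                  genes = paste0(out_prefix, "_genes.bed"),
                  panel = paste0(out_prefix, "_panel.tsv"))
    write_vcf(block, files$vcf)
    write_bed(elements, files$elements)
    write_score_track(conservation, files$conservation)
    write_bed(genes, files$genes)
    write_panel(panel, files$panel)
    out$files <- files
  }
  out
}

# Founder-copy sweep restricted to one population of a joint block.
.deme_sweep <- function(block, panel, pop, core_pos, freq, crossover) {
  gp <- haplotype_populations(block, panel)
  rows <- which(gp == pop)
  m <- max(1L, round(freq * length(rows)))
  carriers <- rows[sample.int(length(rows), m)]
  founder <- carriers[1L]
  while (core_pos %in% block$positions) core_pos <- core_pos + 1
  for (h in carriers) {
    d_left <- stats::rgeom(1L, crossover)
    d_right <- stats::rgeom(1L, crossover)
    tract <- block$positions >= core_pos - d_left &
      block$positions <= core_pos + d_right
    block$alleles[h, tract] <- block$alleles[founder, tract]
  }
  core_col <- integer(n_haplotypes(block)); core_col[carriers] <- 1L
  at <- sum(block$positions < core_pos)
  alleles <- cbind(block$alleles[, seq_len(at), drop = FALSE], core_col,
                   block$alleles[, seq_len(ncol(block$alleles)) > at,
                                 drop = FALSE])
  positions <- append(block$positions, core_pos, after = at)
  out <- haplotype_block(alleles, positions, chrom = block$chrom,
                         sample_ids = block$sample_ids,
                         length_bp = block$length_bp)
  attr(out, "core_pos") <- core_pos
  out
}

#' Run the full selection scan from files to tables
#'
#' End-to-end driver: reads a phased VCF, element BED, conservation
#' bedGraph, gene BED, and sample panel; computes per-element sliding-
#' window SFS statistics with bootstrap means and permutation tests
#' against the genome-wide background (in the focal population);
#' per-site MAF/DAF, global and pairwise Weir-Cockerham F_ST,
#' conservation classes; an iHS scan in the focal population; the
#' composite selection caller with gene annotation; and low-DAF
#' enrichment per element class. All outputs are TSV (calls also BED)
#' under `out_dir`. Deterministic under `seed`.
#'
#' @param vcf,elements_bed,conservation_bedgraph,genes_bed,panel_tsv
#'   input file paths.
#' @param out_dir output directory (created if needed).
#' @param focal_pop population whose haplotypes drive the SFS windows,
#'   iHS scan, and per-population DAF of the caller.
#' @param seed RNG seed for bootstrap/permutation.
#' @param window_size,window_step window geometry (bp).
#' @param n_boot,n_perm bootstrap and permutation replicates.
#' @param daf_min,fst_min,ihs_min,k caller thresholds.
#' @param gerp_thresholds conservation thresholds.
#' @return invisible list of the main result tables (also written as
#'   files: `window_stats.tsv`, `element_comparisons.tsv`,
#'   `site_stats.tsv`, `conservation_summary.tsv`, `enrichment.tsv`,
#'   `selection_calls.tsv`, `selection_calls.bed`).
#' @export
run_selection_scan <- function(vcf, elements_bed, conservation_bedgraph,
                               genes_bed, panel_tsv, out_dir,
                               focal_pop = NULL, seed = 1,
                               window_size = 10000, window_step = 5000,
                               n_boot = 1000, n_perm = 1000,
                               daf_min = 0.5, fst_min = 0.3, ihs_min = 2,
                               k = 2, gerp_thresholds = c(2, 3)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  block <- read_vcf(vcf)
  elements <- read_bed(elements_bed, as = "element")
  conservation <- read_score_track(conservation_bedgraph)
  genes <- read_bed(genes_bed, as = "gene")
  panel <- read_panel(panel_tsv)
  gp <- haplotype_populations(block, panel)
  if (is.null(focal_pop)) focal_pop <- sort(unique(gp))[1]
  focal <- subset_haplotypes(block, gp == focal_pop)

  # --- windowed SFS statistics, element vs genome-wide background ----
  background <- sliding_windows(focal, size = window_size,
                                step = window_step)
  win_rows <- list(); cmp_rows <- list()
  for (cl in sort(unique(elements$class))) {
    cc <- concatenate_element(focal, elements, cl)
    w <- sliding_windows(cc$block, size = window_size, step = window_step)
    if (nrow(w)) {
      w <- cbind(element_class = cl, population = focal_pop, w)
      win_rows[[cl]] <- w
      cmp <- lapply(c("D", "pi_site"), function(st)
        tryCatch({
          bs <- bootstrap_mean(w[[st]], n_boot = n_boot,
                               seed = derive_seed(seed, 100 + match(cl, sort(unique(elements$class)))))
          pt <- permutation_test(w[[st]], background[[st]],
                                 n_perm = n_perm,
                                 seed = derive_seed(seed, 200 + match(cl, sort(unique(elements$class)))))
          data.frame(element_class = cl, statistic = st,
                     n_windows = sum(!is.na(w[[st]])),
                     boot_mean = bs$mean, boot_se = bs$se,
                     mean_background = pt$mean_background,
                     delta_obs = pt$delta_obs, p_perm = pt$p)
        }, error = function(e) NULL))
      cmp_rows[[cl]] <- do.call(rbind, cmp)
    }
  }
  window_stats <- do.call(rbind, win_rows)
  comparisons <- do.call(rbind, cmp_rows)

  # --- per-site frequencies, F_ST, conservation ----------------------
  freq <- maf_daf(block, panel)
  fst <- global_and_pairwise_fst(block, panel)
  site <- data.frame(chrom = block$chrom, pos = block$positions,
                     maf = freq$maf, daf = freq$daf,
                     daf_focal = freq[[paste0("daf_", focal_pop)]],
                     fst_global = fst$global$per_site$theta)
  for (nm in names(fst$pairwise))
    site[[paste0("fst_", nm)]] <- fst$pairwise[[nm]]$per_site$theta
  cons <- classify_conservation(block$positions, conservation,
                                thresholds = gerp_thresholds,
                                chrom = block$chrom)
  site <- cbind(site, cons[, -1, drop = FALSE])
  site$element_class <- element_class_of(block$positions, elements,
                                         chrom = block$chrom)

  # --- iHS scan in the focal population ------------------------------
  scan <- ihs_scan(focal)
  site$ihs <- NA_real_
  site$ihs[scan$core_index] <- scan$ihs_std

  # --- caller + gene annotation --------------------------------------
  records <- data.frame(chrom = site$chrom, pos = site$pos,
                        daf = site$daf_focal, fst = site$fst_global,
                        ihs = site$ihs,
                        element_class = site$element_class)
  calls <- call_selection(records, daf_min = daf_min, fst_min = fst_min,
                          ihs_min = ihs_min, k = k)
  calls <- annotate_genes(calls, genes)
  called <- calls[calls$called, , drop = FALSE]

  # --- conservation summary and low-DAF enrichment -------------------
  cons_summary <- do.call(rbind, lapply(gerp_thresholds, function(t)
    cbind(threshold = t,
          element_conserved_fraction(elements, conservation, t))))
  bg_low <- site$daf <= 0.05
  enrich <- do.call(rbind, lapply(sort(unique(elements$class)), function(cl) {
    in_cl <- site$element_class == cl
    if (sum(in_cl, na.rm = TRUE) == 0) return(NULL)
    et <- enrichment_test(bg_low[which(in_cl)], bg_low)
    cbind(element_class = cl, predicate = "DAF<=0.05", et)
  }))

  utils::write.table(window_stats, file.path(out_dir, "window_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparisons, file.path(out_dir, "element_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(site, file.path(out_dir, "site_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cons_summary, file.path(out_dir, "conservation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(out_dir, "selection_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(called)) {
    bed <- data.frame(called$chrom,
                      format(called$pos, scientific = FALSE, trim = TRUE),
                      format(called$pos + 1, scientific = FALSE, trim = TRUE),
                      ifelse(called$genes == "", ".", called$genes))
    utils::write.table(bed, file.path(out_dir, "selection_calls.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(list(window_stats = window_stats, comparisons = comparisons,
                 site_stats = site, conservation_summary = cons_summary,
                 enrichment = enrich, calls = calls))
}

#' Element class at each position
#'
#' @param positions 0-based positions.
#' @param elements an `element_track`.
#' @param chrom chromosome of the positions.
#' @return character vector (NA where no element covers the position).
#' @export
element_class_of <- function(positions, elements, chrom = "chr1") {
  d <- elements[elements$chrom == chrom, , drop = FALSE]
  out <- rep(NA_character_, length(positions))
  if (nrow(d) == 0) return(out)
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(start = positions + 1, width = 1L),
    IRanges::IRanges(start = d$start + 1, end = d$end))
  out[S4Vectors::queryHits(ov)] <- d$class[S4Vectors::subjectHits(ov)]
  out
}
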