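#!/usr/bin/env Rscript

# Step 3: allele-frequency spectra, F_ST, and conservation classes.
#
# Per site: MAF, DAF (global and per population), global three-
# population Weir-Cockerham F_ST and pairwise F_ST; spectrum binning;
# GERP-style conservation classification at thresholds 2 and 3; low-DAF
# (<= 0.05) fraction per element class and conservation class, with
# chi-square / Fisher enrichment against the genome-wide background.

library(ncsel)

ind <- "results/study_inputs"
out_dir <- "results"
block <- read_vcf(file.path(ind, "study.vcf"))
elements <- read_bed(file.path(ind, "study_elements.bed"))
conservation <- read_score_track(file.path(ind, "study_conservation.bedGraph"))
panel <- read_panel(file.path(ind, "study_panel.tsv"))

freq <- maf_daf(block, panel)
fst <- global_and_pairwise_fst(block, panel)
cat(sprintf("Global F_ST: mean of per-site = %.4f, ratio-of-sums = %.4f\n",
            fst$global$mean_theta, fst$global$ratio_of_sums))
for (nm in names(fst$pairwise))
  cat(sprintf("  pairwise %s: %.4f\n", nm, fst$pairwise[[nm]]$ratio_of_sums))

site <- data.frame(chrom = block$chrom, pos = block$positions,
                   maf = freq$maf, daf = freq$daf,
                   fst_global = fst$global$per_site$theta,
                   element_class = element_class_of(block$positions, elements))
cons <- classify_conservation(block$positions, conservation)
site <- cbind(site, cons[, -1])
write.table(site, file.path(out_dir, "site_frequency_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# DAF spectrum per element class
edges <- seq(0, 1, by = 0.05)
spec <- do.call(rbind, lapply(sort(unique(site$element_class)), function(cl) {
  bs <- bin_spectrum(site$daf[site$element_class %in% cl], edges)
  data.frame(element_class = cl, bin = names(bs$counts),
             count = as.integer(bs$counts))
}))
write.table(spec, file.path(out_dir, "daf_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# conservation summary and low-DAF enrichment
cons_summary <- do.call(rbind, lapply(c(2, 3), function(t)
  cbind(threshold = t, element_conserved_fraction(elements, conservation, t))))
write.table(cons_summary, file.path(out_dir, "conservation_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

low_bg <- site$daf <= 0.05
enrich <- do.call(rbind, lapply(sort(unique(na.omit(site$element_class))),
  function(cl) {
    sel <- which(site$element_class %in% cl)
    et <- enrichment_test(low_bg[sel], low_bg)
    lf <- fraction_low_daf(site$daf[sel])
    cbind(element_class = cl, frac_low_daf = lf$fraction, et)
  }))
write.table(enrich, file.path(out_dir, "low_daf_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Low-DAF enrichment by class:\n")
print(enrich[, c("element_class", "frac_low_daf", "p", "ratio", "direction")],
      row.names = FALSE)
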