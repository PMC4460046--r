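#!/usr/bin/env Rscript

# Step 5: composite positive-selection calls.
#
# Per site: focal-population DAF, global F_ST, standardized iHS; a site
# is called when at least two of DAF > 0.5, F_ST > 0.3, |iHS| > 2 hold
# (strict inequalities). Calls are annotated with genes overlapping or
# within 5 kb, and per-element call enrichment is tested against the
# genome-wide background.

library(ncsel)

ind <- "results/study_inputs"
out_dir <- "results"
block <- read_vcf(file.path(ind, "study.vcf"))
elements <- read_bed(file.path(ind, "study_elements.bed"))
genes <- read_bed(file.path(ind, "study_genes.bed"), as = "gene")
panel <- read_panel(file.path(ind, "study_panel.tsv"))
meta <- read.delim(file.path(ind, "study_meta.tsv"), header = FALSE,
                   row.names = 1)
ihs <- read.delim(file.path(out_dir, "ihs_scan.tsv"))

freq <- maf_daf(block, panel)
fst <- global_and_pairwise_fst(block, panel)

records <- data.frame(chrom = block$chrom, pos = block$positions,
                      daf = freq$daf_pop1,
                      fst = fst$global$per_site$theta,
                      ihs = NA_real_,
                      element_class = element_class_of(block$positions,
                                                       elements))
records$ihs[ihs$core_index] <- ihs$ihs_std

calls <- call_selection(records)
calls <- annotate_genes(calls, genes)
called <- calls[calls$called, ]
cat(sprintf("%d of %d sites called (>= 2 of 3 criteria).\n",
            nrow(called), nrow(calls)))

core_pos <- as.numeric(meta["sweep_core_pos", 1])
core <- calls[calls$pos == core_pos, ]
cat(sprintf("Sweep core: called = %s, criteria met = %d, genes = %s\n",
            core$called, core$n_criteria_met, core$genes))

# per-element enrichment of calls vs genome background
enr <- do.call(rbind, lapply(sort(unique(na.omit(calls$element_class))),
  function(cl) {
    sel <- calls$element_class %in% cl
    cbind(element_class = cl,
          enrichment_test(calls$called[sel], calls$called))
  }))
write.table(calls, file.path(out_dir, "selection_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(enr, file.path(out_dir, "call_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
bed <- data.frame(called$chrom, called$pos, called$pos + 1,
                  ifelse(called$genes == "", ".", called$genes))
write.table(bed, file.path(out_dir, "selection_calls.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat("Calls and enrichment tables written under", out_dir, "\n")
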