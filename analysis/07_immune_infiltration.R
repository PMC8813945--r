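#!/usr/bin/env Rscript
# Differential immune infiltration (paired signed-rank, BH q < 0.01),
# infiltration-associated methylation regions (Spearman q < 0.01 across
# tumor samples), their DMR overlap statistics and PMD stratification.

library(dmrscape)

b <- read_cohort("results/cohort")
beta <- filter_sites(b$beta)

diff_ct <- differential_infiltration(b$infiltration, b$samples)
write.table(diff_ct, "results/differential_infiltration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cts <- diff_ct$cell_type[diff_ct$is_differential]
message(sprintf("%d of %d cell types differentially abundant: %s",
                length(cts), nrow(diff_ct), paste(cts, collapse = ", ")))

dmrs <- list(promoter = read.delim("results/dmrs_promoter.tsv"),
             enhancer = read.delim("results/dmrs_enhancer.tsv"))
imr_rows <- list(); ov_rows <- list()
for (k in c("promoter", "enhancer")) {
  rm <- aggregate_region_methylation(beta, assign_cpgs_to_regions(b$cpgs, b$regions[[k]]))
  dmr_ids <- dmrs[[k]]$region_id[dmrs[[k]]$is_dmr]
  imr <- define_imrs(rm, b$infiltration, cts, b$samples, dmr_ids = dmr_ids)
  ids <- imr_region_ids(imr)
  ov <- imr_dmr_overlap_stats(ids, rownames(rm$values), dmr_ids, k)
  split <- stratify_by_pmd(ids, b$regions[[k]], b$regions$pmd)
  imr$pmd_status <- ifelse(imr$region_id %in% split$inside, "inside", "outside")
  imr_rows[[k]] <- cbind(kind = k, imr)
  ov_rows[[k]] <- ov
  message(sprintf(
    "%s: %d IMRs; IMR share %.1f%% of DMRs vs %.1f%% of non-DMRs (OR %.1f); %d inside PMDs",
    k, length(ids), 100 * ov$prop_dmr, 100 * ov$prop_nondmr,
    ov$odds_ratio_haldane, length(split$inside)))
}
write.table(do.call(rbind, imr_rows), "results/imrs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, ov_rows), "results/imr_dmr_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
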