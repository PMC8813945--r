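#!/usr/bin/env Rscript
# Focal-tumor-type-specific genes (fold > 2 and one-sided rank test p < 0.05
# against every comparison group) and the methylation-expression Spearman
# correlation contrast between specific and non-specific DMR target genes.

library(dmrscape)

b <- read_cohort("results/cohort")
beta <- filter_sites(b$beta)
norm <- normalize_counts(b$counts)$normalized
pairs <- match_pairs(b$samples)

focal <- norm[, pairs$tumor]
comparison <- c(b$panel, list(cohort_normal = norm[, pairs$normal]))
specific <- define_specific_genes(focal, comparison)
writeLines(specific, "results/specific_genes.txt")
message(sprintf("%d focal-specific genes (planted: %d, recovered: %d)",
                length(specific), length(b$truth$true_specific_genes),
                sum(b$truth$true_specific_genes %in% specific)))

rm_p <- aggregate_region_methylation(beta, assign_cpgs_to_regions(b$cpgs, b$regions$promoter))
rm_e <- aggregate_region_methylation(beta, assign_cpgs_to_regions(b$cpgs, b$regions$enhancer))
dmrs <- list(promoter = read.delim("results/dmrs_promoter.tsv"),
             enhancer = read.delim("results/dmrs_enhancer.tsv"))
targets <- rbind(map_promoter_targets(b$genes)[, c("region_id", "gene_id")],
                 map_enhancer_targets(b$epi_map, b$genes)[, c("region_id", "gene_id")])
dmr_ids <- c(dmrs$promoter$region_id[dmrs$promoter$is_dmr],
             dmrs$enhancer$region_id[dmrs$enhancer$is_dmr])
full <- list(values = rbind(rm_p$values, rm_e$values))
class(full) <- "region_methylation"
cors <- correlate_methylation_expression(
  full, norm, targets[targets$region_id %in% dmr_ids, ])
cors$is_specific_gene <- cors$gene_id %in% specific
write.table(cors, "results/methylation_expression_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- compare_correlation_distributions(cors$rho[cors$is_specific_gene],
                                         cors$rho[!cors$is_specific_gene])
message(sprintf(
  "median rho: specific %.3f vs other %.3f (two-sided rank test p = %.3g)",
  cmp$median_specific, cmp$median_other, cmp$p_value))
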