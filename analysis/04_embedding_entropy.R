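#!/usr/bin/env Rscript
# Embed sample methylation profiles restricted to pDMRs alone, eDMRs alone
# and all DMRs (tSNE perplexity 10; UMAP on the first 10 PCs), cluster with
# k-means (k = 2) and score tumor/normal separation by weighted entropy.

library(dmrscape)

b <- read_cohort("results/cohort")
beta <- filter_sites(b$beta)
rm_p <- aggregate_region_methylation(beta, assign_cpgs_to_regions(b$cpgs, b$regions$promoter))
rm_e <- aggregate_region_methylation(beta, assign_cpgs_to_regions(b$cpgs, b$regions$enhancer))
dmrs <- list(promoter = read.delim("results/dmrs_promoter.tsv"),
             enhancer = read.delim("results/dmrs_enhancer.tsv"))
full <- list(values = rbind(rm_p$values, rm_e$values))
class(full) <- "region_methylation"

rep <- compare_profiles(full, dmrs, b$samples, methods = c("tsne", "umap"),
                        seed = 42)
write.table(rep, "results/cluster_entropy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(rep))) {
  message(sprintf("%-6s %-5s entropy = %.3f over %d DMRs",
                  rep$profile_kind[i], rep$method[i], rep$entropy[i],
                  rep$n_regions[i]))
}
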