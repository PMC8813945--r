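#!/usr/bin/env Rscript
# Gene-set enrichment (one-sided Fisher, BH) of functional-DMR target genes
# and risk-SNP proximity enrichment among DMRs (5 kb window, upper-tail
# binomial against the DMR share of tested regions).

library(dmrscape)

b <- read_cohort("results/cohort")
fun <- read.delim("results/functional_dmrs.tsv")
gene_sets <- make_synthetic_gene_sets(b)
universe <- b$genes$gene_id[b$genes$is_coding]

rows <- list()
for (k in c("promoter", "enhancer")) {
  q <- intersect(unique(fun$gene_id[fun$is_functional & fun$kind == k]), universe)
  if (!length(q)) next
  res <- fisher_enrichment(q, universe, gene_sets,
                           categories = attr(gene_sets, "categories"))
  rows[[k]] <- cbind(kind = k, res)
  message(sprintf("%s: top set '%s' (q = %.3g, odds ratio %.1f)",
                  k, res$set_name[1], res$q_value[1], res$odds_ratio_haldane[1]))
}
write.table(do.call(rbind, rows), "results/gene_set_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

dmrs <- list(promoter = read.delim("results/dmrs_promoter.tsv"),
             enhancer = read.delim("results/dmrs_enhancer.tsv"))
tested <- rbind(as.data.frame(b$regions$promoter), as.data.frame(b$regions$enhancer))
all_regions <- region_set(tested$chrom, tested$start, tested$end,
                          tested$region_id, kind = "promoter")
dmr_ids <- c(dmrs$promoter$region_id[dmrs$promoter$is_dmr],
             dmrs$enhancer$region_id[dmrs$enhancer$is_dmr])
snp <- snp_dmr_enrichment(b$snps,
                          all_regions[all_regions$region_id %in% dmr_ids, ],
                          all_regions)
write.table(snp$snp_hits, "results/snp_dmr_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "%d of %d profilable SNPs within 5 kb of a DMR (background p0 = %.3f): binomial p = %.3g",
  snp$k_hits, snp$n_snps, snp$p0, snp$p_value))
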