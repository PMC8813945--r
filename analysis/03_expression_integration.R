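#!/usr/bin/env Rscript
# Differential expression (paired test on log2 normalized counts,
# |log2FC| > 2 & q < 0.01), target mapping (downstream gene for promoters,
# PET-filtered EPI links for enhancers), functional DMRs (opposite direction
# of methylation and expression change) and super-enhancer DMRs.

library(dmrscape)

b <- read_cohort("results/cohort")
dmr <- lapply(c(promoter = "promoter", enhancer = "enhancer"), function(k)
  read.delim(sprintf("results/dmrs_%s.tsv", k)))

degs <- call_degs(b$counts, b$samples)
write.table(degs, "results/degs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d DEGs (%d up / %d down) of %d genes",
                sum(degs$is_deg), sum(degs$is_deg & degs$direction == "up"),
                sum(degs$is_deg & degs$direction == "down"), nrow(degs)))

targets <- list(promoter = map_promoter_targets(b$genes),
                enhancer = map_enhancer_targets(b$epi_map, b$genes))
fun <- lapply(c(promoter = "promoter", enhancer = "enhancer"), function(k)
  define_functional_dmrs(dmr[[k]], degs, targets[[k]]))
pairs <- rbind(fun$promoter$pairs, fun$enhancer$pairs)
write.table(pairs, "results/functional_dmrs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (k in names(fun)) {
  s <- fun[[k]]$summary
  message(sprintf("functional %s DMRs: %d hypo / %d hyper (%d + %d target genes)",
                  k, s$n_functional_dmrs[1], s$n_functional_dmrs[2],
                  s$n_target_genes[1], s$n_target_genes[2]))
}

sed <- define_sedmrs(b$regions$super_enhancer, dmr$enhancer,
                     b$regions$enhancer, targets$enhancer)
write.table(sed, "results/sedmrs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d super-enhancers overlap an eDMR (seDMRs)",
                nrow(sed), nrow(b$regions$super_enhancer)))
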