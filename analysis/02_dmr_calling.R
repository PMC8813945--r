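#!/usr/bin/env Rscript
# Call promoter and enhancer DMRs (paired M-value t-test, BH within kind,
# FDR < 0.01) on the cohort written by 01_simulate.R and score the calls
# against the planted truth.

library(dmrscape)

b <- read_cohort("results/cohort")
beta <- filter_sites(b$beta)

for (kind in c("promoter", "enhancer")) {
  rm <- aggregate_region_methylation(beta, assign_cpgs_to_regions(b$cpgs, b$regions[[kind]]))
  tab <- call_dmrs(rm, b$samples, kind)
  out <- sprintf("results/dmrs_%s.tsv", kind)
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- b$truth$true_dmrs[b$truth$true_dmrs$kind == kind, ]
  called <- tab$region_id[tab$is_dmr]
  message(sprintf(
    "%s: %d DMRs called (%d hypo / %d hyper); sensitivity %.3f, observed FDR %.3f -> %s",
    kind, length(called),
    sum(tab$is_dmr & tab$direction == "hypo"),
    sum(tab$is_dmr & tab$direction == "hyper"),
    mean(tr$region_id %in% called),
    mean(!(called %in% tr$region_id)), out))
}
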