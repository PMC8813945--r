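#!/usr/bin/env Rscript
# Generate the study-scale synthetic cohort (37 tumor/normal pairs, ~50k CpGs
# over 2000 promoters + 3000 enhancers, planted DMRs / expression coupling /
# infiltration coupling / risk SNPs) and write it under results/cohort/.

library(dmrscape)

cfg <- synthetic_config(seed = 2024)
bundle <- generate_cohort(cfg)
manifest <- write_cohort(bundle, "results/cohort")

message(sprintf("cohort: %d pairs, %d CpG sites, %d promoters, %d enhancers",
                nrow(bundle$samples) / 2, nrow(bundle$cpgs),
                nrow(bundle$regions$promoter), nrow(bundle$regions$enhancer)))
message(sprintf("planted: %d DMRs (%d hypo / %d hyper), %d coupled pairs, %d specific genes",
                nrow(bundle$truth$true_dmrs),
                sum(bundle$truth$true_dmrs$direction == "hypo"),
                sum(bundle$truth$true_dmrs$direction == "hyper"),
                nrow(bundle$truth$true_functional),
                length(bundle$truth$true_specific_genes)))
message(sprintf("wrote %d files to results/cohort", nrow(manifest)))
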