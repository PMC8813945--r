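# dmrscape

Promoter-versus-enhancer differential DNA methylation analysis for paired
tumor/adjacent-normal cohorts, built for methylation-array studies that ask
which regulatory compartment — promoters or enhancers — carries the
epigenetic signal of a tumor type.

Given CpG-level beta values, region annotations, an enhancer–promoter
interaction (EPI) map, expression counts, immune-infiltration fractions and
a risk-SNP table, the package:

- calls **DMRs** per region kind with a paired t-test on region-mean
  M-values (`M = log2(β/(1−β))`), Benjamini–Hochberg correction within
  kind, FDR < 0.01, direction from the sign of Δβ (hypo = lower in tumor);
- maps **target genes** (downstream gene for promoters; PET ≥ 5 filtered
  EPI links for enhancers; coding whitelist) and defines **functional
  DMRs** — DMRs whose target is a DEG (|log2FC| > 2, q < 0.01) changing in
  the opposite direction — plus **seDMRs** from super-enhancer overlap;
- scores tumor/normal separability of pDMR-only, eDMR-only and total-DMR
  beta profiles by tSNE (perplexity 10) / UMAP (first 10 PCs) embedding,
  k-means (k = 2), and size-weighted cluster entropy
  `H = Σ_c (n_c/N)(−Σ_t p_ct log2 p_ct)`;
- contrasts the Spearman correlation of methylation with expression between
  tumor-type-specific genes (fold > 2 and one-sided rank p < 0.05 against
  *every* comparison group) and all other target genes;
- runs **gene-set enrichment** (one-sided Fisher exact test, BH) and
  **risk-SNP proximity enrichment** (upper-tail binomial on SNPs within
  5 kb of a DMR, background = DMR share of tested regions);
- relates methylation to **immune infiltration**: differentially abundant
  cell types (paired signed-rank, q < 0.01), infiltration-associated
  methylation regions (IMRs; Spearman q < 0.01 across tumor samples), their
  DMR overlap odds ratios, and stratification by partially methylated
  domains (PMDs).

A synthetic paired-cohort generator (`generate_cohort()`) with planted
ground truth — DMRs, inverse methylation–expression coupling, specific
genes, infiltration coupling, SNP proximity — makes the whole pipeline
testable offline; every contract in the test suite is scored against the
planted truth or an exact independent oracle.

## Worked example

The `analysis/` scripts run the full study on a generated cohort, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort + planted truth
Rscript analysis/02_dmr_calling.R       # promoter/enhancer DMRs
Rscript analysis/03_expression_integration.R
Rscript analysis/04_embedding_entropy.R
Rscript analysis/05_specificity_correlation.R
Rscript analysis/06_enrichment_snp.R
Rscript analysis/07_immune_infiltration.R
```

Output of a run at the default configuration (37 pairs, 2,000 promoters,
3,000 enhancers, ~50k CpGs, 200 hypo + 100 hyper planted DMRs at Δβ = 0.25):

```
promoter: 121 DMRs called (80 hypo / 41 hyper); sensitivity 1.000, observed FDR 0.008
enhancer: 182 DMRs called (120 hypo / 62 hyper); sensitivity 1.000, observed FDR 0.011
116 DEGs (74 up / 42 down) of 4000 genes
functional promoter DMRs: 32 hypo / 21 hyper (32 + 21 target genes)
functional enhancer DMRs: 46 hypo / 21 hyper (43 + 21 target genes)
50 focal-specific genes (planted: 50, recovered: 50)
median rho: specific -0.869 vs other -0.029 (two-sided rank test p = 2.79e-20)
49 of 94 profilable SNPs within 5 kb of a DMR (background p0 = 0.061): binomial p = 2.09e-34
promoter: 24 IMRs; IMR share 12.4% of DMRs vs 0.5% of non-DMRs (OR 28.7)
enhancer: 75 IMRs; IMR share 34.1% of DMRs vs 0.5% of non-DMRs (OR 107.8)
```

Reading: every planted DMR is recovered with the observed false-discovery
rate at the nominal 1%; planted inverse coupling shows up as strongly
negative methylation–expression correlations confined to the planted
specific genes; SNPs planted near DMRs are flagged by the binomial test;
and infiltration-coupled regions concentrate on enhancer DMRs, giving a
much larger IMR–DMR odds ratio for enhancers than promoters. Cluster
entropies are 0 for all profiles at this effect size (perfect tumor/normal
separation); they order eDMR ≤ pDMR when signal is planted
enhancer-dominantly.

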