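---
title: "Promoter versus enhancer methylation in paired tumor cohorts: models and design choices"
author: "dmrscape"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Promoter versus enhancer methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bulk DNA-methylation arrays report, per CpG site and sample, a beta value:
the fraction of molecules methylated at that site, in [0, 1]. In a paired
tumor/adjacent-normal design the question is which *regulatory regions* —
annotated promoters and enhancers — change methylation in tumors
(differentially methylated regions, DMRs), which of those changes plausibly
drive expression of a target gene, and whether the promoter or the enhancer
compartment carries more of the regulatory signal. dmrscape implements that
comparison end to end: region-level DMR calling, target-gene mapping,
integration with differential expression, cluster-separation scoring of DMR
profiles, specificity-correlation contrasts, gene-set and risk-SNP
enrichment, and immune-infiltration association. A synthetic cohort
generator with planted ground truth makes every stage testable without any
external download.

# Data model and conventions

All intervals are 0-based, half-open (BED convention) internally; SNP
tables are read as 1-based and converted on ingest; chromosome names are
normalized to the `chr`-prefixed dialect. Strand is carried but ignored by
every overlap operation — nothing in the analysis is strand-sensitive. A
CpG site that falls in both a promoter and an enhancer contributes to both,
because the two annotation universes are analyzed independently.

Region-level methylation is the unweighted arithmetic mean of the
non-missing site betas in the region, per sample. Site-count weighting was
considered and rejected: it complicates the variance model and there is no
canonical weighting rule for array regions. Regions where any sample has no
informative site are dropped (and reported), so downstream matrices are
complete.

# Differential methylation

Testing happens on M-values, `M = log2(beta / (1 - beta))` with beta
clipped to `[1e-3, 1 - 1e-3]`: the logit transform approximately stabilizes
the variance of beta values near the boundaries. Each region is tested with
a paired t-test on per-patient M-value differences (tumor minus matched
normal), using pairwise-complete patients; regions with fewer than three
complete pairs are flagged untestable and excluded from multiplicity
correction. Effects are reported as `delta_beta` on the interpretable beta
scale; a region is hypomethylated when the tumor mean is lower.
Benjamini–Hochberg correction is applied separately within promoters and
within enhancers — the two compartments are reported as separate analyses —
and regions with q below 0.01 are labeled DMRs.

Array-scale pipelines typically delegate the region test to a package
internal. Here the test is a documented paired t on region means instead:
transparent, exactly reproducible against a textbook computation, and
preserving the same decision structure (region-level p, BH, FDR < 0.01).
Whether such internals combine site-level statistics or test region means
is generally opaque; the region-mean choice is documented rather than
claimed equivalent. All-zero paired differences give p = 1 by convention,
as does any zero-variance difference vector.

# Differential expression

Counts are normalized with median-of-ratios size factors (geometric-mean
reference over genes with all-nonzero counts; upper-quartile fallback when
no such gene exists, which is flagged). Differential expression is a paired
t-test on per-patient differences of `log2(normalized + 1)`; the
pseudocount of 1 keeps zeros finite. `log2fc` is the mean paired
difference. A gene is a DEG iff `|log2fc|` **strictly** exceeds 2 and the
BH q is below 0.01. A negative-binomial model with dispersion shrinkage
would be the usual choice for small cohorts; at 37 pairs the paired t on
log counts is adequate, self-contained, and exactly testable, and the
thresholds and pairing are unchanged. This substitution is deliberate and
the package documents it rather than emulating a specific NB
implementation.

# Target mapping and functional DMRs

Promoter targets are the downstream gene of each promoter — a one-to-one
map, so a promoter claimed by two genes is a data error and raises. Enhancer
targets come from an enhancer–promoter interaction (EPI) table supported by
paired-end-tag (PET) counts; links with PET < 5 are discarded at read time
(stringent filtration), duplicates keep the maximum count, and the map is
many-to-many. Both maps pass through a coding-gene whitelist.

A (DMR, target) pair is *functional* when the target is a DEG changing in
the direction opposite to the methylation change: hypomethylated with
up-regulation or hypermethylated with down-regulation. A DMR is functional
if at least one of its pairs is. Super-enhancer DMRs (seDMRs) are
super-enhancer intervals overlapping at least one enhancer DMR; their
targets are the union of the overlapping eDMRs' targets and the functional
filter is re-applied to that union.

# Cluster separation of DMR profiles

Sample profiles restricted to pDMRs alone, eDMRs alone, or all DMRs are
embedded in two dimensions with tSNE (perplexity 10) and with UMAP applied
to the first 10 principal components (the `dims = 1:10` convention of
single-cell toolkits). k-means with k = 2 and 10 restarts is run on the
2-D embedding coordinates; running k-means on raw region betas instead is
available by passing the beta matrix directly to `kmeans_cluster()`, since
it is genuinely unclear which is preferable — coordinates were chosen as
the default because the embedding is what the separation claim is about.
Separation is scored by size-weighted entropy of tissue labels within
clusters,

\[ H = \sum_c \frac{n_c}{N}\Big(-\sum_t p_{ct}\log_2 p_{ct}\Big), \]

with `0 log 0 = 0`; for two tissue labels H is in [0, 1] and 0 means
perfect tumor/normal separation. Entropy is invariant to cluster
relabeling, and refining a partition can never increase it — both properties
are tested against brute-force enumeration. Every stochastic step (tSNE,
UMAP, k-means) takes an explicit seed, defaulting to 42, and results are
reproducible at a fixed seed with single-threaded embedding.

# Specificity correlation

Focal-tumor-type-specific genes are those whose expression exceeds every
comparison group (a multi-cancer panel plus the cohort's own normals) by a
fold change of group means above 2 *and* a one-sided rank test p below
0.05, as a conjunction over all groups — a pooled comparison would let one
aberrant group hide. The comparison groups are unpaired, so the unpaired
one-sided Wilcoxon rank-sum test is used; a signed-rank test would require
a pairing that does not exist between independent cancer cohorts, and this
deviation is deliberate.

Spearman correlation between region methylation and target expression is
computed across tumor and normal cohort samples jointly — the joint range
maximizes the dynamic range of both variables; a tumor-only scope is
available via the `samples` argument. Genes whose expression stays below 1
in every sample are removed first (the filter is max-based: a gene above
the floor in even one sample is kept; an any-sample reading of the filter
would discard most of the transcriptome). Degenerate links with constant
methylation or expression have no defined rank correlation and are dropped
with a flag. The specific-versus-other contrast of correlation
distributions uses the two-sided rank-sum test with group medians reported.

# Enrichment statistics

Gene-set enrichment is the one-sided Fisher exact test on the 2×2 table of
query membership against set membership within a fixed gene universe, sets
intersected with the universe first, BH across the collection. Odds ratios
report `ad/bc` with `Inf`/0 at zero cells, plus a Haldane-corrected column
(0.5 added to each cell) for plotting and comparisons.

Risk-SNP enrichment counts, among SNPs that can be profiled at all (within
the window of at least one tested region), those within 5 kb of a DMR, and
tests the count with an upper-tail binomial. The window is measured from
region *edges*, symmetric on both flanks; measuring from midpoints would
couple the test to region length for no analytical benefit. The background
probability p0 is the DMR fraction among tested regions — the chance a
profilable SNP sits near a DMR were SNPs exchangeable across tested
regions. Genome-length-weighted backgrounds were rejected as not
identifiable from an array design; a user-supplied p0 is accepted. The test
is one-sided (enrichment); depletion is out of scope.

# Immune infiltration

Deconvolved infiltration fractions (cell type × sample, columns summing to
1) are an input — deconvolution itself is out of scope. Differentially
abundant cell types come from a paired Wilcoxon signed-rank test with BH
across cell types (q < 0.01). For those cell types, every (region, cell
type) pair is scored by Spearman correlation across the in-scope samples;
the default scope is tumor samples only, since infiltration is a property
of the tumor microenvironment, with an all-samples mode available. P-values
use the t approximation to the Spearman null (the `cor.test(exact =
FALSE)` behavior), BH is applied jointly across all pairs within a region
kind, and a region is an infiltration-associated methylation region (IMR)
if any of its pairs clears q < 0.01 — IMR status is per region, which is
what the DMR-overlap proportions need. The overlap report gives the 2×2 of
DMR status by IMR status with both proportions and odds ratio. IMRs are
stratified by any-overlap with partially methylated domains (PMDs), an
exhaustive and disjoint partition, and target-gene set enrichment is run
per stratum.

# The synthetic cohort generator

`generate_cohort()` emulates the study conditions the pipeline is designed
for, with defaults fixed at: 37 tumor/normal pairs; 2,000 promoters and
3,000 enhancers laid on chr1–chr22 with 4–16 CpGs per region (about 50,000
sites); planted DMR fractions of 4% hypo- and 2% hypermethylated per kind
(200 hypo + 100 hyper in total, the 2:1 hypomethylation dominance of tumor
methylomes) with a mean beta shift of 0.25; 40% of planted DMRs inversely
coupled to a target gene at log2 fold change 3; negative-binomial counts
with dispersion 0.3; a 5-group pan-cancer panel of 20 samples each with 50
planted focal-specific genes; 10 immune cell types, 4 differentially
abundant, 100 infiltration-coupled regions allocated 65/15/12/8% to
enhancer DMRs / promoter DMRs / non-DMR enhancers / non-DMR promoters (so
infiltration coupling is enriched on enhancer DMRs); and 94 risk SNPs
placed near a DMR with probability 0.5, or uniformly across tested regions
in the null configuration.

Methylation is logit-normal rather than Beta-distributed: the logit scale
makes patient effects, sample offsets and the region × sample interaction
additive with interpretable standard deviations (0.15, 0.10 and 0.25 by
default, with site-level dispersion 0.35). The patient effect is shared
between a patient's tumor and normal sample, so paired tests are strictly
more powerful than unpaired ones — the point of the paired design. The
per-sample global offset is deliberately *not* paired away: it makes tests
across regions positively correlated within one cohort, as real batch
structure does, which is why p-value calibration is exact only marginally
across cohorts (the FDR checks average over 20 seeds; the per-cohort
uniformity check switches this term off).

Planted DMRs shift the tumor-side region mean by ±delta on the beta scale
(the logit shift is computed from the clamped target mean). Expression
coupling ties a coupled gene's log2 mean linearly to its region's
generative methylation per sample with slope `coupling_log2fc /
delta_beta` and opposite sign, which yields both the planted tumor/normal
fold change and a negative within-cohort correlation. Infiltration
coupling works in the reverse causal direction: a latent per-sample
infiltration level for each differential cell type feeds back additively
(scale 0.5 logit units) into its coupled regions' methylation. Coupling
each cell type to the average of its many regions instead would dilute any
single region's correlation toward 1/sqrt(k) and make per-region recovery
impossible — the latent-feedback construction keeps each planted (region,
cell type) pair individually detectable, which is what the recall contract
is about. Fractions are softmax-normalized log-normal weights, so columns
sum to one by construction.

SNP placement attaches each SNP to one tested region (a DMR with the
configured probability) and draws its position uniformly in the region's
5 kb flank envelope; the region lattice keeps inter-region gaps above twice
the window so envelopes never overlap and the null hit probability equals
the DMR fraction exactly.

What the generator does *not* emulate: array chemistry (two probe designs,
detection p-values, cross-reactive probes), read-level RNA-seq,
deconvolution error structure, genomic covariates of methylation (CpG
density, replication timing) and linkage between SNPs. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under the stated generative model, not that any biological
conclusion transfers to a particular real cohort.

# Problem sizes and numerical choices

The test suite runs the study-scale configuration (37 pairs, 5,000
regions, ~50k CpGs) for the recovery and determinism checks, 20 null
cohorts of 2,000 regions at 15 pairs for FDR control, and reduced cohorts
(8–37 pairs, 150 regions) for unit tests; these sizes were chosen so the
full suite exercises every contract at the cohort scale the defaults
describe while remaining comfortable on a laptop. Exact-kernel checks
(Fisher versus hypergeometric tail, binomial versus term-wise summation,
BH versus an independent step-up, Spearman versus rank-then-Pearson) are
asserted to 1e-12. Beta values are written to disk with 6 decimals; region
coordinates and counts round-trip exactly. Ties in rank tests fall back to
the normal approximation via `wilcox.test`'s standard behavior.

# Known limitations

The region test assumes approximate normality of paired M-value
differences; heavy contamination or bimodal regions would call for a rank
test, which the region-mean design does not currently provide. BH assumes
positive dependence across regions — satisfied by the generator's
equicorrelated structure but not guaranteed for arbitrary real data. The
binomial SNP test conditions on the profilable SNP set and treats SNPs as
exchangeable; linked SNP clusters violate that and would need pruning
upstream. Entropy compares partitions only at k = 2 clusters; with more
clusters it remains valid but is no longer bounded by 1. The specificity
conjunction becomes conservative as the number of comparison groups grows.
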