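# Shared fixtures and brute-force oracles. Cohorts are cached per session so
# several test files can reuse the same generated data.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort with strong planted structure, cheap enough for unit tests
small_config <- function(seed = 101, ...) {
  args <- list(
    n_pairs = 8, n_genes = 300, n_promoters = 60, n_enhancers = 90,
    n_super_enhancers = 10, cpgs_per_region_range = c(3, 6),
    dmr_fraction_hypo = 0.2, dmr_fraction_hyper = 0.1,
    n_specific_genes = 5, infiltration_coupled_regions = 12,
    n_celltypes = 6, n_diff_celltypes = 3,
    n_other_cancer_groups = 2, samples_per_group = 8,
    n_snps = 40, seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

small_cohort <- function() cached("small_cohort", generate_cohort(small_config()))

# more pairs so correlation-based recovery (IMRs) has power at q < 0.01
imr_cohort <- function() {
  cached("imr_cohort", generate_cohort(small_config(n_pairs = 37, seed = 131)))
}

# study-scale cohort (the generator defaults); shared by acceptance checks
default_manifest <- function() {
  cached("default_manifest", {
    run_pipeline(pipeline_config(
      synthetic = synthetic_config(seed = 2024),
      outdir = file.path(tempdir(), "dmrscape_default_run")
    ))
  })
}

## ---- brute-force oracles ---------------------------------------------------

bf_assign_cpgs <- function(cpgs, regions) {
  out <- setNames(vector("list", nrow(regions)), regions$region_id)
  for (i in seq_len(nrow(regions))) {
    hit <- cpgs$chrom == regions$chrom[i] &
      cpgs$pos >= regions$start[i] & cpgs$pos < regions$end[i]
    out[[i]] <- cpgs$site_id[hit]
  }
  out
}

bf_within_window <- function(snps, regions, window_bp) {
  out <- setNames(vector("list", nrow(snps)), snps$rsid)
  for (i in seq_len(nrow(snps))) {
    hit <- regions$chrom == snps$chrom[i] &
      snps$pos[i] >= pmax(regions$start - window_bp, 0) &
      snps$pos[i] < regions$end + window_bp
    out[[i]] <- regions$region_id[hit]
  }
  out
}

# textbook step-up BH, written independently of stats::p.adjust
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

bf_hypergeom_tail <- function(a, query_size, set_size, universe_size) {
  sum(dhyper(a:min(query_size, set_size), set_size,
             universe_size - set_size, query_size))
}

bf_binom_tail <- function(k, n, p0) sum(dbinom(k:n, n, p0))

bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

bf_entropy <- function(labels, tissues) {
  n <- length(labels)
  total <- 0
  for (cl in unique(labels)) {
    sub <- tissues[labels == cl]
    h <- 0
    for (t in unique(sub)) {
      pr <- mean(sub == t)
      h <- h - pr * log2(pr)
    }
    total <- total + length(sub) / n * h
  }
  total
}

random_region_set <- function(n, kind = "enhancer", seed = 1, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(2e6, n)
  width <- sample(200:5000, n, replace = TRUE)
  region_set(chrom, start, start + width, sprintf("R%03d", seq_len(n)), kind = kind)
}
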