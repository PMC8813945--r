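test_that("configuration validation rejects infeasible settings", {
  expect_error(synthetic_config(n_pairs = 2), "n_pairs")
  expect_error(synthetic_config(dmr_fraction_hypo = 0.8, dmr_fraction_hyper = 0.3),
               "at most 1")
  expect_error(synthetic_config(delta_beta = 1.2), "delta_beta")
  expect_error(synthetic_config(n_promoters = 10, n_genes = 5), "gene per promoter")
  # more specific genes than coupled genes can support
  expect_error(generate_cohort(small_config(n_specific_genes = 200)),
               "n_specific_genes")
})

test_that("nothing is planted under the null configuration", {
  b <- generate_cohort(null_config(
    n_pairs = 4, n_genes = 100, n_promoters = 20, n_enhancers = 30,
    n_super_enhancers = 3, n_snps = 10, seed = 71
  ))
  expect_equal(nrow(b$truth$true_dmrs), 0)
  expect_equal(nrow(b$truth$true_functional), 0)
  expect_equal(length(b$truth$true_specific_genes), 0)
  expect_equal(nrow(b$truth$true_imr), 0)
})

test_that("the same seed reproduces the bundle exactly; seeds differ otherwise", {
  cfg <- small_config(seed = 72)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$beta, b2$beta)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$infiltration, b2$infiltration)
  expect_identical(b1$snps, b2$snps)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_cohort(small_config(seed = 73))
  expect_false(identical(b1$beta, b3$beta))
})

test_that("generated values satisfy their range and consistency contracts", {
  b <- small_cohort()
  expect_true(all(b$beta > 0 & b$beta < 1))
  expect_true(all(b$counts >= 0))
  expect_true(all(b$counts == round(b$counts)))
  expect_true(all(abs(colSums(b$infiltration) - 1) < 1e-9))
  expect_true(all(b$infiltration >= 0))
  # shared sample columns across modalities
  expect_identical(colnames(b$beta), b$samples$sample_id)
  expect_identical(colnames(b$counts), b$samples$sample_id)
  expect_identical(colnames(b$infiltration), b$samples$sample_id)
  # all cross-references resolve
  expect_true(all(b$cpgs$region_id %in%
                    c(b$regions$promoter$region_id, b$regions$enhancer$region_id)))
  expect_true(all(b$truth$true_dmrs$region_id %in%
                    c(b$regions$promoter$region_id, b$regions$enhancer$region_id)))
  expect_true(all(b$truth$true_functional$gene_id %in% b$genes$gene_id))
  expect_true(all(b$truth$true_imr$cell_type %in% rownames(b$infiltration)))
  # hypo dominance mirrors the planted fractions
  tr <- b$truth$true_dmrs
  expect_gte(sum(tr$direction == "hypo"), sum(tr$direction == "hyper"))
})

test_that("planted methylation shifts hit their advertised magnitude", {
  cfg <- synthetic_config(
    n_pairs = 20, n_genes = 1200, n_promoters = 1000, n_enhancers = 1000,
    n_super_enhancers = 20, cpgs_per_region_range = c(4, 10),
    dmr_fraction_hypo = c(promoter = 0, enhancer = 0.1),
    dmr_fraction_hyper = c(promoter = 0, enhancer = 0),
    delta_beta = 0.3, n_specific_genes = 0, coupling_fraction = 0,
    infiltration_coupled_regions = 0, n_snps = 20, seed = 74,
    n_other_cancer_groups = 1, samples_per_group = 5
  )
  b <- generate_cohort(cfg)
  tr <- b$truth$true_dmrs
  expect_equal(nrow(tr), 100)
  rm <- aggregate_region_methylation(b$beta, assign_cpgs_to_regions(b$cpgs, b$regions$enhancer))
  tum <- b$samples$sample_id[b$samples$tissue == "tumor"]
  nor <- b$samples$sample_id[b$samples$tissue == "normal"]
  planted <- rm$values[tr$region_id, ]
  diff <- mean(planted[, tum]) - mean(planted[, nor])
  expect_lt(abs(diff - (-0.3)), 0.02)
})

test_that("a null cohort gives exchangeable tumor/normal methylation", {
  # sample_sd = 0: the per-sample global offset is shared across regions, so
  # within one cohort realization it shifts every region's paired difference
  # together and p-values are only uniform across cohorts, not within one.
  # With it off, region noise is independent and per-cohort calibration is
  # exact.
  for (seed in 1:3) {
    b <- generate_cohort(null_config(
      n_pairs = 30, n_genes = 2000, n_promoters = 2000, n_enhancers = 50,
      n_super_enhancers = 5, cpgs_per_region_range = c(3, 6), n_snps = 10,
      n_other_cancer_groups = 1, samples_per_group = 5, sample_sd = 0,
      seed = 80 + seed
    ))
    rm <- aggregate_region_methylation(
      b$beta, assign_cpgs_to_regions(b$cpgs, b$regions$promoter))
    tab <- call_dmrs(rm, b$samples, "promoter")
    ks <- suppressWarnings(ks.test(tab$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("planted inverse coupling yields strongly negative Spearman correlations", {
  b <- imr_cohort()
  rm_all <- aggregate_region_methylation(
    b$beta, c(assign_cpgs_to_regions(b$cpgs, b$regions$promoter),
              assign_cpgs_to_regions(b$cpgs, b$regions$enhancer)))
  norm <- normalize_counts(b$counts)$normalized
  tru <- b$truth$true_functional
  out <- correlate_methylation_expression(
    rm_all, norm, data.frame(region_id = tru$region_id, gene_id = tru$gene_id),
    min_expr = 0)
  expect_lt(median(out$rho), -0.3)
})

test_that("cohort write/read round trips and checksums are reproducible", {
  b <- generate_cohort(small_config(seed = 75, n_pairs = 4))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man1 <- write_cohort(b, dir1)
  man2 <- write_cohort(generate_cohort(small_config(seed = 75, n_pairs = 4)), dir2)
  expect_equal(man1$file, man2$file)
  expect_equal(man1$md5, man2$md5)   # byte-identical regeneration
  expect_equal(sort(man1$file), sort(setdiff(list.files(dir1), "manifest.tsv")))

  back <- read_cohort(dir1)
  expect_equal(as.data.frame(back$regions$promoter),
               as.data.frame(b$regions$promoter[order(b$regions$promoter$chrom,
                                                      b$regions$promoter$start), ]),
               ignore_attr = TRUE)
  expect_equal(back$epi_map, b$epi_map)
  expect_equal(back$snps, b$snps)
  expect_equal(back$samples, b$samples)
  expect_equal(back$counts, b$counts)
  expect_equal(back$beta, round(b$beta, 6), tolerance = 1e-12)
  expect_equal(back$truth$true_dmrs, b$truth$true_dmrs)
})
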