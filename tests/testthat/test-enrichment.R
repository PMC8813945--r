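test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.5)), c(0.004, 0.02, 0.04, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("BH equals an independent step-up implementation on random vectors", {
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("Fisher enrichment matches the hypergeometric tail sum exactly", {
  # worked example: universe 100, set 10, query 10, overlap 5
  universe <- sprintf("G%03d", 1:100)
  sets <- list(S = universe[1:10])
  query <- universe[c(1:5, 51:55)]
  res <- fisher_enrichment(query, universe, sets)
  expect_equal(res$a, 5)
  expect_equal(res$odds_ratio, (5 * 85) / (5 * 5))
  expect_equal(res$p_value, bf_hypergeom_tail(5, 10, 10, 100), tolerance = 1e-12)

  set.seed(32)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    uni <- sprintf("g%04d", seq_len(N))
    set_size <- sample(1:N, 1)
    q_size <- sample(1:N, 1)
    sets <- list(S = sample(uni, set_size))
    query <- sample(uni, q_size)
    res <- fisher_enrichment(query, uni, sets)
    expect_equal(res$p_value,
                 bf_hypergeom_tail(res$a, q_size, set_size, N),
                 tolerance = 1e-12)
  }
})

test_that("degenerate Fisher tables behave as saturation predicts", {
  universe <- sprintf("G%02d", 1:30)
  sets <- list(A = universe[1:10], B = universe[11:15])
  res <- fisher_enrichment(universe, universe, sets)   # query = universe
  expect_true(all(res$p_value == 1))
  res0 <- fisher_enrichment(universe[16:20], universe, sets["B"])
  expect_equal(res0$p_value, 1)                        # zero overlap
  expect_equal(res0$odds_ratio, 0)
  # genes outside the universe never change the counts
  sets_padded <- list(A = c(sets$A, "NOT_IN_UNIVERSE"))
  expect_equal(fisher_enrichment(universe[1:5], universe, sets_padded)$a,
               fisher_enrichment(universe[1:5], universe, sets["A"])$a)
})

test_that("SNP binomial enrichment equals the exact tail summation", {
  regions <- random_region_set(60, "enhancer", seed = 33)
  dmrs <- regions[1:18, ]
  set.seed(34)
  snps <- data.frame(rsid = sprintf("rs%03d", 1:120),
                     chrom = sample(c("chr1", "chr2"), 120, replace = TRUE),
                     pos = sample.int(2.1e6, 120))
  res <- snp_dmr_enrichment(snps, dmrs, regions, window_bp = 5000)
  expect_equal(res$p0, 18 / 60)
  expect_equal(res$p_value, bf_binom_tail(res$k_hits, res$n_snps, res$p0),
               tolerance = 1e-12)
  # the exact tail at the study's scale (94 profilable, 49 hits)
  expect_equal(pbinom(48, 94, 0.3, lower.tail = FALSE),
               bf_binom_tail(49, 94, 0.3), tolerance = 1e-12)
})

test_that("SNP enrichment degenerate cases collapse to p = 1", {
  regions <- region_set("chr1", c(0, 100000), c(1000, 101000), c("A", "B"), "promoter")
  far <- data.frame(rsid = "rs1", chrom = "chr1", pos = 50000)
  expect_equal(snp_dmr_enrichment(far, regions[1, ], regions,
                                  window_bp = 60000)$p_value < 1, TRUE)
  # k = 0: SNP profilable but not near the DMR subset
  near_b <- data.frame(rsid = "rs1", chrom = "chr1", pos = 100500)
  res <- snp_dmr_enrichment(near_b, regions[1, ], regions, window_bp = 1000)
  expect_equal(res$k_hits, 0)
  expect_equal(res$p_value, 1)
  # p0 = 1 (every tested region is a DMR)
  res <- snp_dmr_enrichment(near_b, regions, regions, window_bp = 1000)
  expect_equal(res$p_value, 1)
  # no profilable SNP -> error
  outside <- data.frame(rsid = "rs9", chrom = "chr9", pos = 10)
  expect_error(snp_dmr_enrichment(outside, regions, regions, 1000), "no SNP")
})

test_that("uniformly placed SNPs give calibrated p-values, planted 3x proximity is detected", {
  b <- small_cohort()
  tested <- rbind(as.data.frame(b$regions$promoter), as.data.frame(b$regions$enhancer))
  dmr_ids <- b$truth$true_dmrs$region_id
  dmr_regions <- region_set(tested$chrom[tested$region_id %in% dmr_ids],
                            tested$start[tested$region_id %in% dmr_ids],
                            tested$end[tested$region_id %in% dmr_ids],
                            tested$region_id[tested$region_id %in% dmr_ids],
                            kind = "promoter")
  all_regions <- region_set(tested$chrom, tested$start, tested$end,
                            tested$region_id, kind = "promoter")
  p0 <- length(dmr_ids) / nrow(tested)
  set.seed(35)
  pit <- replicate(200, {
    snps <- simulate_risk_snps(tested, dmr_ids, 94, near_dmr_prob = NULL)
    res <- snp_dmr_enrichment(snps, dmr_regions, all_regions, 5000)
    # randomized PIT: uniform iff the binomial tail model is exact
    pbinom(res$k_hits, res$n_snps, res$p0, lower.tail = FALSE) +
      runif(1) * dbinom(res$k_hits, res$n_snps, res$p0)
  })
  expect_gt(suppressWarnings(ks.test(pit, "punif"))$p.value, 0.01)

  set.seed(36)
  planted <- replicate(100, {
    snps <- simulate_risk_snps(tested, dmr_ids, 94, near_dmr_prob = min(1, 3 * p0))
    snp_dmr_enrichment(snps, dmr_regions, all_regions, 5000)$p_value
  })
  expect_gte(mean(planted < 0.01), 0.95)
})

test_that("GMT round trip is lossless and agrees with an independent reader", {
  sets <- list(alpha = c("G1", "G2", "G3"), beta = c("G2", "G9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[names(sets)], sets)
  ext <- fgsea::gmtPathways(path)
  expect_equal(ext, sets, ignore_attr = TRUE)
})
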