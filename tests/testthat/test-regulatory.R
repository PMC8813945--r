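test_that("promoter target mapping is one-to-one and coding-only", {
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    promoter_region_id = c("P1", "P2", NA, "P3"),
    is_coding = c(TRUE, FALSE, TRUE, TRUE)
  )
  tm <- map_promoter_targets(genes)
  expect_equal(nrow(tm), 2)                    # G2 non-coding, G3 no promoter
  expect_setequal(tm$gene_id, c("G1", "G4"))
  expect_true(all(tm$link_type == "promoter_downstream"))
  genes$promoter_region_id[3] <- "P1"          # second gene claims P1
  expect_error(map_promoter_targets(genes), "more than one gene")
  expect_equal(nrow(map_promoter_targets(genes[0, ])), 0)
})

test_that("enhancer target mapping equals a brute-force join with the whitelist", {
  genes <- data.frame(gene_id = sprintf("G%02d", 1:30),
                      promoter_region_id = NA_character_,
                      is_coding = rep(c(TRUE, TRUE, FALSE), 10))
  set.seed(51)
  epi <- data.frame(enhancer_id = sample(sprintf("E%02d", 1:10), 40, replace = TRUE),
                    gene_id = sample(c(genes$gene_id, "UNKNOWN"), 40, replace = TRUE),
                    pet_count = 5L)
  epi <- epi[!duplicated(epi[, 1:2]), ]
  expect_warning(tm <- map_enhancer_targets(epi, genes), "unknown")
  want <- epi[epi$gene_id %in% genes$gene_id[genes$is_coding], ]
  expect_equal(nrow(tm), nrow(want))
  expect_setequal(paste(tm$region_id, tm$gene_id),
                  paste(want$enhancer_id, want$gene_id))
  # many-to-many is preserved
  epi2 <- data.frame(enhancer_id = c("E1", "E1", "E2"),
                     gene_id = c("G01", "G02", "G01"), pet_count = 9L)
  tm2 <- map_enhancer_targets(epi2, genes)
  expect_equal(nrow(tm2), 3)
  expect_equal(length(unique(tm2$gene_id)), 2)
})

test_that("functional DMRs require a DEG target with the opposite direction", {
  dmrs <- data.frame(
    region_id = c("R1", "R2", "R3", "R4"), kind = "promoter",
    direction = c("hypo", "hypo", "hyper", "hyper"),
    is_dmr = c(TRUE, TRUE, TRUE, FALSE)
  )
  degs <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    direction = c("up", "down", "down", "up"),
    is_deg = c(TRUE, TRUE, TRUE, FALSE)
  )
  targets <- data.frame(region_id = c("R1", "R2", "R3", "R4"),
                        gene_id = c("G1", "G2", "G3", "G4"))
  fd <- define_functional_dmrs(dmrs, degs, targets)
  fun <- fd$pairs[fd$pairs$is_functional, ]
  expect_setequal(fun$region_id, c("R1", "R3"))  # hypo+up, hyper+down
  expect_false("R2" %in% fun$region_id)          # hypo+down excluded
  expect_false("R4" %in% fd$pairs$region_id)     # not a DMR at all
  expect_equal(fd$summary$n_functional_dmrs, c(1L, 1L))
})

test_that("planted functional pairs are recovered on the synthetic cohort", {
  b <- imr_cohort()   # 37 pairs: full power for the q < 0.01 DEG threshold
  rm_p <- aggregate_region_methylation(b$beta, assign_cpgs_to_regions(b$cpgs, b$regions$promoter))
  rm_e <- aggregate_region_methylation(b$beta, assign_cpgs_to_regions(b$cpgs, b$regions$enhancer))
  dmr_p <- call_dmrs(rm_p, b$samples, "promoter")
  dmr_e <- call_dmrs(rm_e, b$samples, "enhancer")
  degs <- call_degs(b$counts, b$samples)
  tm_p <- map_promoter_targets(b$genes)
  tm_e <- map_enhancer_targets(b$epi_map, b$genes)
  pairs <- rbind(define_functional_dmrs(dmr_p, degs, tm_p)$pairs,
                 define_functional_dmrs(dmr_e, degs, tm_e)$pairs)
  rec <- pairs[pairs$is_functional, c("region_id", "gene_id")]
  tru <- b$truth$true_functional
  # recovered set equals planted set intersected with called DMRs x DEGs
  called_dmrs <- c(dmr_p$region_id[dmr_p$is_dmr], dmr_e$region_id[dmr_e$is_dmr])
  called_degs <- degs$gene_id[degs$is_deg]
  expected <- tru[tru$region_id %in% called_dmrs & tru$gene_id %in% called_degs, ]
  expect_true(all(paste(expected$region_id, expected$gene_id) %in%
                    paste(rec$region_id, rec$gene_id)))
  expect_gte(mean(paste(rec$region_id, rec$gene_id) %in%
                    paste(tru$region_id, tru$gene_id)), 0.8)
})

test_that("seDMR definition equals brute-force overlap plus target union", {
  set.seed(52)
  enh <- random_region_set(60, "enhancer", seed = 52)
  se <- random_region_set(15, "super_enhancer", seed = 53)
  se$region_id <- sprintf("SE%02d", 1:15)
  edmrs <- data.frame(region_id = enh$region_id,
                      direction = sample(c("hypo", "hyper"), 60, replace = TRUE),
                      is_dmr = runif(60) < 0.5)
  targets <- data.frame(region_id = sample(enh$region_id, 80, replace = TRUE),
                        gene_id = sample(sprintf("G%02d", 1:40), 80, replace = TRUE))
  targets <- targets[!duplicated(targets), ]
  got <- define_sedmrs(se, edmrs, enh, targets)
  # brute force
  dm <- edmrs[edmrs$is_dmr, ]
  for (i in seq_len(nrow(se))) {
    hit <- character(0)
    for (j in which(enh$region_id %in% dm$region_id)) {
      if (enh$chrom[j] == se$chrom[i] &&
          enh$start[j] < se$end[i] && se$start[i] < enh$end[j]) {
        hit <- c(hit, enh$region_id[j])
      }
    }
    if (!length(hit)) {
      expect_false(se$region_id[i] %in% got$se_id)
    } else {
      row <- got[got$se_id == se$region_id[i], ]
      expect_equal(row$edmr_ids, paste(sort(hit), collapse = ","))
      want_genes <- sort(unique(targets$gene_id[targets$region_id %in% hit]))
      expect_equal(row$target_genes, paste(want_genes, collapse = ","))
    }
  }
})

test_that("specific genes demand every comparison group to be cleared", {
  set.seed(54)
  genes <- sprintf("G%d", 1:3)
  focal <- matrix(rep(c(100, 100, 100), 20), 3, 20, dimnames = list(genes, NULL))
  g1 <- focal + matrix(rnorm(60, 0, 1), 3)
  # identical distributions -> nothing specific
  expect_equal(length(define_specific_genes(focal, list(a = g1))), 0)
  # G1 at 10x in focal vs every group -> specific; G2 10x vs one group only
  focal2 <- focal
  focal2["G1", ] <- 1000 + rnorm(20)
  focal2["G2", ] <- 1000 + rnorm(20)
  gA <- focal + matrix(rnorm(60, 0, 1), 3)
  gB <- focal + matrix(rnorm(60, 0, 1), 3)
  gB["G2", ] <- 1000 + rnorm(20)   # G2 not elevated relative to gB
  out <- define_specific_genes(focal2, list(a = gA, b = gB))
  expect_equal(out, "G1")
  expect_error(define_specific_genes(focal2, list(a = gA[, 1:2, drop = FALSE])),
               "fewer than 3")
})

test_that("methylation-expression correlation matches rank-then-Pearson", {
  set.seed(55)
  n <- 20
  meth <- list(values = matrix(runif(5 * n), 5, n,
                               dimnames = list(sprintf("R%d", 1:5), sprintf("S%02d", 1:n))))
  class(meth) <- "region_methylation"
  expr <- matrix(rexp(6 * n, 0.01), 6, n,
                 dimnames = list(sprintf("G%d", 1:6), sprintf("S%02d", 1:n)))
  targets <- expand.grid(region_id = sprintf("R%d", 1:5),
                         gene_id = sprintf("G%d", 1:5), stringsAsFactors = FALSE)
  out <- correlate_methylation_expression(meth, expr, targets, min_expr = 0)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$rho[i],
                 bf_spearman(meth$values[out$region_id[i], ],
                             expr[out$gene_id[i], ]),
                 tolerance = 1e-12)
  }
  # strictly decreasing expression in beta -> rho = -1
  expr["G1", ] <- 100 - 50 * meth$values["R1", ]
  out <- correlate_methylation_expression(
    meth, expr, data.frame(region_id = "R1", gene_id = "G1"), min_expr = 0)
  expect_equal(out$rho, -1)
  # constant expression -> dropped with flag
  expr["G2", ] <- 5
  out <- correlate_methylation_expression(
    meth, expr, data.frame(region_id = "R1", gene_id = "G2"), min_expr = 0)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped")$gene_id, "G2")
})

test_that("the expression floor removes genes below it in every sample", {
  meth <- list(values = matrix(runif(2 * 10), 2, 10,
                               dimnames = list(c("R1", "R2"), sprintf("S%02d", 1:10))))
  class(meth) <- "region_methylation"
  expr <- rbind(G1 = rep(0.5, 10), G2 = c(rep(0.2, 9), 3))
  colnames(expr) <- sprintf("S%02d", 1:10)
  targets <- data.frame(region_id = c("R1", "R2"), gene_id = c("G1", "G2"))
  out <- correlate_methylation_expression(meth, expr, targets, min_expr = 1)
  expect_equal(out$gene_id, "G2")   # G1 never reaches 1, G2 does once
})

test_that("correlation-distribution comparison behaves under shift and symmetry", {
  set.seed(56)
  x <- runif(200, -1, 1)
  same <- compare_correlation_distributions(x, x)
  expect_gt(same$p_value, 0.99)
  y <- pmax(x - 0.5, -1)
  shifted <- compare_correlation_distributions(y, x)
  expect_lt(shifted$p_value, 1e-6)
  expect_equal(compare_correlation_distributions(x, y)$p_value,
               shifted$p_value, tolerance = 1e-12)
  expect_error(compare_correlation_distributions(x[1:2], x), "at least 3")
})
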