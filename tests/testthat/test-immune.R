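make_samples <- function(n) {
  data.frame(
    sample_id = c(sprintf("T%02d", 1:n), sprintf("N%02d", 1:n)),
    patient_id = rep(sprintf("P%02d", 1:n), 2),
    tissue = rep(c("tumor", "normal"), each = n)
  )
}

make_fractions <- function(n, k = 5, shift_ct = NULL, shift = 0.15, seed = 61) {
  set.seed(seed)
  w <- matrix(rgamma(k * 2 * n, shape = 5), k, 2 * n)
  if (!is.null(shift_ct)) w[shift_ct, 1:n] <- w[shift_ct, 1:n] * (1 + shift * 10)
  f <- sweep(w, 2, colSums(w), "/")
  dimnames(f) <- list(sprintf("CT%02d", 1:k),
                      c(sprintf("T%02d", 1:n), sprintf("N%02d", 1:n)))
  f
}

test_that("identical tumor and normal fractions yield no differential cell types", {
  n <- 10
  f <- make_fractions(n)
  f[, sprintf("N%02d", 1:n)] <- f[, sprintf("T%02d", 1:n)]
  out <- differential_infiltration(f, make_samples(n))
  expect_true(all(out$p_value == 1))
  expect_equal(sum(out$is_differential), 0)
})

test_that("a planted abundance shift at 37 pairs is detected", {
  n <- 37
  f <- make_fractions(n, shift_ct = 2)
  out <- differential_infiltration(f, make_samples(n))
  expect_true(out$is_differential[out$cell_type == "CT02"])
})

test_that("the signed-rank statistic mirrors under tissue swap", {
  n <- 12
  f <- make_fractions(n, shift_ct = 1, seed = 62)
  samples <- make_samples(n)
  out <- differential_infiltration(f, samples)
  swapped <- samples
  swapped$tissue <- ifelse(samples$tissue == "tumor", "normal", "tumor")
  out_sw <- differential_infiltration(f, swapped)
  expect_equal(out$statistic + out_sw$statistic, rep(n * (n + 1) / 2, nrow(f)))
  expect_equal(out$p_value, out_sw$p_value, tolerance = 1e-12)
})

test_that("IMR correlation recovers a perfectly coupled region with rho = 1", {
  n <- 20
  samples <- make_samples(n)
  f <- make_fractions(n, seed = 63)
  meth <- list(values = matrix(runif(3 * 2 * n), 3, 2 * n,
                               dimnames = list(c("R1", "R2", "R3"), colnames(f))))
  class(meth) <- "region_methylation"
  tum <- sprintf("T%02d", 1:n)
  meth$values["R1", tum] <- 0.1 + 0.8 * rank(f["CT01", tum]) / n
  out <- define_imrs(meth, f, c("CT01", "CT02"), samples, sample_scope = "tumor")
  row <- out[out$region_id == "R1" & out$cell_type == "CT01", ]
  expect_equal(row$rho, 1)
  expect_true(row$is_imr_pair)
  # p-values follow the t approximation used by cor.test(exact = FALSE)
  row2 <- out[out$region_id == "R2" & out$cell_type == "CT01", ]
  ref <- cor.test(meth$values["R2", tum], f["CT01", tum],
                  method = "spearman", exact = FALSE)
  expect_equal(row2$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(row2$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("planted infiltration couplings are recovered on the synthetic cohort", {
  b <- imr_cohort()
  rm_e <- aggregate_region_methylation(b$beta, assign_cpgs_to_regions(b$cpgs, b$regions$enhancer))
  diff_ct <- differential_infiltration(b$infiltration, b$samples, q_threshold = 0.05)
  cts <- diff_ct$cell_type[diff_ct$is_differential]
  expect_gt(length(cts), 0)
  imr <- define_imrs(rm_e, b$infiltration, cts, b$samples,
                     dmr_ids = b$truth$true_dmrs$region_id)
  tru <- b$truth$true_imr
  tru <- tru[tru$region_id %in% rownames(rm_e$values) & tru$cell_type %in% cts, ]
  key <- function(d) paste(d$region_id, d$cell_type)
  rec <- imr[imr$is_imr_pair, ]
  expect_gte(mean(key(tru) %in% key(rec)), 0.7)
  # recovered signs match the planted coupling signs
  m <- merge(rec, tru, by.x = c("region_id", "cell_type"),
             by.y = c("region_id", "cell_type"))
  expect_true(all(sign(m$rho) == m$sign))
})

test_that("overlap statistics evaluate the 2x2 arithmetic", {
  uni <- sprintf("R%03d", 1:200)
  dmr <- uni[1:100]
  imr <- uni[c(1:80, 101:120)]   # a=80 b=20 c=20 d=80
  st <- imr_dmr_overlap_stats(imr, uni, dmr, "enhancer")
  expect_equal(c(st$a, st$b, st$c, st$d), c(80, 20, 20, 80))
  expect_equal(st$prop_dmr, 0.8)
  expect_equal(st$prop_nondmr, 0.2)
  expect_equal(st$odds_ratio, 16)
  # equal proportions -> OR 1
  st2 <- imr_dmr_overlap_stats(uni[c(1:50, 101:150)], uni, dmr)
  expect_equal(st2$odds_ratio, 1)
  expect_error(imr_dmr_overlap_stats(imr, character(0), dmr), "empty")
})

test_that("PMD stratification is an exhaustive disjoint partition matching brute force", {
  regions <- random_region_set(80, "enhancer", seed = 64)
  pmds <- random_region_set(10, "pmd", seed = 65)
  pmds$region_id <- sprintf("PMD%02d", 1:10)
  ids <- sample(regions$region_id, 50)
  got <- stratify_by_pmd(ids, regions, pmds)
  expect_setequal(c(got$inside, got$outside), ids)
  expect_equal(length(intersect(got$inside, got$outside)), 0)
  for (id in ids) {
    r <- regions[regions$region_id == id, ]
    hit <- any(pmds$chrom == r$chrom & pmds$start < r$end & r$start < pmds$end)
    expect_equal(id %in% got$inside, hit)
  }
})

test_that("IMR target enrichment ranks a perfectly matching set first", {
  universe <- sprintf("G%02d", 1:40)
  targets <- data.frame(region_id = rep(c("R1", "R2"), each = 3),
                        gene_id = universe[1:6])
  sets <- list(match = universe[1:6], other = universe[21:30])
  res <- imr_target_enrichment(c("R1", "R2"), targets, sets, universe)
  expect_equal(res$set_name[1], "match")
  expect_equal(res$p_value[1], bf_hypergeom_tail(6, 6, 6, 40), tolerance = 1e-12)
  expect_warning(empty <- imr_target_enrichment("nope", targets, sets, universe),
                 "no target gene")
  expect_equal(nrow(empty), 0)
})
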