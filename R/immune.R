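#' Differential immune-infiltration abundance between tumor and normal
#'
#' Per cell type, a paired Wilcoxon signed-rank test of tumor vs matched
#' normal fractions, BH-corrected across cell types; differentially
#' abundant cell types have q below the threshold. Cell types with
#' identical fractions in every pair get p = 1.
#'
#' @param fractions cell type x sample matrix; sample columns sum to 1.
#' @param samples sample sheet with sample_id, patient_id, tissue.
#' @param q_threshold FDR threshold (default 0.01).
#' @return data frame with cell_type, median_tumor, median_normal,
#'   statistic, p_value, q_value, is_differential.
#' @export
differential_infiltration <- function(fractions, samples, q_threshold = 0.01) {
  pairs <- match_pairs(samples)
  if (length(pairs$patient_id) < 3) stop("fewer than 3 complete pairs")
  ft <- fractions[, pairs$tumor, drop = FALSE]
  fn <- fractions[, pairs$normal, drop = FALSE]
  res <- lapply(seq_len(nrow(fractions)), function(i) {
    d <- ft[i, ] - fn[i, ]
    if (all(d == 0)) return(list(stat = NA_real_, p = 1))
    w <- suppressWarnings(wilcox.test(ft[i, ], fn[i, ], paired = TRUE))
    list(stat = unname(w$statistic), p = w$p.value)
  })
  p <- vapply(res, `[[`, 0, "p")
  q <- bh_adjust(p)
  out <- data.frame(
    cell_type = rownames(fractions),
    median_tumor = apply(ft, 1, median),
    median_normal = apply(fn, 1, median),
    statistic = vapply(res, `[[`, 0, "stat"),
    p_value = p,
    q_value = q,
    is_differential = q < q_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Define infiltration-associated methylation regions (IMRs)
#'
#' Spearman correlation of each region's methylation with each
#' differentially abundant cell type's fraction across the in-scope samples
#' (tumor samples by default, since infiltration is a tumor-microenvironment
#' property); p-values use the t approximation and BH correction is applied
#' jointly across all tested (region, cell type) pairs. A region is an IMR
#' iff any of its pairs has q below the threshold.
#'
#' @param region_meth a `region_methylation` of one region kind.
#' @param fractions cell type x sample matrix.
#' @param cell_types character vector of (differentially abundant) cell
#'   types to test.
#' @param samples sample sheet.
#' @param sample_scope `"tumor"` (default) or `"all"`.
#' @param q_threshold FDR threshold (default 0.01).
#' @param dmr_ids optional character vector used to annotate DMR status.
#' @return data frame with region_id, cell_type, rho, p_value, q_value,
#'   is_imr_pair, is_dmr; degenerate (constant) pairs are skipped and listed
#'   in the `"skipped"` attribute.
#' @export
define_imrs <- function(region_meth, fractions, cell_types, samples,
                        sample_scope = c("tumor", "all"), q_threshold = 0.01,
                        dmr_ids = character()) {
  sample_scope <- match.arg(sample_scope)
  if (!length(cell_types)) stop("cell_types must be non-empty")
  scope <- if (sample_scope == "tumor") {
    samples$sample_id[samples$tissue == "tumor"]
  } else {
    samples$sample_id
  }
  scope <- Reduce(intersect, list(scope, colnames(region_meth$values), colnames(fractions)))
  if (length(scope) < 5) stop("fewer than 5 samples in scope")
  m <- region_meth$values[, scope, drop = FALSE]
  f <- fractions[cell_types, scope, drop = FALSE]
  const_region <- apply(m, 1, sd) == 0
  const_ct <- apply(f, 1, sd) == 0
  rho <- cor(t(m[!const_region, , drop = FALSE]),
             t(f[!const_ct, , drop = FALSE]), method = "spearman")
  n <- length(scope)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  out <- data.frame(
    region_id = rep(rownames(rho), times = ncol(rho)),
    cell_type = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho),
    p_value = as.vector(p),
    stringsAsFactors = FALSE
  )
  out$q_value <- bh_adjust(out$p_value)
  out$is_imr_pair <- out$q_value < q_threshold
  out$is_dmr <- out$region_id %in% dmr_ids
  skipped <- expand.grid(
    region_id = rownames(m)[const_region], cell_type = rownames(f),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

#' Region ids labeled IMR (any significant cell-type pair)
#'
#' @param imrs a [define_imrs()] table.
#' @return character vector of IMR region ids.
#' @export
imr_region_ids <- function(imrs) {
  unique(imrs$region_id[imrs$is_imr_pair])
}

#' Overlap statistics between IMRs and DMRs
#'
#' 2x2 contingency of DMR status against IMR status over the testable
#' region universe of one kind: `prop_dmr` is the proportion of DMRs that
#' are IMRs, `prop_nondmr` the proportion of non-DMRs that are, and the
#' odds ratio is `ad/bc` (with a Haldane-corrected companion for zero
#' cells).
#'
#' @param imr_ids character vector of IMR region ids.
#' @param universe_ids character vector of all testable region ids of the
#'   kind.
#' @param dmr_ids character vector of DMR region ids.
#' @param kind annotation carried to output.
#' @return one-row data frame with kind, a (IMR∩DMR), b (DMR non-IMR),
#'   c (IMR non-DMR), d (neither), prop_dmr, prop_nondmr, odds_ratio,
#'   odds_ratio_haldane.
#' @export
imr_dmr_overlap_stats <- function(imr_ids, universe_ids, dmr_ids, kind = NA_character_) {
  if (!length(universe_ids)) stop("empty region universe")
  imr <- universe_ids %in% imr_ids
  dmr <- universe_ids %in% dmr_ids
  a <- sum(imr & dmr)
  b <- sum(!imr & dmr)
  c_ <- sum(imr & !dmr)
  d <- sum(!imr & !dmr)
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else 0
  } else (a * d) / (b * c_)
  data.frame(
    kind = kind, a = a, b = b, c = c_, d = d,
    prop_dmr = a / (a + b),
    prop_nondmr = c_ / (c_ + d),
    odds_ratio = or,
    odds_ratio_haldane = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
    stringsAsFactors = FALSE
  )
}

#' Stratify regions by partially methylated domain (PMD) overlap
#'
#' A region is inside iff it overlaps at least one PMD interval (any
#' overlap); the partition is exhaustive and disjoint.
#'
#' @param region_ids character vector of region ids to partition.
#' @param regions [region_set()] holding the coordinates of `region_ids`.
#' @param pmd_regions [region_set()] of PMD intervals.
#' @return list with `inside` and `outside` character vectors.
#' @export
stratify_by_pmd <- function(region_ids, regions, pmd_regions) {
  sub <- regions[regions$region_id %in% region_ids, , drop = FALSE]
  if (!all(region_ids %in% sub$region_id)) {
    stop("some region_ids are missing from the coordinate table")
  }
  ov <- overlap_regions(sub, pmd_regions)
  inside <- intersect(region_ids, unique(ov$query_id))
  list(inside = inside, outside = setdiff(region_ids, inside))
}

#' Gene-set enrichment for genes regulated by an IMR subset
#'
#' Resolves the target genes of the given IMR regions through a target map
#' and tests them with [fisher_enrichment()] against a gene universe.
#'
#' @param imr_region_ids character vector of IMR region ids.
#' @param targets target map with region_id, gene_id.
#' @param gene_sets named list of gene sets.
#' @param universe background gene universe.
#' @param categories optional set categories.
#' @return a [fisher_enrichment()] table; empty (with a warning) when no
#'   target gene resolves.
#' @export
imr_target_enrichment <- function(imr_region_ids, targets, gene_sets, universe,
                                  categories = NULL) {
  genes <- unique(targets$gene_id[targets$region_id %in% imr_region_ids])
  genes <- intersect(genes, universe)
  if (!length(genes)) {
    warning("no target gene resolves for the given IMR regions")
    return(data.frame())
  }
  fisher_enrichment(genes, universe, gene_sets, categories = categories)
}
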