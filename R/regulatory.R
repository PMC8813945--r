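#' Map promoters to their downstream target genes
#'
#' One-to-one promoter-to-gene links from a gene annotation table; genes
#' failing the coding whitelist are dropped, and a promoter claimed by two
#' genes violates the one-to-one contract and raises an error.
#'
#' @param genes data frame with gene_id, promoter_region_id (NA allowed),
#'   is_coding.
#' @return data frame with region_id, gene_id, link_type =
#'   `"promoter_downstream"`.
#' @export
map_promoter_targets <- function(genes) {
  g <- genes[!is.na(genes$promoter_region_id) & genes$is_coding, , drop = FALSE]
  dup <- g$promoter_region_id[duplicated(g$promoter_region_id)]
  if (length(dup)) {
    stop(sprintf("promoter %s is referenced by more than one gene", dup[1]))
  }
  out <- data.frame(
    region_id = g$promoter_region_id,
    gene_id = g$gene_id,
    link_type = if (nrow(g)) "promoter_downstream" else character(0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Map enhancers to target genes via an EPI map
#'
#' Many-to-many enhancer-gene links from a PET-filtered interaction map;
#' links to genes missing from the annotation are dropped with a warning,
#' non-coding targets are dropped silently (whitelist rule).
#'
#' @param epi data frame with enhancer_id, gene_id, pet_count (already
#'   PET-filtered, see [read_epi_map()]).
#' @param genes gene annotation with gene_id, is_coding.
#' @return data frame with region_id, gene_id, link_type = `"epi"`.
#' @export
map_enhancer_targets <- function(epi, genes) {
  unknown <- setdiff(epi$gene_id, genes$gene_id)
  if (length(unknown)) {
    warning(sprintf("%d EPI link(s) to unknown gene(s) dropped", length(unknown)))
    epi <- epi[!epi$gene_id %in% unknown, , drop = FALSE]
  }
  coding <- genes$gene_id[genes$is_coding]
  epi <- epi[epi$gene_id %in% coding, , drop = FALSE]
  out <- data.frame(
    region_id = epi$enhancer_id,
    gene_id = epi$gene_id,
    link_type = if (nrow(epi)) "epi" else character(0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Define functional DMRs from opposite methylation/expression changes
#'
#' A (DMR, target gene) pair is functional iff the target is a DEG and the
#' direction of expression change opposes the methylation change
#' (hypomethylated with up-regulation, or hypermethylated with
#' down-regulation). A DMR is functional iff at least one of its pairs is.
#'
#' @param dmrs a [call_dmrs()] table (only rows with `is_dmr` are used).
#' @param degs a [call_degs()] table.
#' @param targets a target map (see [map_promoter_targets()] /
#'   [map_enhancer_targets()]).
#' @return list with `pairs` (region_id, kind, direction, gene_id,
#'   deg_direction, is_functional) and `summary` (counts of functional DMRs
#'   by direction plus distinct target genes).
#' @export
define_functional_dmrs <- function(dmrs, degs, targets) {
  dm <- dmrs[dmrs$is_dmr, , drop = FALSE]
  pairs <- merge(
    dm[, c("region_id", "kind", "direction")],
    targets[, c("region_id", "gene_id")],
    by = "region_id"
  )
  deg_dir <- setNames(ifelse(degs$is_deg, degs$direction, NA_character_),
                      degs$gene_id)
  pairs$deg_direction <- unname(deg_dir[pairs$gene_id])
  pairs$is_functional <- !is.na(pairs$deg_direction) &
    ((pairs$direction == "hypo" & pairs$deg_direction == "up") |
       (pairs$direction == "hyper" & pairs$deg_direction == "down"))
  pairs <- pairs[order(pairs$region_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  fun <- pairs[pairs$is_functional, , drop = FALSE]
  summary <- data.frame(
    direction = c("hypo", "hyper"),
    n_functional_dmrs = c(length(unique(fun$region_id[fun$direction == "hypo"])),
                          length(unique(fun$region_id[fun$direction == "hyper"]))),
    n_target_genes = c(length(unique(fun$gene_id[fun$direction == "hypo"])),
                       length(unique(fun$gene_id[fun$direction == "hyper"]))),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, summary = summary)
}

#' Define super-enhancer DMRs (seDMRs)
#'
#' A super-enhancer is a seDMR iff it overlaps at least one enhancer DMR;
#' its targets are the union of the overlapping eDMRs' targets and its
#' direction set collects their directions.
#'
#' @param super_enhancers [region_set()] of super-enhancer intervals.
#' @param edmrs an enhancer [call_dmrs()] table (rows with `is_dmr` used).
#' @param enhancer_regions [region_set()] giving eDMR coordinates.
#' @param targets enhancer target map.
#' @return data frame with se_id, edmr_ids (comma-joined), directions
#'   (comma-joined set), target_genes (comma-joined union), n_edmrs.
#' @export
define_sedmrs <- function(super_enhancers, edmrs, enhancer_regions, targets) {
  dm <- edmrs[edmrs$is_dmr, , drop = FALSE]
  dm_regions <- enhancer_regions[enhancer_regions$region_id %in% dm$region_id, , drop = FALSE]
  ov <- overlap_regions(super_enhancers, dm_regions)
  if (!nrow(ov)) {
    return(data.frame(se_id = character(), edmr_ids = character(),
                      directions = character(), target_genes = character(),
                      n_edmrs = integer(), stringsAsFactors = FALSE))
  }
  dir_of <- setNames(dm$direction, dm$region_id)
  tg <- split(targets$gene_id, targets$region_id)
  rows <- lapply(split(ov$subject_id, ov$query_id), function(eids) {
    eids <- sort(unique(eids))
    genes <- sort(unique(unlist(tg[eids], use.names = FALSE)))
    data.frame(
      edmr_ids = paste(eids, collapse = ","),
      directions = paste(sort(unique(dir_of[eids])), collapse = ","),
      target_genes = paste(genes, collapse = ","),
      n_edmrs = length(eids),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(se_id = names(rows), stringsAsFactors = FALSE), out)
  out <- out[order(out$se_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define focal-tumor-type-specific genes
#'
#' A gene is specific to the focal group iff, against every comparison
#' group, the fold change of group means exceeds `fc_threshold` and a
#' one-sided rank-sum test (focal greater) gives p below `p_threshold`.
#' Groups are unpaired, so the one-sided Wilcoxon rank-sum test is used.
#'
#' @param focal gene x sample expression matrix of the focal group.
#' @param comparison_groups list of gene x sample matrices sharing the gene
#'   universe of `focal`.
#' @param fc_threshold fold-change threshold on group means (default 2,
#'   strict).
#' @param p_threshold per-group p threshold (default 0.05).
#' @return character vector of specific gene ids.
#' @export
define_specific_genes <- function(focal, comparison_groups, fc_threshold = 2,
                                  p_threshold = 0.05) {
  for (g in comparison_groups) {
    if (ncol(g) < 3) stop("comparison group with fewer than 3 samples")
    if (!identical(rownames(g), rownames(focal))) {
      stop("comparison groups must share the focal gene universe (same order)")
    }
  }
  if (ncol(focal) < 3) stop("focal group with fewer than 3 samples")
  specific <- rep(TRUE, nrow(focal))
  fm <- rowMeans(focal)
  for (g in comparison_groups) {
    gm <- rowMeans(g)
    fc_ok <- fm > fc_threshold * gm
    test_idx <- which(specific & fc_ok)
    p_ok <- rep(FALSE, nrow(focal))
    for (i in test_idx) {
      p <- suppressWarnings(
        wilcox.test(focal[i, ], g[i, ], alternative = "greater")$p.value
      )
      p_ok[i] <- is.finite(p) && p < p_threshold
    }
    specific <- specific & fc_ok & p_ok
  }
  rownames(focal)[specific]
}

#' Correlate region methylation with target-gene expression
#'
#' Spearman correlation across shared samples for every (region, target)
#' link; genes whose maximum expression across samples is below `min_expr`
#' are excluded, and degenerate links (constant methylation or expression)
#' are dropped with a flag.
#'
#' @param region_meth a `region_methylation`.
#' @param expr gene x sample expression matrix (normalized scale).
#' @param targets target map with region_id, gene_id.
#' @param min_expr expression floor (default 1): genes below it in all
#'   samples are removed.
#' @param samples optional character vector restricting the sample columns
#'   used (default: all shared samples).
#' @return data frame with region_id, gene_id, rho, n; dropped degenerate
#'   links are listed in the `"dropped"` attribute.
#' @export
correlate_methylation_expression <- function(region_meth, expr, targets,
                                             min_expr = 1, samples = NULL) {
  shared <- intersect(colnames(region_meth$values), colnames(expr))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 5) stop("fewer than 5 shared samples")
  keep_genes <- rownames(expr)[apply(expr[, shared, drop = FALSE], 1, max) >= min_expr]
  links <- targets[targets$gene_id %in% keep_genes &
                     targets$region_id %in% rownames(region_meth$values), , drop = FALSE]
  m <- region_meth$values[, shared, drop = FALSE]
  e <- expr[, shared, drop = FALSE]
  rho <- numeric(nrow(links))
  degenerate <- logical(nrow(links))
  for (i in seq_len(nrow(links))) {
    x <- m[links$region_id[i], ]
    y <- e[links$gene_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) {
      degenerate[i] <- TRUE
      next
    }
    rho[i] <- cor(x, y, method = "spearman")
  }
  out <- data.frame(
    region_id = links$region_id, gene_id = links$gene_id,
    rho = rho, n = length(shared), stringsAsFactors = FALSE
  )[!degenerate, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- links[degenerate, c("region_id", "gene_id")]
  out
}

#' Compare two correlation-coefficient distributions
#'
#' Two-sided rank-sum comparison of two samples of Spearman coefficients
#' (e.g. specific-gene links vs all other links), with group medians.
#'
#' @param specific_rhos,other_rhos numeric vectors.
#' @return list with p_value, median_specific, median_other.
#' @export
compare_correlation_distributions <- function(specific_rhos, other_rhos) {
  if (length(specific_rhos) < 3 || length(other_rhos) < 3) {
    stop("each group needs at least 3 values")
  }
  p <- suppressWarnings(
    wilcox.test(specific_rhos, other_rhos, alternative = "two.sided")$p.value
  )
  list(p_value = p,
       median_specific = median(specific_rhos),
       median_other = median(other_rhos))
}
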