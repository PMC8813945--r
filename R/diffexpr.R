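#' Median-of-ratios normalization of a count matrix
#'
#' Size factor of a sample = median over reference genes of the ratio of its
#' count to the gene's geometric mean across samples; reference genes are
#' those with all-nonzero counts. When no such gene exists, upper-quartile
#' factors are used instead (flagged in the `"method"` attribute).
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return list with `normalized` (counts / size factor, column-wise) and
#'   `size_factors` (named, geometric mean 1 for median-of-ratios).
#' @export
normalize_counts <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (!all(colSums(counts) > 0)) stop("a sample has all-zero counts")
  ref <- rowSums(counts == 0) == 0
  if (any(ref)) {
    geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
    sf <- apply(counts[ref, , drop = FALSE], 2, function(col) median(col / geo))
    method <- "median_of_ratios"
  } else {
    uq <- apply(counts, 2, function(col) quantile(col[col > 0], 0.75))
    sf <- uq / exp(mean(log(uq)))
    method <- "upper_quartile"
    message("no all-nonzero gene; falling back to upper-quartile size factors")
  }
  sf <- setNames(as.numeric(sf), colnames(counts))
  out <- list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
  attr(out, "method") <- method
  out
}

#' Call differentially expressed genes (DEGs)
#'
#' Paired t-test on per-patient differences of `log2(normalized + 1)`
#' between tumor and matched normal; `log2fc` is the mean difference. BH
#' correction is applied over all tested genes, and a gene is a DEG iff
#' `|log2fc| > lfc_threshold` (strict) and `q < q_threshold`.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample sheet with sample_id, patient_id, tissue.
#' @param lfc_threshold log2 fold-change threshold (default 2, strict
#'   inequality).
#' @param q_threshold FDR threshold (default 0.01).
#' @return data frame with gene_id, log2fc, p_value, q_value, direction,
#'   is_deg.
#' @export
call_degs <- function(counts, samples, lfc_threshold = 2, q_threshold = 0.01) {
  pairs <- match_pairs(samples)
  if (length(pairs$patient_id) < 3) stop("fewer than 3 complete pairs")
  norm <- normalize_counts(counts)$normalized
  lt <- log2(norm[, pairs$tumor, drop = FALSE] + 1)
  ln <- log2(norm[, pairs$normal, drop = FALSE] + 1)
  res <- paired_t_rows(lt, ln)
  q <- bh_adjust(res$p_value)
  out <- data.frame(
    gene_id = rownames(counts),
    log2fc = res$mean_diff,
    p_value = res$p_value,
    q_value = q,
    direction = ifelse(res$mean_diff > 0, "up", "down"),
    is_deg = abs(res$mean_diff) > lfc_threshold & q < q_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
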