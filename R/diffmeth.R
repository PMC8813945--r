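#' Filter CpG sites from a beta matrix
#'
#' Stand-in for array-level preprocessing: removes blocklisted probes and
#' sites whose missing fraction exceeds `max_missing_frac`. Site order is
#' preserved.
#'
#' @param beta numeric site x sample matrix of beta values in \[0,1\]
#'   (rownames = site ids), `NA` allowed.
#' @param blocklist character vector of site ids to drop.
#' @param max_missing_frac maximum tolerated fraction of missing samples per
#'   site (default 0.2).
#' @return filtered beta matrix.
#' @export
filter_sites <- function(beta, blocklist = character(), max_missing_frac = 0.2) {
  keep <- !(rownames(beta) %in% blocklist)
  miss <- rowMeans(is.na(beta))
  keep <- keep & miss <= max_missing_frac
  if (!any(keep)) stop("no CpG sites left after filtering")
  beta[keep, , drop = FALSE]
}

#' Average site-level betas into region-level methylation
#'
#' The methylation level of a region in a sample is the arithmetic mean of
#' its non-missing CpG site betas. Regions where any sample has zero
#' non-missing sites are dropped (their ids are returned in the
#' `"dropped"` attribute).
#'
#' @param beta site x sample beta matrix with rownames = site ids.
#' @param region_map named list region_id -> site ids, from
#'   [assign_cpgs_to_regions()].
#' @return list with `values` (region x sample matrix), `n_sites`
#'   (named integer), and attribute-carried `dropped` ids; class
#'   `region_methylation`.
#' @export
aggregate_region_methylation <- function(beta, region_map) {
  region_map <- region_map[lengths(region_map) > 0]
  region_map <- lapply(region_map, intersect, x = rownames(beta))
  region_map <- Filter(length, region_map)
  if (!length(region_map)) stop("no region has any profiled CpG site")
  sites <- unlist(region_map, use.names = FALSE)
  grp <- rep(names(region_map), lengths(region_map))
  sub <- beta[sites, , drop = FALSE]
  ok <- !is.na(sub)
  sub[!ok] <- 0
  sums <- rowsum(sub, grp, reorder = FALSE)
  ns <- rowsum(ok + 0, grp, reorder = FALSE)
  values <- sums / ns
  dropped <- rownames(values)[apply(ns == 0, 1, any)]
  keep <- setdiff(rownames(values), dropped)
  values <- values[keep, , drop = FALSE]
  out <- list(
    values = values,
    n_sites = setNames(lengths(region_map)[keep], keep),
    dropped = dropped
  )
  class(out) <- "region_methylation"
  out
}

#' @export
print.region_methylation <- function(x, ...) {
  cat(sprintf("region_methylation: %d regions x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` with beta clipped to `[eps, 1 - eps]`; the
#' logit scale stabilizes variance near the 0/1 boundaries for testing.
#'
#' @param beta numeric vector/matrix in \[0,1\].
#' @param eps clipping bound (default 1e-3).
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Split sample columns into matched tumor/normal pairs
#'
#' @param samples data frame with sample_id, patient_id, tissue
#'   (`"tumor"`/`"normal"`).
#' @return list with `tumor` and `normal` sample-id vectors aligned by
#'   patient, and `patient_id`.
#' @export
match_pairs <- function(samples) {
  stopifnot(all(c("sample_id", "patient_id", "tissue") %in% names(samples)))
  tum <- samples[samples$tissue == "tumor", ]
  nor <- samples[samples$tissue == "normal", ]
  if (anyDuplicated(tum$patient_id) || anyDuplicated(nor$patient_id)) {
    stop("a patient may have at most one tumor and one normal sample")
  }
  patients <- intersect(tum$patient_id, nor$patient_id)
  list(
    tumor = tum$sample_id[match(patients, tum$patient_id)],
    normal = nor$sample_id[match(patients, nor$patient_id)],
    patient_id = patients
  )
}

# Row-wise paired t-test on per-patient differences (x_tumor - x_normal).
# Pairwise-complete patients per row; rows with < 3 complete pairs are
# untestable (NA p). All-equal differences give p = 1 by convention.
paired_t_rows <- function(x_tumor, x_normal) {
  d <- x_tumor - x_normal
  ok <- !is.na(d)
  n <- rowSums(ok)
  d0 <- d
  d0[!ok] <- 0
  mean_d <- rowSums(d0) / n
  var_d <- rowSums((d0 - ifelse(ok, mean_d, 0))^2 * ok) / pmax(n - 1, 1)
  se <- sqrt(var_d / n)
  tstat <- mean_d / se
  p <- 2 * pt(-abs(tstat), df = n - 1)
  zero_var <- var_d == 0 | !is.finite(tstat)
  p[zero_var] <- 1
  tstat[zero_var & var_d == 0] <- 0
  p[n < 3] <- NA_real_
  data.frame(mean_diff = mean_d, t = tstat, p_value = p, n_pairs = n)
}

#' Paired test of one region's methylation
#'
#' Paired t-test on per-patient M-value differences (tumor - normal); the
#' effect size `delta_beta` is reported on the beta scale.
#'
#' @param region_values named numeric vector of per-sample mean beta.
#' @param samples sample sheet (see [match_pairs()]).
#' @return list with delta_beta, p_value, n_pairs.
#' @export
test_region <- function(region_values, samples) {
  pairs <- match_pairs(samples)
  bt <- region_values[pairs$tumor]
  bn <- region_values[pairs$normal]
  res <- paired_t_rows(matrix(beta_to_m(bt), 1), matrix(beta_to_m(bn), 1))
  if (res$n_pairs < 3) stop("fewer than 3 complete tumor/normal pairs")
  list(delta_beta = mean(bt - bn, na.rm = TRUE),
       p_value = res$p_value, n_pairs = res$n_pairs)
}

#' Call differentially methylated regions (DMRs)
#'
#' Paired t-tests on region-mean M-values with Benjamini-Hochberg correction
#' applied within the given region kind; regions with q below `q_threshold`
#' are labeled DMRs, hypomethylated when the tumor mean beta is lower.
#'
#' @param region_meth a `region_methylation` (see
#'   [aggregate_region_methylation()]).
#' @param samples sample sheet with sample_id, patient_id, tissue.
#' @param kind `"promoter"` or `"enhancer"` (annotation carried to output).
#' @param q_threshold FDR threshold for the DMR label (default 0.01).
#' @return data frame with region_id, kind, mean_beta_tumor,
#'   mean_beta_normal, delta_beta, p_value, q_value, direction, is_dmr,
#'   n_sites. Untestable regions (< 3 complete pairs) carry NA p/q and are
#'   excluded from the correction.
#' @export
call_dmrs <- function(region_meth, samples, kind = c("promoter", "enhancer"),
                      q_threshold = 0.01) {
  kind <- match.arg(kind)
  pairs <- match_pairs(samples)
  vals <- region_meth$values
  bt <- vals[, pairs$tumor, drop = FALSE]
  bn <- vals[, pairs$normal, drop = FALSE]
  res <- paired_t_rows(beta_to_m(bt), beta_to_m(bn))
  d <- bt - bn
  okd <- !is.na(d)
  d[!okd] <- 0
  delta_beta <- rowSums(d) / rowSums(okd)
  q <- rep(NA_real_, nrow(vals))
  testable <- !is.na(res$p_value)
  q[testable] <- bh_adjust(res$p_value[testable])
  out <- data.frame(
    region_id = rownames(vals),
    kind = kind,
    mean_beta_tumor = rowMeans(bt, na.rm = TRUE),
    mean_beta_normal = rowMeans(bn, na.rm = TRUE),
    delta_beta = delta_beta,
    p_value = res$p_value,
    q_value = q,
    direction = ifelse(delta_beta < 0, "hypo", "hyper"),
    is_dmr = !is.na(q) & q < q_threshold,
    n_sites = as.integer(region_meth$n_sites[rownames(vals)]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
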