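#' Embed sample methylation profiles in two dimensions
#'
#' Samples are embedded from their region-level beta profiles restricted to
#' a DMR subset. `"tsne"` runs t-SNE with the given perplexity (default 10);
#' `"umap"` first projects onto the leading principal components (default
#' dims 1:10) and then embeds them with UMAP. Both are seeded and
#' reproducible at a fixed seed.
#'
#' @param region_meth a `region_methylation` restricted to the regions of
#'   interest (or any region x sample beta matrix).
#' @param method `"tsne"` or `"umap"`.
#' @param seed RNG seed (default 42).
#' @param perplexity t-SNE perplexity (default 10); must be below
#'   `(n_samples - 1) / 3`.
#' @param n_pcs number of principal components fed to UMAP (default 10,
#'   capped at the data rank).
#' @return list of class `embedding_result` with `coords` (sample x 2,
#'   rownames = sample ids), `method`, and a `params` echo.
#' @export
embed_profile <- function(region_meth, method = c("tsne", "umap"), seed = 42,
                          perplexity = 10, n_pcs = 10) {
  method <- match.arg(method)
  vals <- if (inherits(region_meth, "region_methylation")) region_meth$values else region_meth
  if (ncol(vals) < 5) stop("need at least 5 samples to embed")
  if (nrow(vals) < 2) stop("need at least 2 regions to embed")
  x <- t(vals)
  n <- nrow(x)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (method == "tsne") {
    if (perplexity >= (n - 1) / 3) {
      stop(sprintf(
        "perplexity %g too large for %d samples; choose perplexity < %g",
        perplexity, n, (n - 1) / 3))
    }
    fit <- Rtsne::Rtsne(x, perplexity = perplexity, check_duplicates = FALSE,
                        pca = TRUE, verbose = FALSE)
    coords <- fit$Y
  } else {
    k <- min(n_pcs, n - 1, ncol(x))
    pcs <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)$x
    coords <- uwot::umap(pcs, n_neighbors = min(15, n - 1), n_threads = 1,
                         n_sgd_threads = 0)
  }
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("dim1", "dim2")
  out <- list(coords = coords, method = method,
              params = list(seed = seed, perplexity = perplexity, n_pcs = n_pcs))
  class(out) <- "embedding_result"
  out
}

#' Two-group k-means clustering of embedding coordinates
#'
#' k-means with `nstart` restarts keeping the best inertia; the label
#' permutation is arbitrary and irrelevant downstream. Degenerate inputs
#' with fewer distinct points than clusters collapse to a single cluster
#' (flagged in the `"degenerate"` attribute).
#'
#' @param coords numeric matrix (samples x d) or an `embedding_result`.
#' @param k number of clusters (default 2).
#' @param seed RNG seed (default 42).
#' @param nstart random restarts (default 10).
#' @return integer cluster labels named by sample.
#' @export
kmeans_cluster <- function(coords, k = 2, seed = 42, nstart = 10) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  if (k > nrow(coords)) stop("k cannot exceed the number of samples")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n_distinct <- nrow(unique(round(coords, 12)))
  if (n_distinct < k) {
    labels <- setNames(rep(1L, nrow(coords)), rownames(coords))
    attr(labels, "degenerate") <- TRUE
    return(labels)
  }
  fit <- kmeans(coords, centers = k, nstart = nstart)
  setNames(as.integer(fit$cluster), rownames(coords))
}

#' Size-weighted entropy of tissue labels within clusters
#'
#' `H = sum_c (n_c / N) * (-sum_t p_ct log2 p_ct)` with `0 log 0 = 0`; for
#' two tissue labels H lies in \[0, 1\], 0 meaning perfect tumor/normal
#' separation.
#'
#' @param labels cluster assignments.
#' @param tissues tissue label per sample (same length).
#' @return entropy in bits.
#' @export
cluster_entropy <- function(labels, tissues) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(tissues)) stop("labels and tissues differ in length")
  n <- length(labels)
  h <- 0
  for (cl in unique(labels)) {
    idx <- labels == cl
    p <- table(tissues[idx]) / sum(idx)
    p <- p[p > 0]
    h <- h + (sum(idx) / n) * (-sum(p * log2(p)))
  }
  as.numeric(h)
}

#' Compare tumor/normal separability of DMR profile subsets
#'
#' Runs embed -> k-means(2) -> entropy for the promoter-DMR-only,
#' enhancer-DMR-only and combined profiles under each requested embedding
#' method, reporting the entropies side by side. Profiles with no DMRs are
#' skipped with a warning.
#'
#' @param region_meth a `region_methylation` covering all regions (both
#'   kinds).
#' @param dmr_tables named list with elements `promoter` and `enhancer`,
#'   each a [call_dmrs()] table.
#' @param samples sample sheet with sample_id, patient_id, tissue.
#' @param methods embedding methods to run (default both).
#' @param seed RNG seed.
#' @param perplexity,n_pcs forwarded to [embed_profile()].
#' @return data frame with profile_kind, method, n_regions, entropy, and
#'   contingency cell counts (cluster x tissue).
#' @export
compare_profiles <- function(region_meth, dmr_tables, samples,
                             methods = c("tsne", "umap"), seed = 42,
                             perplexity = 10, n_pcs = 10) {
  ids <- list(
    pDMR = dmr_tables$promoter$region_id[dmr_tables$promoter$is_dmr],
    eDMR = dmr_tables$enhancer$region_id[dmr_tables$enhancer$is_dmr]
  )
  ids$total <- c(ids$pDMR, ids$eDMR)
  tissues <- samples$tissue[match(colnames(region_meth$values), samples$sample_id)]
  rows <- list()
  for (profile in names(ids)) {
    sel <- intersect(ids[[profile]], rownames(region_meth$values))
    if (length(sel) < 2) {
      warning(sprintf("profile %s has %d usable DMR region(s); skipped",
                      profile, length(sel)))
      next
    }
    sub <- region_meth$values[sel, , drop = FALSE]
    for (m in methods) {
      emb <- embed_profile(sub, method = m, seed = seed,
                           perplexity = perplexity, n_pcs = n_pcs)
      labels <- kmeans_cluster(emb, k = 2, seed = seed)
      tab <- table(cluster = labels, tissue = tissues)
      rows[[length(rows) + 1L]] <- data.frame(
        profile_kind = profile, method = m, n_regions = length(sel),
        entropy = cluster_entropy(labels, tissues),
        c1_tumor = tab[1, "tumor"],
        c1_normal = tab[1, "normal"],
        c2_tumor = if (nrow(tab) > 1) tab[2, "tumor"] else 0L,
        c2_normal = if (nrow(tab) > 1) tab[2, "normal"] else 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
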