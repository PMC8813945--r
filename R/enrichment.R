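#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over `stats::p.adjust(method = "BH")`: q-values
#' are monotone in p rank, at least p, and at most 1.
#'
#' @param p numeric vector of p-values in \[0,1\] (NA allowed, propagated).
#' @return q-values, same length/order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("malformed GMT line: need name, description, >= 1 gene")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (defaults to set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) exact test of each set against a query gene list
#' within a fixed universe; sets are intersected with the universe first and
#' BH correction is applied across the tested collection.
#'
#' @param query character vector of genes (must lie within `universe`).
#' @param universe character vector, the background gene universe.
#' @param sets named list of character vectors (gene sets).
#' @param categories optional named character vector of set categories.
#' @return data frame sorted by q-value with set_name, category, a, b, c, d
#'   (a = |query ∩ set|, a+b = |query|, a+c = |set ∩ universe|,
#'   a+b+c+d = |universe|), odds_ratio (= ad/bc, `Inf` when bc = 0 with
#'   ad > 0), odds_ratio_haldane (0.5 added to each cell), p_value, q_value.
#' @export
fisher_enrichment <- function(query, universe, sets, categories = NULL) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must be contained in the universe")
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    a <- length(intersect(query, s))
    b <- length(query) - a
    c_ <- length(s) - a
    d <- length(universe) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    or <- if (b * c_ == 0) {
      if (a * d > 0) Inf else 0
    } else (a * d) / (b * c_)
    data.frame(
      set_name = nm,
      category = if (!is.null(categories)) unname(categories[nm]) else NA_character_,
      a = a, b = b, c = c_, d = d,
      odds_ratio = or,
      odds_ratio_haldane = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
      p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Risk-SNP proximity enrichment among DMRs
#'
#' Counts SNPs falling within `window_bp` of any DMR among the SNPs that can
#' be profiled at all (within the window of at least one tested region), and
#' tests the count against an upper-tail binomial with background hit
#' probability `p0`. By default `p0` is the DMR fraction among tested
#' regions — each profilable SNP's chance of sitting near a DMR were SNPs
#' exchangeable across tested regions.
#'
#' @param snps data frame with rsid, chrom, pos (0-based).
#' @param dmr_regions [region_set()] of DMR intervals (subset of
#'   `tested_regions`).
#' @param tested_regions [region_set()] of all testable regions.
#' @param window_bp flank width in bp (default 5000).
#' @param p0 background hit probability; default
#'   `nrow(dmr_regions) / nrow(tested_regions)`.
#' @return list with n_snps (profilable), k_hits, p0, p_value
#'   (`P(X >= k_hits)`), and the per-SNP hit table.
#' @export
snp_dmr_enrichment <- function(snps, dmr_regions, tested_regions,
                               window_bp = 5000, p0 = NULL) {
  if (!all(dmr_regions$region_id %in% tested_regions$region_id)) {
    stop("dmr_regions must be a subset of tested_regions")
  }
  prof <- within_window(snps, tested_regions, window_bp)
  profilable <- names(prof)[lengths(prof) > 0]
  n <- length(profilable)
  if (n == 0) stop("no SNP lies within the window of any tested region")
  hits <- within_window(snps[snps$rsid %in% profilable, , drop = FALSE],
                        dmr_regions, window_bp)
  hit_flag <- lengths(hits) > 0
  k <- sum(hit_flag)
  if (is.null(p0)) p0 <- nrow(dmr_regions) / nrow(tested_regions)
  if (p0 <= 0 || p0 > 1) stop("p0 must lie in (0, 1]")
  p_value <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(
    n_snps = n, k_hits = k, p0 = p0, p_value = p_value,
    snp_hits = data.frame(rsid = names(hits), near_dmr = unname(hit_flag),
                          stringsAsFactors = FALSE)
  )
}
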