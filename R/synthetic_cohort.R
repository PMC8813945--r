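inv_logit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Configuration for the synthetic paired-cohort generator
#'
#' Defaults mirror the study conditions the pipeline is designed for: 37
#' tumor/normal pairs profiled over 2,000 promoter and 3,000 enhancer
#' regions (~50,000 CpG sites), planted differential methylation with
#' hypomethylation dominance (4% hypo vs 2% hyper per kind, mean beta shift
#' 0.25), inverse methylation-expression coupling for a fraction of planted
#' DMRs, a multi-group pan-cancer expression panel with planted
#' tumor-type-specific genes, immune-infiltration fractions coupled to
#' chosen regions, and risk SNPs placed near DMRs with elevated probability.
#'
#' @param n_pairs number of tumor/normal patient pairs (>= 3).
#' @param n_genes,n_promoters,n_enhancers,n_super_enhancers element counts;
#'   `n_promoters <= n_genes` (one downstream gene per promoter).
#' @param cpgs_per_region_range inclusive integer range of CpG sites per
#'   region.
#' @param dmr_fraction_hypo,dmr_fraction_hyper fraction of regions planted
#'   as hypo-/hypermethylated DMRs; scalar or named per-kind vector
#'   (`promoter`, `enhancer`).
#' @param delta_beta planted mean beta shift in (0,1); scalar or named
#'   per-kind vector. Hypomethylated DMRs shift the tumor mean down.
#' @param beta_dispersion site-level logit-scale noise s.d.
#' @param patient_sd s.d. of the per-patient random effect shared between a
#'   patient's tumor and normal samples (global methylation level).
#' @param sample_sd s.d. of the per-sample global offset.
#' @param region_sample_sd s.d. of the region x sample interaction.
#' @param coupling_fraction fraction of planted DMRs whose target gene is
#'   inversely coupled to the region's methylation.
#' @param coupling_log2fc planted expression log2 fold change magnitude for
#'   coupled genes (sign opposite to the methylation shift).
#' @param nb_dispersion negative-binomial overdispersion of counts
#'   (`size = 1/nb_dispersion`).
#' @param n_other_cancer_groups,samples_per_group shape of the unpaired
#'   pan-cancer expression panel.
#' @param n_specific_genes planted focal-tumor-type-specific genes (drawn
#'   from hypomethylation-coupled, up-regulated targets).
#' @param n_celltypes,n_diff_celltypes immune cell types simulated and how
#'   many are differentially abundant between tumor and normal.
#' @param infiltration_coupled_regions number of regions whose methylation
#'   is coupled to a differential cell type's abundance. Allocated 65% to
#'   enhancer DMRs, 15% to promoter DMRs, 12% to non-DMR enhancers and 8%
#'   to non-DMR promoters, so infiltration coupling is enriched on enhancer
#'   DMRs.
#' @param infil_gamma logit-scale coupling strength between the latent
#'   infiltration level and coupled regions' methylation.
#' @param infil_noise_sd s.d. of the latent per-sample infiltration level.
#' @param n_snps number of risk SNPs.
#' @param snp_near_dmr_prob probability that a SNP is placed within the
#'   5 kb window of a planted DMR (elsewhere it lands near a random
#'   non-DMR region); `NULL` places SNPs uniformly across all tested
#'   regions (the null configuration).
#' @param seed RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 37,
                             n_genes = 4000,
                             n_promoters = 2000,
                             n_enhancers = 3000,
                             n_super_enhancers = 120,
                             cpgs_per_region_range = c(4, 16),
                             dmr_fraction_hypo = 0.04,
                             dmr_fraction_hyper = 0.02,
                             delta_beta = 0.25,
                             beta_dispersion = 0.35,
                             patient_sd = 0.15,
                             sample_sd = 0.10,
                             region_sample_sd = 0.25,
                             coupling_fraction = 0.4,
                             coupling_log2fc = 3,
                             nb_dispersion = 0.3,
                             n_other_cancer_groups = 5,
                             samples_per_group = 20,
                             n_specific_genes = 50,
                             n_celltypes = 10,
                             n_diff_celltypes = 4,
                             infiltration_coupled_regions = 100,
                             infil_gamma = 0.5,
                             infil_noise_sd = 0.5,
                             n_snps = 94,
                             snp_near_dmr_prob = 0.5,
                             seed = 1) {
  per_kind <- function(x, nm) {
    if (length(x) == 1 && is.null(names(x))) {
      return(c(promoter = unname(x), enhancer = unname(x)))
    }
    stopifnot(all(c("promoter", "enhancer") %in% names(x)))
    x[c("promoter", "enhancer")]
  }
  cfg <- list(
    n_pairs = n_pairs, n_genes = n_genes, n_promoters = n_promoters,
    n_enhancers = n_enhancers, n_super_enhancers = n_super_enhancers,
    cpgs_per_region_range = cpgs_per_region_range,
    dmr_fraction_hypo = per_kind(dmr_fraction_hypo),
    dmr_fraction_hyper = per_kind(dmr_fraction_hyper),
    delta_beta = per_kind(delta_beta),
    beta_dispersion = beta_dispersion, patient_sd = patient_sd,
    sample_sd = sample_sd, region_sample_sd = region_sample_sd,
    coupling_fraction = coupling_fraction, coupling_log2fc = coupling_log2fc,
    nb_dispersion = nb_dispersion,
    n_other_cancer_groups = n_other_cancer_groups,
    samples_per_group = samples_per_group,
    n_specific_genes = n_specific_genes,
    n_celltypes = n_celltypes, n_diff_celltypes = n_diff_celltypes,
    infiltration_coupled_regions = infiltration_coupled_regions,
    infil_gamma = infil_gamma, infil_noise_sd = infil_noise_sd,
    n_snps = n_snps, snp_near_dmr_prob = snp_near_dmr_prob,
    seed = seed
  )
  if (n_pairs < 3) stop("n_pairs must be at least 3")
  if (n_promoters > n_genes) stop("need at least one gene per promoter")
  fr <- cfg$dmr_fraction_hypo + cfg$dmr_fraction_hyper
  if (any(c(cfg$dmr_fraction_hypo, cfg$dmr_fraction_hyper) < 0) || any(fr > 1)) {
    stop("DMR fractions must be in [0,1] and sum to at most 1 per kind")
  }
  if (any(cfg$delta_beta <= 0) || any(cfg$delta_beta >= 1)) {
    stop("delta_beta must lie in (0,1)")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' A null configuration with nothing planted
#'
#' Convenience wrapper: no planted DMRs, no expression coupling, no
#' specific genes, no infiltration coupling, uniformly placed SNPs.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
null_config <- function(...) {
  args <- list(...)
  defaults <- list(dmr_fraction_hypo = 0, dmr_fraction_hyper = 0,
                   coupling_fraction = 0, n_specific_genes = 0,
                   infiltration_coupled_regions = 0, n_diff_celltypes = 0,
                   snp_near_dmr_prob = NULL)
  for (nm in names(defaults)) if (is.null(args[[nm]])) args[nm] <- defaults[nm]
  do.call(synthetic_config, args)
}

# Lay promoters and enhancers on a shared lattice over chr1..chr22 with
# inter-region gaps wider than twice the 5 kb SNP window, so region flanks
# never overlap and proximity counts stay exact.
layout_regions <- function(n_promoters, n_enhancers) {
  n <- n_promoters + n_enhancers
  kinds <- sample(c(rep("promoter", n_promoters), rep("enhancer", n_enhancers)))
  chroms <- paste0("chr", rep(1:22, length.out = n)[order(rep(1:22, length.out = n))])
  per_chrom <- table(factor(rep(1:22, length.out = n)))
  widths <- sample(500:2000, n, replace = TRUE)
  gaps <- sample(12000:30000, n, replace = TRUE)
  start <- integer(n)
  chrom <- character(n)
  i <- 0L
  for (cc in seq_len(22)) {
    pos <- 10000L
    for (j in seq_len(per_chrom[[cc]])) {
      i <- i + 1L
      chrom[i] <- paste0("chr", cc)
      start[i] <- pos
      pos <- pos + widths[i] + gaps[i]
    }
  }
  data.frame(chrom = chrom, start = start, end = start + widths,
             kind = kinds, slot = seq_len(n), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic paired tumor/normal cohort
#'
#' Produces CpG-level beta values (logit-normal with shared patient effects,
#' per-sample offsets and region x sample interaction), planted hypo/hyper
#' DMRs, negative-binomial expression counts with inverse
#' methylation-expression coupling, an enhancer-promoter interaction map, a
#' pan-cancer expression panel with planted focal-specific genes,
#' immune-infiltration fractions coupled to chosen regions, risk SNPs
#' placed near or away from DMRs, and the planted-truth tables every
#' downstream check scores against. Identical seeds give identical bundles.
#'
#' @param config a [synthetic_config()].
#' @return list of class `cohort_bundle` with elements samples, cpgs, beta,
#'   regions (promoter/enhancer/super_enhancer/pmd [region_set()]s),
#'   epi_raw, epi_map, genes, counts, panel, infiltration, snps, truth,
#'   region_beta (region-level generative means), config.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n_pairs <- config$n_pairs
  patients <- sprintf("P%03d", seq_len(n_pairs))
  samples <- data.frame(
    sample_id = c(sprintf("T%03d", seq_len(n_pairs)), sprintf("N%03d", seq_len(n_pairs))),
    patient_id = c(patients, patients),
    tissue = rep(c("tumor", "normal"), each = n_pairs),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(samples)
  is_tumor <- samples$tissue == "tumor"

  ## --- regions -------------------------------------------------------------
  lay <- layout_regions(config$n_promoters, config$n_enhancers)
  lay$region_id <- ifelse(lay$kind == "promoter",
                          sprintf("prom_%04d", cumsum(lay$kind == "promoter")),
                          sprintf("enh_%04d", cumsum(lay$kind == "enhancer")))
  promoters <- with(lay[lay$kind == "promoter", ],
                    region_set(chrom, start, end, region_id, kind = "promoter"))
  enhancers <- with(lay[lay$kind == "enhancer", ],
                    region_set(chrom, start, end, region_id, kind = "enhancer"))

  # super-enhancers: spans of 2-4 consecutive lattice slots on one chromosome
  se_rows <- list()
  if (config$n_super_enhancers > 0) {
    starts <- sort(sample(seq_len(nrow(lay) - 4), config$n_super_enhancers))
    for (k in seq_along(starts)) {
      i <- starts[k]
      span <- sample(2:4, 1)
      j <- min(i + span - 1, nrow(lay))
      while (j > i && lay$chrom[j] != lay$chrom[i]) j <- j - 1
      se_rows[[k]] <- data.frame(chrom = lay$chrom[i], start = lay$start[i],
                                 end = lay$end[j], stringsAsFactors = FALSE)
    }
  }
  se_df <- if (length(se_rows)) do.call(rbind, se_rows) else
    data.frame(chrom = character(), start = integer(), end = integer())
  se_df <- unique(se_df)
  super_enhancers <- region_set(se_df$chrom, se_df$start, se_df$end,
                                sprintf("se_%03d", seq_len(nrow(se_df))),
                                kind = "super_enhancer")

  # PMDs: contiguous stretches of 5-15 lattice slots covering ~25% of slots
  pmd_rows <- list()
  covered <- 0L
  target <- round(0.25 * nrow(lay))
  next_free <- 1L
  while (covered < target && next_free < nrow(lay) - 15) {
    i <- next_free + sample(3:20, 1)
    if (i >= nrow(lay) - 15) break
    span <- sample(5:15, 1)
    j <- min(i + span - 1, nrow(lay))
    while (j > i && lay$chrom[j] != lay$chrom[i]) j <- j - 1
    pmd_rows[[length(pmd_rows) + 1L]] <- data.frame(
      chrom = lay$chrom[i], start = lay$start[i] - 2000L, end = lay$end[j] + 2000L,
      stringsAsFactors = FALSE)
    covered <- covered + (j - i + 1L)
    next_free <- j + 1L
  }
  pmd_df <- if (length(pmd_rows)) do.call(rbind, pmd_rows) else
    data.frame(chrom = character(), start = integer(), end = integer())
  pmds <- region_set(pmd_df$chrom, pmd_df$start, pmd_df$end,
                     sprintf("pmd_%03d", seq_len(nrow(pmd_df))), kind = "pmd")

  ## --- CpG sites -----------------------------------------------------------
  rng <- config$cpgs_per_region_range
  n_sites_per <- sample(rng[1]:rng[2], nrow(lay), replace = TRUE)
  site_region <- rep(lay$region_id, n_sites_per)
  site_chrom <- rep(lay$chrom, n_sites_per)
  site_pos <- unlist(lapply(seq_len(nrow(lay)), function(i) {
    sort(sample(lay$start[i]:(lay$end[i] - 1L), n_sites_per[i]))
  }), use.names = FALSE)
  cpgs <- data.frame(
    site_id = sprintf("cg%06d", seq_along(site_pos)),
    chrom = site_chrom, pos = site_pos, region_id = site_region,
    stringsAsFactors = FALSE
  )

  ## --- planted DMRs --------------------------------------------------------
  plant_kind <- function(kind, ids) {
    n <- length(ids)
    n_hypo <- round(config$dmr_fraction_hypo[[kind]] * n)
    n_hyper <- round(config$dmr_fraction_hyper[[kind]] * n)
    if (n_hypo + n_hyper > n) stop("more planted DMRs than regions of kind ", kind)
    sel <- sample(ids, n_hypo + n_hyper)
    data.frame(
      region_id = sel,
      kind = rep(kind, length(sel)),
      direction = rep(c("hypo", "hyper"), c(n_hypo, n_hyper)),
      stringsAsFactors = FALSE
    )
  }
  true_dmrs <- rbind(plant_kind("promoter", promoters$region_id),
                     plant_kind("enhancer", enhancers$region_id))

  ## --- region-level methylation model -------------------------------------
  n_regions <- nrow(lay)
  base_beta <- setNames(runif(n_regions, 0.35, 0.65), lay$region_id)
  mu <- logit(base_beta)
  shift <- setNames(numeric(n_regions), lay$region_id)
  if (nrow(true_dmrs)) {
    dlt <- config$delta_beta[true_dmrs$kind]
    sgn <- ifelse(true_dmrs$direction == "hypo", -1, 1)
    target <- pmin(pmax(base_beta[true_dmrs$region_id] + sgn * dlt, 0.02), 0.98)
    shift[true_dmrs$region_id] <- logit(target) - mu[true_dmrs$region_id]
  }
  a_pat <- rnorm(n_pairs, 0, config$patient_sd)[match(samples$patient_id, patients)]
  b_smp <- rnorm(n_samples, 0, config$sample_sd)
  c_int <- matrix(rnorm(n_regions * n_samples, 0, config$region_sample_sd),
                  n_regions, n_samples)
  logit_region <- mu + outer(shift, as.numeric(is_tumor)) + c_int
  logit_region <- sweep(logit_region, 2, a_pat + b_smp, "+")
  rownames(logit_region) <- lay$region_id
  colnames(logit_region) <- samples$sample_id

  ## --- immune infiltration (latent level feeds back into methylation) -----
  K <- config$n_celltypes
  celltypes <- sprintf("CT%02d", seq_len(K))
  ct_base <- rnorm(K, 0, 0.5)
  ct_shift <- numeric(K)
  if (config$n_diff_celltypes > 0) {
    nd <- min(config$n_diff_celltypes, K)
    ct_shift[seq_len(nd)] <- rep(c(0.8, -0.8), length.out = nd)
  }
  u <- matrix(rnorm(K * n_samples, 0, config$infil_noise_sd), K, n_samples)
  eta <- ct_base + outer(ct_shift, as.numeric(is_tumor)) + u
  w <- exp(eta)
  infiltration <- sweep(w, 2, colSums(w), "/")
  rownames(infiltration) <- celltypes
  colnames(infiltration) <- samples$sample_id

  true_imr <- data.frame(region_id = character(), cell_type = character(),
                         sign = integer(), is_dmr = logical(),
                         stringsAsFactors = FALSE)
  if (config$infiltration_coupled_regions > 0 && config$n_diff_celltypes > 0) {
    dmr_enh <- intersect(true_dmrs$region_id, enhancers$region_id)
    dmr_prom <- intersect(true_dmrs$region_id, promoters$region_id)
    non_enh <- setdiff(enhancers$region_id, dmr_enh)
    non_prom <- setdiff(promoters$region_id, dmr_prom)
    alloc <- c(round(0.65 * config$infiltration_coupled_regions),
               round(0.15 * config$infiltration_coupled_regions),
               round(0.12 * config$infiltration_coupled_regions))
    alloc <- c(alloc, config$infiltration_coupled_regions - sum(alloc))
    pools <- list(dmr_enh, dmr_prom, non_enh, non_prom)
    if (any(vapply(pools, length, 0L) < alloc)) {
      stop("infiltration_coupled_regions exceeds the available region pools")
    }
    coupled <- unlist(mapply(sample, pools, alloc, SIMPLIFY = FALSE), use.names = FALSE)
    diff_cts <- celltypes[seq_len(min(config$n_diff_celltypes, K))]
    true_imr <- data.frame(
      region_id = coupled,
      cell_type = rep(diff_cts, length.out = length(coupled)),
      sign = sample(c(-1L, 1L), length(coupled), replace = TRUE),
      is_dmr = coupled %in% true_dmrs$region_id,
      stringsAsFactors = FALSE
    )
    z <- u / config$infil_noise_sd
    for (i in seq_len(nrow(true_imr))) {
      r <- true_imr$region_id[i]
      ct <- match(true_imr$cell_type[i], celltypes)
      logit_region[r, ] <- logit_region[r, ] +
        true_imr$sign[i] * config$infil_gamma * z[ct, ]
    }
  }

  region_beta <- inv_logit(logit_region)

  ## --- site-level beta -----------------------------------------------------
  site_logit <- logit_region[cpgs$region_id, , drop = FALSE] +
    matrix(rnorm(nrow(cpgs) * n_samples, 0, config$beta_dispersion),
           nrow(cpgs), n_samples)
  beta <- inv_logit(site_logit)
  rownames(beta) <- cpgs$site_id
  colnames(beta) <- samples$sample_id

  ## --- genes, promoter map, EPI map ---------------------------------------
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  is_coding <- runif(config$n_genes) < 0.9
  genes <- data.frame(
    gene_id = gene_ids,
    promoter_region_id = c(promoters$region_id,
                           rep(NA_character_, config$n_genes - config$n_promoters)),
    is_coding = is_coding,
    stringsAsFactors = FALSE
  )
  n_links <- sample(1:3, config$n_enhancers, replace = TRUE)
  epi_raw <- data.frame(
    enhancer_id = rep(enhancers$region_id, n_links),
    gene_id = sample(gene_ids, sum(n_links), replace = TRUE),
    pet_count = sample(1:20, sum(n_links), replace = TRUE),
    stringsAsFactors = FALSE
  )
  epi_map <- filter_epi_links(epi_raw, min_pet = 5)

  ## --- expression with inverse coupling ------------------------------------
  base_log2 <- setNames(rnorm(config$n_genes, 6, 1.5), gene_ids)
  coding_set <- gene_ids[is_coding]
  prom_gene <- setNames(genes$gene_id[!is.na(genes$promoter_region_id)],
                        genes$promoter_region_id[!is.na(genes$promoter_region_id)])
  epi_by_enh <- split(epi_map$gene_id, epi_map$enhancer_id)

  n_couple <- round(config$coupling_fraction * nrow(true_dmrs))
  true_functional <- data.frame(region_id = character(), gene_id = character(),
                                direction = character(), stringsAsFactors = FALSE)
  if (n_couple > 0) {
    cand <- true_dmrs[sample(nrow(true_dmrs)), , drop = FALSE]
    used_genes <- character(0)
    picked <- list()
    for (i in seq_len(nrow(cand))) {
      if (length(picked) >= n_couple) break
      r <- cand$region_id[i]
      g <- if (cand$kind[i] == "promoter") {
        gg <- unname(prom_gene[r])
        if (!is.na(gg) && gg %in% coding_set) gg else NA_character_
      } else {
        opts <- setdiff(intersect(epi_by_enh[[r]], coding_set), used_genes)
        if (length(opts)) opts[sample.int(length(opts), 1)] else NA_character_
      }
      if (is.na(g) || g %in% used_genes) next
      used_genes <- c(used_genes, g)
      picked[[length(picked) + 1L]] <- data.frame(
        region_id = r, gene_id = g, direction = cand$direction[i],
        stringsAsFactors = FALSE)
    }
    true_functional <- do.call(rbind, picked)
  }

  log2mu <- matrix(rep(base_log2, n_samples), config$n_genes, n_samples)
  rownames(log2mu) <- gene_ids
  colnames(log2mu) <- samples$sample_id
  if (nrow(true_functional)) {
    for (i in seq_len(nrow(true_functional))) {
      r <- true_functional$region_id[i]
      g <- true_functional$gene_id[i]
      kind_r <- if (r %in% promoters$region_id) "promoter" else "enhancer"
      slope <- config$coupling_log2fc / config$delta_beta[[kind_r]]
      log2mu[g, ] <- base_log2[g] + slope * (base_beta[r] - region_beta[r, ])
    }
  }
  counts <- matrix(
    rnbinom(length(log2mu), mu = 2^log2mu, size = 1 / config$nb_dispersion),
    nrow(log2mu), ncol(log2mu), dimnames = dimnames(log2mu)
  )

  ## --- pan-cancer panel with planted specific genes ------------------------
  hypo_coupled <- true_functional$gene_id[true_functional$direction == "hypo"]
  if (config$n_specific_genes > length(hypo_coupled)) {
    stop("n_specific_genes exceeds the number of hypomethylation-coupled genes")
  }
  true_specific <- if (config$n_specific_genes > 0) {
    sort(sample(hypo_coupled, config$n_specific_genes))
  } else character(0)
  panel_base <- base_log2
  bump <- setdiff(hypo_coupled, true_specific)
  panel_base[bump] <- base_log2[bump] + config$coupling_log2fc
  panel <- list()
  if (config$n_other_cancer_groups > 0) {
    for (gidx in seq_len(config$n_other_cancer_groups)) {
      nm <- sprintf("other%02d", gidx)
      mat <- matrix(
        rnbinom(config$n_genes * config$samples_per_group,
                mu = 2^panel_base, size = 1 / config$nb_dispersion),
        config$n_genes, config$samples_per_group,
        dimnames = list(gene_ids, sprintf("%s_S%02d", nm, seq_len(config$samples_per_group)))
      )
      panel[[nm]] <- mat
    }
  }

  ## --- risk SNPs ------------------------------------------------------------
  tested <- rbind(as.data.frame(promoters), as.data.frame(enhancers))
  snps <- simulate_risk_snps(tested, true_dmrs$region_id, config$n_snps,
                             near_dmr_prob = config$snp_near_dmr_prob,
                             window_bp = 5000)

  truth <- list(
    true_dmrs = true_dmrs,
    true_functional = true_functional,
    true_specific_genes = true_specific,
    true_imr = true_imr,
    snp_near_dmr = attr(snps, "truth")
  )
  attr(snps, "truth") <- NULL
  bundle <- list(
    config = config, samples = samples, cpgs = cpgs, beta = beta,
    regions = list(promoter = promoters, enhancer = enhancers,
                   super_enhancer = super_enhancers, pmd = pmds),
    epi_raw = epi_raw, epi_map = epi_map, genes = genes,
    counts = counts, panel = panel, infiltration = infiltration,
    snps = as.data.frame(snps), truth = truth, region_beta = region_beta
  )
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "cohort_bundle: %d pairs, %d CpGs over %d promoters + %d enhancers, %d genes\n",
    nrow(x$samples) / 2, nrow(x$cpgs), nrow(x$regions$promoter),
    nrow(x$regions$enhancer), nrow(x$genes)))
  invisible(x)
}

#' Place risk SNPs near or away from DMRs
#'
#' Each SNP is attached to one tested region: a DMR with probability
#' `near_dmr_prob` (uniformly among DMRs), otherwise a uniformly chosen
#' non-DMR region; with `near_dmr_prob = NULL` the region is uniform over
#' all tested regions, the exchangeable null. The position is uniform
#' within the region's `window_bp` flank envelope.
#'
#' @param tested_regions data frame with chrom, start, end, region_id.
#' @param dmr_ids character vector of DMR region ids.
#' @param n_snps number of SNPs.
#' @param near_dmr_prob probability of DMR placement, or `NULL` for the
#'   uniform null.
#' @param window_bp flank width (default 5000).
#' @return data frame rsid, chrom, pos (0-based); the per-SNP truth flag is
#'   in the `"truth"` attribute.
#' @export
simulate_risk_snps <- function(tested_regions, dmr_ids, n_snps,
                               near_dmr_prob = 0.5, window_bp = 5000) {
  is_dmr <- tested_regions$region_id %in% dmr_ids
  if (is.null(near_dmr_prob)) {
    idx <- sample.int(nrow(tested_regions), n_snps, replace = TRUE)
  } else {
    if (!any(is_dmr) && near_dmr_prob > 0) stop("no DMR regions to place SNPs near")
    near <- runif(n_snps) < near_dmr_prob
    idx <- integer(n_snps)
    idx[near] <- sample(which(is_dmr), sum(near), replace = TRUE)
    idx[!near] <- sample(which(!is_dmr), sum(!near), replace = TRUE)
  }
  lo <- pmax(tested_regions$start[idx] - window_bp, 0L)
  hi <- tested_regions$end[idx] + window_bp - 1L
  pos <- lo + floor(runif(n_snps) * (hi - lo + 1L))
  out <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    chrom = tested_regions$chrom[idx],
    pos = as.integer(pos),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- data.frame(
    rsid = out$rsid, near_dmr = is_dmr[idx], stringsAsFactors = FALSE
  )
  out
}

write_tsv <- function(df, path, row_col = NULL) {
  if (!is.null(row_col)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE), row_col),
                as.data.frame(df))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort bundle to disk
#'
#' Emits every table in the pipeline's external formats (BED for regions,
#' TSV elsewhere, 1-based SNP positions, config echo as YAML) plus a
#' manifest of file checksums. Beta values are written with 6 significant
#' decimals.
#'
#' @param bundle a [generate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return data frame manifest (file, md5), invisibly; also written as
#'   `manifest.tsv`.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_regions(bundle$regions$promoter, fp("promoters.bed"))
  write_regions(bundle$regions$enhancer, fp("enhancers.bed"))
  write_regions(bundle$regions$super_enhancer, fp("super_enhancers.bed"))
  write_regions(bundle$regions$pmd, fp("pmds.bed"))
  write_tsv(bundle$cpgs[, c("site_id", "chrom", "pos")], fp("cpg_manifest.tsv"))
  write_tsv(as.data.frame(round(bundle$beta, 6)), fp("beta_matrix.tsv"), "site_id")
  write_tsv(as.data.frame(bundle$counts), fp("counts.tsv"), "gene_id")
  for (nm in names(bundle$panel)) {
    write_tsv(as.data.frame(bundle$panel[[nm]]), fp(sprintf("panel_%s.tsv", nm)), "gene_id")
  }
  write_tsv(bundle$epi_raw, fp("epi_map.tsv"))
  snps_out <- bundle$snps
  snps_out$pos <- snps_out$pos + 1L  # 1-based on disk
  write_tsv(snps_out, fp("snps.tsv"))
  write_tsv(as.data.frame(round(bundle$infiltration, 8)), fp("infiltration.tsv"), "cell_type")
  write_tsv(bundle$samples, fp("samples.tsv"))
  write_tsv(bundle$genes, fp("genes.tsv"))
  write_tsv(bundle$truth$true_dmrs, fp("truth_dmrs.tsv"))
  write_tsv(bundle$truth$true_functional, fp("truth_functional.tsv"))
  writeLines(bundle$truth$true_specific_genes, fp("truth_specific_genes.txt"))
  write_tsv(bundle$truth$true_imr, fp("truth_imr.tsv"))
  write_tsv(bundle$truth$snp_near_dmr, fp("truth_snps.tsv"))
  cfg <- bundle$config
  class(cfg) <- NULL
  cfg$snp_near_dmr_prob <- if (is.null(cfg$snp_near_dmr_prob)) "null" else cfg$snp_near_dmr_prob
  yaml::write_yaml(cfg, fp("config.yaml"))
  files <- sort(setdiff(list.files(dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, fp("manifest.tsv"))
  invisible(manifest)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param min_pet PET filter applied to the EPI map on read (default 5).
#' @return list with the same data elements as a `cohort_bundle` (truth
#'   tables included when present).
#' @export
read_cohort <- function(dir, min_pet = 5) {
  fp <- function(x) file.path(dir, x)
  panel_files <- list.files(dir, pattern = "^panel_.*\\.tsv$")
  panel <- lapply(panel_files, function(f) read_matrix_tsv(fp(f)))
  names(panel) <- sub("^panel_(.*)\\.tsv$", "\\1", panel_files)
  out <- list(
    samples = read.delim(fp("samples.tsv"), stringsAsFactors = FALSE),
    cpgs = read_cpg_manifest(fp("cpg_manifest.tsv")),
    beta = read_matrix_tsv(fp("beta_matrix.tsv")),
    regions = list(
      promoter = read_regions(fp("promoters.bed"), "promoter"),
      enhancer = read_regions(fp("enhancers.bed"), "enhancer"),
      super_enhancer = read_regions(fp("super_enhancers.bed"), "super_enhancer"),
      pmd = read_regions(fp("pmds.bed"), "pmd")
    ),
    epi_map = read_epi_map(fp("epi_map.tsv"), min_pet = min_pet),
    genes = read.delim(fp("genes.tsv"), stringsAsFactors = FALSE),
    counts = read_matrix_tsv(fp("counts.tsv")),
    panel = panel,
    infiltration = read_matrix_tsv(fp("infiltration.tsv")),
    snps = read_snps(fp("snps.tsv"))
  )
  if (file.exists(fp("truth_dmrs.tsv"))) {
    out$truth <- list(
      true_dmrs = read.delim(fp("truth_dmrs.tsv"), stringsAsFactors = FALSE),
      true_functional = read.delim(fp("truth_functional.tsv"), stringsAsFactors = FALSE),
      true_specific_genes = readLines(fp("truth_specific_genes.txt")),
      true_imr = read.delim(fp("truth_imr.tsv"), stringsAsFactors = FALSE),
      snp_near_dmr = read.delim(fp("truth_snps.tsv"), stringsAsFactors = FALSE)
    )
  }
  out
}
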