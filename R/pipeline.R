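#' Pipeline configuration
#'
#' Collects every analysis threshold (with the study defaults), the input
#' source (a [synthetic_config()] or a directory of tables in the external
#' formats), stage toggles, seeds and the output directory.
#'
#' @param synthetic a [synthetic_config()], or `NULL` to read `input_dir`.
#' @param input_dir directory readable by [read_cohort()] (ignored when
#'   `synthetic` is given).
#' @param outdir output directory for stage tables.
#' @param dmr_q,deg_lfc,deg_q,pet_min,snp_window,imr_q,infil_q,specific_fc,specific_p
#'   analysis thresholds; defaults are the study values (DMR FDR < 0.01,
#'   DEG |log2FC| > 2 & q < 0.01, PET >= 5, 5 kb SNP window, IMR and
#'   infiltration q < 0.01, specific genes fold > 2 & one-sided p < 0.05).
#' @param embed_seed seed for embedding/clustering.
#' @param embed_methods embedding methods to run.
#' @param perplexity t-SNE perplexity (default 10, the study setting).
#' @param max_missing_frac site missingness filter.
#' @param gene_sets optional named list of gene sets for enrichment stages;
#'   when `NULL` in synthetic mode, sets are built with
#'   [make_synthetic_gene_sets()].
#' @param stages named logical vector toggling optional stages
#'   (`embedding`, `specificity`, `enrichment`, `snp`, `immune`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL,
                            outdir = tempfile("dmrscape_run_"),
                            dmr_q = 0.01, deg_lfc = 2, deg_q = 0.01,
                            pet_min = 5, snp_window = 5000,
                            imr_q = 0.01, infil_q = 0.01,
                            specific_fc = 2, specific_p = 0.05,
                            embed_seed = 42,
                            embed_methods = c("tsne", "umap"),
                            perplexity = 10,
                            max_missing_frac = 0.2,
                            gene_sets = NULL,
                            stages = c(embedding = TRUE, specificity = TRUE,
                                       enrichment = TRUE, snp = TRUE,
                                       immune = TRUE)) {
  if (is.null(synthetic) && is.null(input_dir)) {
    stop("either a synthetic config or an input directory is required")
  }
  stopifnot(dmr_q > 0, deg_lfc > 0, deg_q > 0, pet_min >= 0, snp_window >= 0,
            imr_q > 0, infil_q > 0, specific_fc > 0, specific_p > 0)
  cfg <- list(
    synthetic = synthetic, input_dir = input_dir, outdir = outdir,
    dmr_q = dmr_q, deg_lfc = deg_lfc, deg_q = deg_q, pet_min = pet_min,
    snp_window = snp_window, imr_q = imr_q, infil_q = infil_q,
    specific_fc = specific_fc, specific_p = specific_p,
    embed_seed = embed_seed, embed_methods = embed_methods,
    perplexity = perplexity,
    max_missing_frac = max_missing_frac, gene_sets = gene_sets,
    stages = stages
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build gene sets from a synthetic cohort
#'
#' One set collecting the planted coupled target genes (diluted with random
#' genes), plus random sets — enough structure for the enrichment stages to
#' have a planted positive and a null background.
#'
#' @param bundle a `cohort_bundle`.
#' @param n_random number of random sets (default 20).
#' @param set_size size of each random set (default 50).
#' @param seed RNG seed.
#' @return named list of gene sets with a `"categories"` attribute.
#' @export
make_synthetic_gene_sets <- function(bundle, n_random = 20, set_size = 50, seed = 7) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  genes <- bundle$genes$gene_id
  sets <- list()
  planted <- unique(bundle$truth$true_functional$gene_id)
  if (length(planted) >= 5) {
    sets[["planted_coupled"]] <- unique(c(
      planted, sample(setdiff(genes, planted), round(length(planted) / 4))
    ))
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_%02d", i)]] <- sample(genes, set_size)
  }
  attr(sets, "categories") <- setNames(
    c(if (length(planted) >= 5) "planted" else NULL, rep("random", n_random)),
    names(sets)
  )
  sets
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  list(result = res, seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full promoter/enhancer methylation pipeline
#'
#' Executes, in order: ingest or synthetic generation; site filtering;
#' region aggregation and DMR calling per kind; target mapping; DEG
#' calling; functional DMRs; seDMRs; embedding/entropy comparison;
#' specificity correlation; gene-set enrichment; SNP proximity enrichment;
#' and the immune-infiltration analysis. Every stage writes its table under
#' `config$outdir` and the run is deterministic at fixed seeds.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_manifest` with `results` (per-stage objects),
#'   `counts` (per-stage row counts), `files` (file -> md5 checksum),
#'   `timing` (per-stage seconds) and a config echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages_on <- function(s) isTRUE(config$stages[[s]])
  results <- list()
  timing <- c()
  counts <- c()
  note <- function(nm, st, n) {
    results[[nm]] <<- st$result
    timing[nm] <<- st$seconds
    counts[nm] <<- n
  }

  st <- run_stage("ingest", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else read_cohort(config$input_dir, min_pet = config$pet_min)
  })
  bundle <- st$result
  note("ingest", st, nrow(bundle$cpgs))

  st <- run_stage("filter_sites", {
    filter_sites(bundle$beta, max_missing_frac = config$max_missing_frac)
  })
  beta <- st$result
  note("filter_sites", st, nrow(beta))

  st <- run_stage("aggregate", {
    lapply(bundle$regions[c("promoter", "enhancer")], function(rs) {
      aggregate_region_methylation(beta, assign_cpgs_to_regions(bundle$cpgs, rs))
    })
  })
  meth <- st$result
  note("aggregate", st, sum(vapply(meth, function(m) nrow(m$values), 0L)))

  st <- run_stage("call_dmrs", {
    list(
      promoter = call_dmrs(meth$promoter, bundle$samples, "promoter", config$dmr_q),
      enhancer = call_dmrs(meth$enhancer, bundle$samples, "enhancer", config$dmr_q)
    )
  })
  dmrs <- st$result
  note("call_dmrs", st, sum(dmrs$promoter$is_dmr) + sum(dmrs$enhancer$is_dmr))
  write_tsv(dmr_table_with_coords(dmrs$promoter, bundle$regions$promoter),
            file.path(outdir, "dmrs_promoter.tsv"))
  write_tsv(dmr_table_with_coords(dmrs$enhancer, bundle$regions$enhancer),
            file.path(outdir, "dmrs_enhancer.tsv"))

  st <- run_stage("targets", {
    list(promoter = map_promoter_targets(bundle$genes),
         enhancer = map_enhancer_targets(bundle$epi_map, bundle$genes))
  })
  targets <- st$result
  note("targets", st, nrow(targets$promoter) + nrow(targets$enhancer))

  st <- run_stage("call_degs", {
    call_degs(bundle$counts, bundle$samples, config$deg_lfc, config$deg_q)
  })
  degs <- st$result
  note("call_degs", st, sum(degs$is_deg))
  write_tsv(degs, file.path(outdir, "degs.tsv"))

  st <- run_stage("functional_dmrs", {
    list(
      promoter = define_functional_dmrs(dmrs$promoter, degs, targets$promoter),
      enhancer = define_functional_dmrs(dmrs$enhancer, degs, targets$enhancer)
    )
  })
  fdmrs <- st$result
  note("functional_dmrs", st,
       sum(fdmrs$promoter$pairs$is_functional) + sum(fdmrs$enhancer$pairs$is_functional))
  write_tsv(rbind(fdmrs$promoter$pairs, fdmrs$enhancer$pairs),
            file.path(outdir, "functional_dmrs.tsv"))

  st <- run_stage("sedmrs", {
    define_sedmrs(bundle$regions$super_enhancer, dmrs$enhancer,
                  bundle$regions$enhancer, targets$enhancer)
  })
  note("sedmrs", st, nrow(st$result))
  write_tsv(st$result, file.path(outdir, "sedmrs.tsv"))

  if (stages_on("embedding")) {
    st <- run_stage("embedding", {
      full_meth <- list(
        values = rbind(meth$promoter$values, meth$enhancer$values),
        n_sites = c(meth$promoter$n_sites, meth$enhancer$n_sites)
      )
      class(full_meth) <- "region_methylation"
      compare_profiles(full_meth, dmrs, bundle$samples,
                       methods = config$embed_methods, seed = config$embed_seed,
                       perplexity = config$perplexity)
    })
    note("embedding", st, nrow(st$result))
    write_tsv(st$result, file.path(outdir, "cluster_entropy.tsv"))
  }

  norm_expr <- normalize_counts(bundle$counts)$normalized
  if (stages_on("specificity")) {
    st <- run_stage("specificity", {
      pairs <- match_pairs(bundle$samples)
      focal <- norm_expr[, pairs$tumor, drop = FALSE]
      comparison <- c(bundle$panel, list(cohort_normal = norm_expr[, pairs$normal, drop = FALSE]))
      specific <- define_specific_genes(focal, comparison,
                                        config$specific_fc, config$specific_p)
      all_targets <- rbind(targets$promoter[, c("region_id", "gene_id")],
                           targets$enhancer[, c("region_id", "gene_id")])
      meth_all <- list(values = rbind(meth$promoter$values, meth$enhancer$values))
      class(meth_all) <- "region_methylation"
      dmr_ids <- c(dmrs$promoter$region_id[dmrs$promoter$is_dmr],
                   dmrs$enhancer$region_id[dmrs$enhancer$is_dmr])
      links <- all_targets[all_targets$region_id %in% dmr_ids, , drop = FALSE]
      cors <- correlate_methylation_expression(meth_all, norm_expr, links)
      is_spec <- cors$gene_id %in% specific
      comp <- if (sum(is_spec) >= 3 && sum(!is_spec) >= 3) {
        compare_correlation_distributions(cors$rho[is_spec], cors$rho[!is_spec])
      } else list(p_value = NA_real_, median_specific = NA_real_, median_other = NA_real_)
      list(specific_genes = specific, correlations = cors, comparison = comp)
    })
    note("specificity", st, nrow(st$result$correlations))
    write_tsv(cbind(st$result$correlations,
                    is_specific_gene = st$result$correlations$gene_id %in%
                      st$result$specific_genes),
              file.path(outdir, "methylation_expression_correlation.tsv"))
    writeLines(st$result$specific_genes, file.path(outdir, "specific_genes.txt"))
  }

  gene_sets <- config$gene_sets
  if (is.null(gene_sets) && !is.null(bundle$truth)) {
    gene_sets <- make_synthetic_gene_sets(bundle)
  }
  if (stages_on("enrichment") && !is.null(gene_sets)) {
    st <- run_stage("enrichment", {
      universe <- bundle$genes$gene_id[bundle$genes$is_coding]
      lapply(fdmrs, function(f) {
        q <- intersect(unique(f$pairs$gene_id[f$pairs$is_functional]), universe)
        if (!length(q)) return(data.frame())
        fisher_enrichment(q, universe, gene_sets,
                          categories = attr(gene_sets, "categories"))
      })
    })
    note("enrichment", st, sum(vapply(st$result, nrow, 0L)))
    enr <- do.call(rbind, Map(cbind, kind = names(st$result),
                              lapply(st$result, function(x) if (nrow(x)) x else NULL)))
    if (!is.null(enr)) write_tsv(enr, file.path(outdir, "gene_set_enrichment.tsv"))
  }

  if (stages_on("snp")) {
    st <- run_stage("snp_enrichment", {
      tested <- region_set(
        c(bundle$regions$promoter$chrom, bundle$regions$enhancer$chrom),
        c(bundle$regions$promoter$start, bundle$regions$enhancer$start),
        c(bundle$regions$promoter$end, bundle$regions$enhancer$end),
        c(bundle$regions$promoter$region_id, bundle$regions$enhancer$region_id),
        kind = "promoter"
      )
      dmr_ids <- c(dmrs$promoter$region_id[dmrs$promoter$is_dmr],
                   dmrs$enhancer$region_id[dmrs$enhancer$is_dmr])
      dmr_regions <- tested[tested$region_id %in% dmr_ids, , drop = FALSE]
      snp_dmr_enrichment(bundle$snps, dmr_regions, tested, config$snp_window)
    })
    note("snp_enrichment", st, st$result$k_hits)
    write_tsv(st$result$snp_hits, file.path(outdir, "snp_dmr_hits.tsv"))
  }

  if (stages_on("immune")) {
    st <- run_stage("immune", {
      diff_ct <- differential_infiltration(bundle$infiltration, bundle$samples,
                                           config$infil_q)
      cts <- diff_ct$cell_type[diff_ct$is_differential]
      imr <- list()
      overlap <- list()
      pmd_split <- list()
      if (length(cts)) {
        for (kind in c("promoter", "enhancer")) {
          dmr_ids <- dmrs[[kind]]$region_id[dmrs[[kind]]$is_dmr]
          imr[[kind]] <- define_imrs(meth[[kind]], bundle$infiltration, cts,
                                     bundle$samples, q_threshold = config$imr_q,
                                     dmr_ids = dmr_ids)
          ids <- imr_region_ids(imr[[kind]])
          overlap[[kind]] <- imr_dmr_overlap_stats(
            ids, rownames(meth[[kind]]$values), dmr_ids, kind)
          pmd_split[[kind]] <- stratify_by_pmd(ids, bundle$regions[[kind]],
                                               bundle$regions$pmd)
        }
      }
      list(differential = diff_ct, imr = imr, overlap = overlap,
           pmd_split = pmd_split)
    })
    note("immune", st, sum(vapply(st$result$imr, function(x) sum(x$is_imr_pair), 0L)))
    write_tsv(st$result$differential, file.path(outdir, "differential_infiltration.tsv"))
    if (length(st$result$imr)) {
      imr_all <- do.call(rbind, Map(cbind, kind = names(st$result$imr), st$result$imr))
      write_tsv(imr_all, file.path(outdir, "imrs.tsv"))
      write_tsv(do.call(rbind, st$result$overlap),
                file.path(outdir, "imr_dmr_overlap.tsv"))
    }
  }

  files <- sort(list.files(outdir))
  manifest <- list(
    config = config,
    counts = counts,
    files = setNames(unname(tools::md5sum(file.path(outdir, files))), files),
    timing = timing,
    results = results
  )
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("dmrscape run manifest\nstage record counts:\n")
  print(x$counts)
  cat(sprintf("%d output file(s) under %s\n", length(x$files), x$config$outdir))
  invisible(x)
}

dmr_table_with_coords <- function(dmr_table, regions) {
  m <- match(dmr_table$region_id, regions$region_id)
  cbind(dmr_table[, "region_id", drop = FALSE],
        regions[m, c("chrom", "start", "end")],
        dmr_table[, setdiff(names(dmr_table), "region_id")])
}
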