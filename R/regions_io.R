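#' @importFrom stats complete.cases cor kmeans median p.adjust pbinom prcomp
#'   pt quantile rbinom rgamma rnbinom rnorm runif sd setNames t.test
#'   fisher.test wilcox.test dbinom dhyper cor.test rpois
#' @importFrom utils read.delim write.table head
NULL

REGION_KINDS <- c("promoter", "enhancer", "super_enhancer", "pmd")

#' Normalize chromosome names to the "chr"-prefixed dialect
#'
#' "1" and "chr1" refer to the same chromosome in common annotation files;
#' all ingest paths funnel through this so overlap arithmetic never compares
#' mixed dialects.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector with a "chr" prefix.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Construct a region set
#'
#' A region set is the unit at which differential methylation is called: a
#' data frame of 0-based half-open genomic intervals of a single kind
#' (promoter, enhancer, super-enhancer or partially methylated domain) with
#' unique identifiers.
#'
#' @param chrom,start,end interval coordinates (0-based, half-open).
#' @param region_id unique identifiers; auto-generated as
#'   `<kind>_<chrom>_<start>_<end>` when `NULL`.
#' @param kind one of `"promoter"`, `"enhancer"`, `"super_enhancer"`, `"pmd"`.
#' @param strand optional strand (`"+"`, `"-"`, `"."`); carried but ignored
#'   by all overlap operations.
#' @return data frame of class `region_set` with columns chrom, start, end,
#'   region_id, kind, strand.
#' @export
region_set <- function(chrom, start, end, region_id = NULL,
                       kind = c("promoter", "enhancer", "super_enhancer", "pmd"),
                       strand = NULL) {
  kind <- match.arg(kind)
  chrom <- normalize_chrom(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-integer region coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval (start >= end) at row %d", bad[1]))
  }
  if (is.null(region_id)) {
    region_id <- sprintf("%s_%s_%d_%d", kind, chrom, start, end)
  }
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id)) {
    stop("region_id values must be unique within a region set")
  }
  if (is.null(strand)) strand <- rep(".", length(chrom))
  df <- data.frame(
    chrom = chrom, start = start, end = end,
    region_id = region_id, kind = kind, strand = strand,
    stringsAsFactors = FALSE
  )
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set of %d %s interval(s)\n", nrow(x), x$kind[1]))
  print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

as_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    # BED half-open [start, end) -> IRanges closed 1-based [start+1, end]
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Read a BED file into a region set
#'
#' Accepts 3+ column BED (0-based, half-open); the optional 4th column is
#' used as the region identifier.
#'
#' @param path BED file path.
#' @param kind region kind for the whole file.
#' @return a [region_set()].
#' @export
read_regions <- function(path, kind = c("promoter", "enhancer", "super_enhancer", "pmd")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(region_set(character(), integer(), integer(), kind = kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("malformed BED row at line %d: fewer than 3 columns",
                 which(ncol < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED row at line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("malformed BED row at line %d: start >= end", bad[1]))
  }
  region_id <- if (all(ncol >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  region_set(chrom, start, end, region_id = region_id, kind = kind)
}

#' Write a region set as BED
#'
#' Rows are emitted sorted by (chrom, start) so output is deterministic.
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  ord <- order(regions$chrom, regions$start, regions$end, regions$region_id)
  df <- regions[ord, c("chrom", "start", "end", "region_id"), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CpG site manifest
#'
#' @param path TSV with header columns site_id, chrom, pos (0-based).
#' @return data frame with site_id, chrom, pos.
#' @export
read_cpg_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "chrom", "pos") %in% names(df)))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in CpG manifest")
  if (any(df$pos < 0)) stop("negative CpG position")
  df$chrom <- normalize_chrom(df$chrom)
  df[, c("site_id", "chrom", "pos")]
}

#' Assign CpG sites to regions by containment
#'
#' Half-open containment (`start <= pos < end`). A site overlapping several
#' regions (e.g. a promoter and an enhancer) is assigned to all of them.
#'
#' @param cpgs data frame with site_id, chrom, pos (0-based).
#' @param regions a [region_set()].
#' @return named list mapping region_id to a character vector of site_ids;
#'   regions without any site map to `character(0)` and are listed in the
#'   `"untestable"` attribute.
#' @export
assign_cpgs_to_regions <- function(cpgs, regions) {
  out <- setNames(vector("list", nrow(regions)), regions$region_id)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (nrow(cpgs) && nrow(regions)) {
    sites <- GenomicRanges::GRanges(
      seqnames = normalize_chrom(cpgs$chrom),
      ranges = IRanges::IRanges(start = cpgs$pos + 1L, width = 1L)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(sites, as_granges(regions)))
    if (length(hits)) {
      sp <- split(cpgs$site_id[S4Vectors::queryHits(hits)],
                  regions$region_id[S4Vectors::subjectHits(hits)])
      out[names(sp)] <- sp
    }
  }
  attr(out, "untestable") <- names(out)[lengths(out) == 0]
  out
}

#' Read an enhancer-promoter interaction (EPI) map
#'
#' Keeps links with PET-count support of at least `min_pet` (the stringent
#' filtration used for chromatin-interaction-derived maps); duplicate
#' (enhancer, gene) pairs are collapsed keeping the maximum PET count.
#'
#' @param path TSV with header columns enhancer_id, gene_id, pet_count.
#' @param min_pet minimum PET count retained (default 5).
#' @return data frame with enhancer_id, gene_id, pet_count.
#' @export
read_epi_map <- function(path, min_pet = 5) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("enhancer_id", "gene_id", "pet_count") %in% names(df)))
  filter_epi_links(df, min_pet = min_pet)
}

#' Filter and deduplicate EPI links
#'
#' @param links data frame with enhancer_id, gene_id, pet_count.
#' @inheritParams read_epi_map
#' @return filtered data frame, deterministic order.
#' @export
filter_epi_links <- function(links, min_pet = 5) {
  if (any(links$pet_count < 0)) stop("pet_count must be non-negative")
  links <- links[links$pet_count >= min_pet, , drop = FALSE]
  if (nrow(links)) {
    key <- paste(links$enhancer_id, links$gene_id, sep = "\r")
    mx <- tapply(links$pet_count, key, max)
    first <- !duplicated(key)
    links <- links[first, , drop = FALSE]
    links$pet_count <- as.integer(mx[paste(links$enhancer_id, links$gene_id, sep = "\r")])
    links <- links[order(links$enhancer_id, links$gene_id), , drop = FALSE]
  }
  rownames(links) <- NULL
  links[, c("enhancer_id", "gene_id", "pet_count")]
}

#' Read a risk-SNP table
#'
#' Positions on disk are 1-based (the convention of GWAS-catalog style
#' tables) and converted to the internal 0-based convention on ingest.
#'
#' @param path TSV with header columns rsid, chrom, pos (1-based).
#' @return data frame with rsid, chrom, pos (0-based).
#' @export
read_snps <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "chrom", "pos") %in% names(df)))
  if (anyDuplicated(df$rsid)) stop("duplicate rsid in SNP table")
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos) - 1L
  df[, c("rsid", "chrom", "pos")]
}

#' Map SNPs to regions within a flanking window
#'
#' A SNP hits a region iff its (0-based) position falls in
#' `[start - window_bp, end + window_bp)`; the window is symmetric on both
#' flanks and measured from the region edges. `window_bp = 0` reduces to
#' plain containment.
#'
#' @param snps data frame with rsid, chrom, pos (0-based).
#' @param regions a [region_set()].
#' @param window_bp flank width in bp (default 5000).
#' @return named list mapping rsid to character vector of overlapped
#'   region_ids (possibly empty).
#' @export
within_window <- function(snps, regions, window_bp = 5000) {
  stopifnot(window_bp >= 0)
  out <- setNames(vector("list", nrow(snps)), snps$rsid)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (nrow(snps) && nrow(regions)) {
    gr_snp <- GenomicRanges::GRanges(
      seqnames = normalize_chrom(snps$chrom),
      ranges = IRanges::IRanges(start = snps$pos + 1L, width = 1L)
    )
    flank_start <- pmax(regions$start - window_bp, 0L)
    gr_reg <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = flank_start + 1L,
                                end = regions$end + window_bp)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_snp, gr_reg))
    if (length(hits)) {
      sp <- split(regions$region_id[S4Vectors::subjectHits(hits)],
                  snps$rsid[S4Vectors::queryHits(hits)])
      out[names(sp)] <- sp
    }
  }
  out
}

#' Overlap two region sets
#'
#' Any-overlap test between half-open intervals; strand is ignored.
#'
#' @param query,subject [region_set()]s.
#' @return data frame with query_id, subject_id, one row per overlapping pair.
#' @export
overlap_regions <- function(query, subject) {
  if (!nrow(query) || !nrow(subject)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(as_granges(query), as_granges(subject)))
  data.frame(
    query_id = query$region_id[S4Vectors::queryHits(hits)],
    subject_id = subject$region_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}
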