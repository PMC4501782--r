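#' Run the full altitudinal selection scan on one transect
#'
#' Orchestrates the stages in order: (optional) locus filters, per-locus
#' statistics with windowed means, Tukey-fence screening, SNP-gene linkage,
#' island segmentation and ranking, candidate-gene assignment, and (when a
#' GO map is given) SNP- and gene-based GO enrichment. The run is
#' deterministic: identical inputs and parameters give identical outputs.
#'
#' @param geno A [genotype_table()].
#' @param design A transect design (see [read_population_map()]).
#' @param exons Exon annotation (see [read_exon_bed()]).
#' @param go_map Optional gene-to-GO map (see [read_go_map()]).
#' @param half_width Window half-width in bp (default 2000).
#' @param fence_multiplier IQR multiplier for the screening fences (1.5).
#' @param gap Island termination gap in bp (4000).
#' @param min_screened Minimum screened SNPs per ranked island (2).
#' @param max_dist SNP-gene linkage distance in bp (5000).
#' @param top_n Top-island report size (20).
#' @param go_terms GO ids to test (default: all in `go_map`).
#' @param apply_filters Run [filter_loci()] first (default `FALSE`; the
#'   filters need depths).
#' @param u_method U-index reading, see [u_index()].
#' @param out_dir Optional directory: results are additionally written as
#'   TSV tables with a provenance header.
#' @return A list of class `scan_result`: `stats`, `screen`, `links`,
#'   `islands`, `islands_ranked`, `top_genes`, `enrichment` (or `NULL`),
#'   `filter` (or `NULL`), `params`.
#' @export
run_scan <- function(geno, design, exons, go_map = NULL,
                     half_width = 2000, fence_multiplier = 1.5,
                     gap = 4000, min_screened = 2, max_dist = 5000,
                     top_n = 20, go_terms = NULL, apply_filters = FALSE,
                     u_method = "consistent", out_dir = NULL) {
  stopifnot(inherits(geno, "genotype_table"))
  orphans <- setdiff(design$sample_id, geno$samples)
  if (length(orphans)) {
    abort(paste0("samples in design absent from genotypes: ",
                 paste(orphans, collapse = ", ")))
  }
  params <- list(half_width = half_width,
                 fence_multiplier = fence_multiplier, gap = gap,
                 min_screened = min_screened, max_dist = max_dist,
                 top_n = top_n, apply_filters = apply_filters,
                 u_method = u_method)
  flt <- NULL
  if (apply_filters) {
    flt <- run_stage("filter", filter_loci(geno))
    geno <- flt$genotypes
  }
  stats <- run_stage("stats", locus_stats(geno, design,
                                          half_width = half_width,
                                          u_method = u_method))
  screen <- run_stage("screen", screen_loci(stats,
                                            multiplier = fence_multiplier))
  links <- run_stage("link", link_snps_to_genes(stats, exons,
                                                max_dist = max_dist))
  islands <- run_stage("islands", segment_islands(stats, gap = gap))
  ranked <- run_stage("rank", rank_islands(islands, screen,
                                           min_screened = min_screened))
  ranked <- island_candidate_genes(ranked, screen, links)
  top_genes <- top_island_genes(ranked, top_n = top_n)
  enrich <- NULL
  if (!is.null(go_map)) {
    enrich <- run_stage("enrich", bind_rows(
      go_enrichment(screen, links, go_map, terms = go_terms, mode = "snp"),
      go_enrichment(screen, links, go_map, terms = go_terms, mode = "gene")
    ))
  }
  res <- structure(
    list(stats = stats, screen = screen, links = links, islands = islands,
         islands_ranked = ranked, top_genes = top_genes,
         enrichment = enrich, filter = flt, params = params),
    class = "scan_result"
  )
  if (!is.null(out_dir)) write_scan_result(res, out_dir)
  res
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Write a scan result as TSV tables
#'
#' @param res A [run_scan()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_scan_result <- function(res, out_dir) {
  stopifnot(inherits(res, "scan_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(
    paste0("altiscan ", as.character(utils::packageVersion("altiscan"))),
    paste0("params: ", paste(names(res$params), unlist(res$params),
                             sep = "=", collapse = " "))
  )
  drop_lists <- function(x) x[!vapply(x, is.list, logical(1))]
  tables <- list(
    locus_stats = as_tibble(res$stats),
    screened = filter(as_tibble(res$screen), .data$screened),
    snp_gene_links = res$links,
    islands = drop_lists(as_tibble(res$islands_ranked)),
    top_genes = res$top_genes
  )
  if (!is.null(res$enrichment)) tables$enrichment <- res$enrichment
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_scan_table(tables[[nm]], p, header = prov)
    paths <- c(paths, p)
  }
  thr <- attr(res$screen, "thresholds")
  p <- file.path(out_dir, "thresholds.tsv")
  write_scan_table(thr, p, header = prov)
  invisible(c(paths, p))
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>\n")
  cat("  loci:           ", nrow(x$stats), "\n", sep = "")
  cat("  screened SNPs:  ", sum(x$screen$screened), "\n", sep = "")
  cat("  islands:        ", nrow(x$islands), " (",
      nrow(x$islands_ranked), " ranked)\n", sep = "")
  cat("  candidate genes:", length(unique(unlist(
    x$islands_ranked$candidate_genes))), "\n")
  invisible(x)
}

#' Shared candidate genes between two transects
#'
#' Intersects the top-N candidate-gene lists of two scans and, when a
#' universe size is given, attaches the Monte-Carlo empirical p-value for
#' an overlap at least that large ([shared_gene_pvalue()]).
#'
#' @param res1,res2 [run_scan()] results.
#' @param n_universe Optional gene-universe size for the p-value.
#' @param trials,seed Passed to [shared_gene_pvalue()].
#' @return A list of class `transect_overlap`: `shared` (character),
#'   `n1`, `n2`, and `test` (tibble or `NULL`).
#' @export
shared_candidate_genes <- function(res1, res2, n_universe = NULL,
                                   trials = 1e6, seed = NULL) {
  g1 <- sort(unique(stats::na.omit(res1$top_genes$gene_id)))
  g2 <- sort(unique(stats::na.omit(res2$top_genes$gene_id)))
  shared <- intersect(g1, g2)
  test <- NULL
  if (!is.null(n_universe)) {
    test <- shared_gene_pvalue(n_universe, length(g1), length(g2),
                               length(shared), trials = trials, seed = seed)
  }
  structure(list(shared = shared, n1 = length(g1), n2 = length(g2),
                 test = test), class = "transect_overlap")
}

#' @export
print.transect_overlap <- function(x, ...) {
  cat("<transect_overlap> ", length(x$shared), " shared of ", x$n1, " / ",
      x$n2, " candidate genes\n", sep = "")
  if (length(x$shared)) cat("  ", paste(x$shared, collapse = ", "), "\n")
  if (!is.null(x$test)) {
    cat("  empirical p = ", signif(x$test$p_hat, 3),
        " (exact ", signif(x$test$p_exact, 3), ")\n", sep = "")
  }
  invisible(x)
}
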