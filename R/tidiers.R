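#' Tidy a scan result
#'
#' @param x A [run_scan()] result.
#' @param ... Unused.
#' @return The per-locus screening table as a plain tibble.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  as_tibble(x$screen)
}

#' One-row summary of a scan result
#'
#' @param x A [run_scan()] result.
#' @param ... Unused.
#' @return A one-row tibble: locus, screened, linked, island, ranked-island
#'   and candidate-gene counts.
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble(
    n_loci = nrow(x$stats),
    n_screened = sum(x$screen$screened),
    n_linked_snps = dplyr::n_distinct(paste(x$links$scaffold,
                                            x$links$position)),
    n_tagged_genes = dplyr::n_distinct(x$links$gene_id),
    n_islands = nrow(x$islands),
    n_ranked_islands = nrow(x$islands_ranked),
    n_candidate_genes = length(unique(unlist(
      x$islands_ranked$candidate_genes)))
  )
}

#' Tidy a diversity summary
#'
#' @param x A [diversity_summary()] result.
#' @param ... Unused.
#' @return The per-deme summary tibble.
#' @method tidy diversity_summary
#' @export
tidy.diversity_summary <- function(x, ...) x$demes

#' One-row overview of a diversity summary
#'
#' @param x A [diversity_summary()] result.
#' @param ... Unused.
#' @return A one-row tibble with deme count and grand means.
#' @method glance diversity_summary
#' @export
glance.diversity_summary <- function(x, ...) {
  tibble(n_demes = nrow(x$demes), mean_he = mean(x$demes$he),
         mean_ho = mean(x$demes$ho),
         n_significant_pairs = sum(x$tests$p_bonferroni < 0.01,
                                   na.rm = TRUE))
}

#' Tidy a transect overlap
#'
#' @param x A [shared_candidate_genes()] result.
#' @param ... Unused.
#' @return One row per shared gene (empty tibble when none).
#' @method tidy transect_overlap
#' @export
tidy.transect_overlap <- function(x, ...) {
  tibble(gene_id = x$shared)
}

#' One-row summary of a transect overlap
#'
#' @param x A [shared_candidate_genes()] result.
#' @param ... Unused.
#' @return A one-row tibble with list sizes, overlap and p-values (NA when
#'   no universe was given).
#' @method glance transect_overlap
#' @export
glance.transect_overlap <- function(x, ...) {
  tibble(n1 = x$n1, n2 = x$n2, n_shared = length(x$shared),
         p_hat = if (is.null(x$test)) NA_real_ else x$test$p_hat,
         p_exact = if (is.null(x$test)) NA_real_ else x$test$p_exact)
}
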