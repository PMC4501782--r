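#' One-tailed Fisher exact p-value of a 2x2 table
#'
#' Hypergeometric upper tail `P(X >= a)` with margins fixed, i.e. the
#' enrichment direction of the classical one-tailed Fisher test for the
#' table `rbind(c(a, b), c(c, d))`. Vectorized.
#'
#' @param a,b,c,d Non-negative integer counts (a = screened-and-term,
#'   b = screened-without-term, c = unscreened-and-term, d = neither).
#' @return P(X >= a).
#' @export
fisher_one_tailed_2x2 <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values (monotone, capped at 1), in the input order.
#' Thin, named wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
fdr_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' GO-term enrichment of the screened set
#'
#' Tests each requested GO term for over-representation among screened
#' units with a one-tailed Fisher test on the disjoint 2x2 table
#' (screened vs not-screened x term vs no-term), BH q-values across the
#' requested terms, and fold enrichment = screened term fraction divided by
#' the background (all units) term fraction.
#'
#' Only gene-linked SNPs participate. In `snp` mode the units are
#' gene-linked SNPs and a SNP carries a term if any linked gene does; in
#' `gene` mode the units are SNP-tagged genes and a gene is screened if at
#' least one screened SNP links to it.
#'
#' @param screen A [screen_loci()] result.
#' @param links A [link_snps_to_genes()] result.
#' @param go_map Gene-to-GO tibble (see [read_go_map()]).
#' @param terms GO ids to test (default: all terms in `go_map`). Terms
#'   absent from the annotation get zero counts and p = 1.
#' @param mode `"snp"` or `"gene"`.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @return A tibble of class `go_enrichment`: `go_id`, `go_name`, `mode`,
#'   the 2x2 counts `n_screened_term`, `n_screened_noterm`,
#'   `n_unscreened_term`, `n_unscreened_noterm`, `fold_enrichment`,
#'   `p_value`, `q_value`, `significant`.
#' @export
go_enrichment <- function(screen, links, go_map, terms = NULL,
                          mode = c("snp", "gene"), q_threshold = 0.05) {
  mode <- match.arg(mode)
  if (is.null(terms)) terms <- sort(unique(go_map$go_id))
  scr <- as_tibble(screen)[c("scaffold", "position", "screened")]

  if (mode == "snp") {
    units <- distinct(links[c("scaffold", "position")])
    units <- inner_join(units, scr, by = c("scaffold", "position"))
    unit_key <- paste(units$scaffold, units$position)
    screened <- units$screened
    unit_terms <- distinct(
      inner_join(links, go_map, by = "gene_id",
                 relationship = "many-to-many"),
      .data$scaffold, .data$position, .data$go_id
    )
    term_key <- paste(unit_terms$scaffold, unit_terms$position)
    term_of <- split(unit_terms$go_id, term_key)
  } else {
    scr_pos <- filter(scr, .data$screened)
    genes <- distinct(links["gene_id"])
    scr_genes <- unique(inner_join(
      links, scr_pos[c("scaffold", "position")],
      by = c("scaffold", "position"))$gene_id)
    unit_key <- genes$gene_id
    screened <- genes$gene_id %in% scr_genes
    gm <- distinct(go_map[c("gene_id", "go_id")])
    gm <- filter(gm, .data$gene_id %in% unit_key)
    term_of <- split(gm$go_id, gm$gene_id)
  }

  n_units <- length(unit_key)
  n_scr <- sum(screened)
  names_tbl <- distinct(go_map[c("go_id", "go_name")])
  has <- matrix(FALSE, n_units, length(terms),
                dimnames = list(NULL, terms))
  tlist <- term_of[unit_key]
  for (j in seq_along(terms)) {
    has[, j] <- map_lgl_in(tlist, terms[j])
  }
  a <- unname(colSums(has & screened))
  ct <- unname(colSums(has))
  b <- n_scr - a
  c_ <- ct - a
  d <- (n_units - n_scr) - c_
  p <- fisher_one_tailed_2x2(a, b, c_, d)
  fold <- ifelse(ct > 0 & n_scr > 0, (a / n_scr) / (ct / n_units), NA_real_)
  out <- tibble(
    go_id = terms,
    go_name = names_tbl$go_name[match(terms, names_tbl$go_id)],
    mode = paste0(mode, "_based"),
    n_screened_term = as.integer(a),
    n_screened_noterm = as.integer(b),
    n_unscreened_term = as.integer(c_),
    n_unscreened_noterm = as.integer(d),
    fold_enrichment = fold,
    p_value = p,
    q_value = fdr_qvalues(p)
  )
  out <- mutate(out, significant = .data$q_value < q_threshold)
  class(out) <- c("go_enrichment", class(out))
  out
}

map_lgl_in <- function(tlist, term) {
  vapply(tlist, function(x) !is.null(x) && term %in% x, logical(1),
         USE.NAMES = FALSE)
}
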