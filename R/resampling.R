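#' Monte-Carlo p-value for shared genes between two candidate lists
#'
#' Draws two gene lists of sizes `n1` and `n2` uniformly without
#' replacement from a universe of `n_universe` genes, `trials` times, and
#' reports the fraction of trials sharing at least `observed` genes — the
#' empirical p-value for the observed overlap between two transects'
#' candidate lists. The exact hypergeometric tail
#' `P(overlap >= observed)` is computed alongside (the overlap of two
#' independent uniform draws is hypergeometric), as is the Monte-Carlo
#' standard error.
#'
#' @param n_universe Universe size N (e.g. all SNP-tagged genes).
#' @param n1,n2 List sizes.
#' @param observed Observed overlap k.
#' @param trials Number of trials (default 1e6).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `p_hat`, `se`, `p_exact`, `observed`,
#'   `trials`, `n_universe`, `n1`, `n2`.
#' @export
shared_gene_pvalue <- function(n_universe, n1, n2, observed,
                               trials = 1e6, seed = NULL) {
  stopifnot(n1 <= n_universe, n2 <= n_universe, trials >= 1)
  if (observed > min(n1, n2)) {
    abort("observed overlap cannot exceed the smaller list size")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(observed)
  hits <- 0L
  for (i in seq_len(trials)) {
    x <- sample.int(n_universe, n1)
    y <- sample.int(n_universe, n2)
    if (sum(match(y, x, 0L) > 0L) >= k) hits <- hits + 1L
  }
  p_hat <- hits / trials
  p_exact <- if (k <= 0L) 1 else {
    phyper(k - 1, n1, n_universe - n1, n2, lower.tail = FALSE)
  }
  tibble(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / trials),
         p_exact = p_exact, observed = k, trials = as.integer(trials),
         n_universe = as.integer(n_universe), n1 = as.integer(n1),
         n2 = as.integer(n2))
}

#' Monte-Carlo p-value for jointly GO-tagged counts in two lists
#'
#' With `n_tagged` of the `n_universe` genes carrying a GO term, draws two
#' independent lists of sizes `n1` and `n2` and reports the fraction of
#' trials in which list 1 contains at least `k1` tagged genes and list 2 at
#' least `k2`. The exact value is the product of the two hypergeometric
#' upper tails (the draws are independent).
#'
#' @param n_universe Universe size N.
#' @param n_tagged Number of tagged genes m in the universe.
#' @param n1,n2 List sizes.
#' @param k1,k2 Observed tagged counts in the two lists.
#' @param trials Number of trials (default 1e6).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `p_hat`, `se`, `p_exact`, `k1`, `k2`,
#'   `trials`, `n_universe`, `n_tagged`, `n1`, `n2`.
#' @export
go_count_pvalue <- function(n_universe, n_tagged, n1, n2, k1, k2,
                            trials = 1e6, seed = NULL) {
  stopifnot(n1 <= n_universe, n2 <= n_universe, trials >= 1,
            k1 <= n1, k2 <= n2)
  if (n_tagged > n_universe) {
    abort("n_tagged cannot exceed the universe size")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(n_tagged)
  hits <- 0L
  for (i in seq_len(trials)) {
    c1 <- sum(sample.int(n_universe, n1) <= m)
    if (c1 < k1) next
    c2 <- sum(sample.int(n_universe, n2) <= m)
    if (c2 >= k2) hits <- hits + 1L
  }
  p_hat <- hits / trials
  tail1 <- if (k1 <= 0) 1 else {
    phyper(k1 - 1, m, n_universe - m, n1, lower.tail = FALSE)
  }
  tail2 <- if (k2 <= 0) 1 else {
    phyper(k2 - 1, m, n_universe - m, n2, lower.tail = FALSE)
  }
  tibble(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / trials),
         p_exact = tail1 * tail2, k1 = as.integer(k1), k2 = as.integer(k2),
         trials = as.integer(trials), n_universe = as.integer(n_universe),
         n_tagged = m, n1 = as.integer(n1), n2 = as.integer(n2))
}
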