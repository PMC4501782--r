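#' Per-deme diversity summaries
#'
#' For each deme: P, the proportion of loci with at least two observed
#' alleles in that deme; He, the mean expected heterozygosity
#' `1 - sum(p_i^2)`; and Ho, the mean fraction of heterozygous individuals.
#' Per-locus He vectors of the four altitude demes are compared pairwise
#' with two-sided Wilcoxon signed-rank tests, Bonferroni-corrected over the
#' six pairs.
#'
#' @param geno A [genotype_table()].
#' @param design A transect design.
#' @return A list of class `diversity_summary`: `demes` (tibble with
#'   `deme`, `role`, `n`, `p_poly`, `he`, `ho`) and `tests` (tibble with
#'   `deme_a`, `deme_b`, `p_value`, `p_bonferroni`).
#' @export
diversity_summary <- function(geno, design) {
  stopifnot(inherits(geno, "genotype_table"))
  demes <- distinct(design, .data$deme, .data$role)
  he_mat <- list()
  rows <- purrr::map_dfr(seq_len(nrow(demes)), function(i) {
    d <- demes$deme[i]
    cols <- match(design$sample_id[design$deme == d], geno$samples)
    if (length(cols) < 2L) {
      abort(paste0("deme ", d, " has fewer than 2 samples"))
    }
    ac <- count_alleles(geno, cols)
    freq <- ac$counts / ifelse(ac$chrom > 0, ac$chrom, NA_real_)
    he <- 1 - rowSums(freq^2)
    he_mat[[d]] <<- he
    het <- rowSums(geno$a1[, cols, drop = FALSE] !=
                     geno$a2[, cols, drop = FALSE], na.rm = TRUE)
    called <- rowSums(!is.na(geno$a1[, cols, drop = FALSE]))
    tibble(
      deme = d, role = demes$role[i], n = length(cols),
      p_poly = mean(rowSums(ac$counts > 0) >= 2, na.rm = TRUE),
      he = mean(he, na.rm = TRUE),
      ho = mean(het / ifelse(called > 0, called, NA_real_), na.rm = TRUE)
    )
  })
  alt <- demes$deme[match(c("lowest", "lower_middle", "higher_middle",
                            "highest"), demes$role)]
  pairs <- utils::combn(alt, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p <- tryCatch(
      wilcox.test(he_mat[[a]], he_mat[[b]], paired = TRUE,
                  alternative = "two.sided", exact = FALSE)$p.value,
      error = function(e) NA_real_
    )
    tibble(deme_a = a, deme_b = b, p_value = p)
  })
  tests$p_bonferroni <- pmin(1, tests$p_value * nrow(tests))
  structure(list(demes = rows, tests = tests), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("<diversity_summary>\n")
  print(x$demes)
  invisible(x)
}

#' Multilocus pairwise G'ST matrix
#'
#' Multilocus G'ST between every pair of demes, aggregating `H_S` and `H_T`
#' across loci before forming `G_ST` and applying Hedrick's k = 2
#' standardization (the standard multilocus construction, not a mean of
#' per-locus values).
#'
#' @param geno A [genotype_table()].
#' @param design A transect design.
#' @return A long tibble: `deme_a`, `deme_b`, `gst_prime` (one row per
#'   unordered pair, both orders included, zero diagonal omitted).
#' @export
multilocus_gst_matrix <- function(geno, design) {
  stopifnot(inherits(geno, "genotype_table"))
  demes <- unique(design$deme)
  freqs <- lapply(demes, function(d) {
    freq_matrix(geno, match(design$sample_id[design$deme == d],
                            geno$samples), what = d)
  })
  names(freqs) <- demes
  pairs <- utils::combn(demes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    p <- freqs[[pairs[1, j]]]; q <- freqs[[pairs[2, j]]]
    hs <- mean(((1 - rowSums(p^2)) + (1 - rowSums(q^2))) / 2)
    ht <- mean(1 - rowSums(((p + q) / 2)^2))
    g <- if (ht <= 0 || hs >= 1) 0 else (ht - hs) / ht * (1 + hs) / (1 - hs)
    tibble(deme_a = pairs[1, j], deme_b = pairs[2, j], gst_prime = g)
  })
}
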