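#' Post-call locus filters
#'
#' Applies the standard SNP cleaning rules to a depth-annotated genotype
#' table, in a fixed order with the first failing rule recorded per dropped
#' locus:
#' \enumerate{
#'   \item `min_depth`: every sample must have at least
#'     `min_reads_per_individual` reads at the locus;
#'   \item `max_total`: the summed depth over samples must not exceed
#'     `max_total_read_count` (repeat-region guard);
#'   \item `min_minor_frac`: the locus-wide frequency of the
#'     second-most-frequent ("antagonistic") allele over called chromosomes
#'     must exceed `min_antagonistic_fraction`.
#' }
#'
#' @param geno A [genotype_table()] with depths (required unless both depth
#'   thresholds are 0).
#' @param min_reads_per_individual Minimum per-sample depth (default 5).
#' @param min_antagonistic_fraction Minimum second-allele frequency
#'   (default 0.20, strict inequality).
#' @param max_total_read_count Maximum summed depth (default 10000).
#' @return A list of class `locus_filter`: `genotypes` (filtered table) and
#'   `rejected` (tibble `scaffold`, `position`, `reason`).
#' @export
filter_loci <- function(geno,
                        min_reads_per_individual = 5,
                        min_antagonistic_fraction = 0.20,
                        max_total_read_count = 10000) {
  stopifnot(inherits(geno, "genotype_table"),
            min_reads_per_individual >= 0, max_total_read_count >= 0,
            min_antagonistic_fraction >= 0, min_antagonistic_fraction <= 1)
  need_depth <- min_reads_per_individual > 0 || max_total_read_count > 0
  if (need_depth && is.null(geno$depth)) {
    abort(paste0("genotype table has no read depths; set ",
                 "min_reads_per_individual = 0 and max_total_read_count = 0 ",
                 "to disable the depth filters"))
  }
  n <- nrow(geno$loci)
  fail_min <- fail_tot <- rep(FALSE, n)
  if (!is.null(geno$depth)) {
    if (min_reads_per_individual > 0) {
      fail_min <- rowSums(geno$depth < min_reads_per_individual |
                            is.na(geno$depth)) > 0
    }
    if (max_total_read_count > 0) {
      fail_tot <- rowSums(geno$depth, na.rm = TRUE) > max_total_read_count
    }
  }
  ac <- count_alleles(geno, seq_along(geno$samples))
  second <- apply(ac$counts, 1, function(x) sort(x, decreasing = TRUE)[2])
  frac2 <- second / ifelse(ac$chrom > 0, ac$chrom, NA_real_)
  fail_frac <- if (min_antagonistic_fraction > 0) {
    !(frac2 > min_antagonistic_fraction) | is.na(frac2)
  } else {
    rep(FALSE, n)
  }
  reason <- rep(NA_character_, n)
  reason[fail_frac] <- "min_minor_frac"
  reason[fail_tot] <- "max_total"
  reason[fail_min] <- "min_depth"   # first-failing wins, order a -> b -> c
  keep <- is.na(reason)
  structure(list(
    genotypes = subset_loci(geno, keep),
    rejected = tibble(scaffold = geno$loci$scaffold[!keep],
                      position = geno$loci$position[!keep],
                      reason = reason[!keep])
  ), class = "locus_filter")
}

#' @export
print.locus_filter <- function(x, ...) {
  cat("<locus_filter> kept ", nrow(x$genotypes$loci), " loci, dropped ",
      nrow(x$rejected), "\n", sep = "")
  if (nrow(x$rejected)) print(count(x$rejected, .data$reason))
  invisible(x)
}
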