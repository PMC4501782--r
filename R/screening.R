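#' Tukey upper fence of a genome-wide statistic
#'
#' `Q3 + multiplier * (Q3 - Q1)` with quartiles by linear interpolation
#' (type-7, the R default) — the screening threshold applied to each
#' windowed index's genome-wide distribution.
#'
#' @param values Numeric vector (at least 4 finite values).
#' @param multiplier IQR multiplier (default 1.5).
#' @return The fence value.
#' @export
upper_fence <- function(values, multiplier = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) abort("at least 4 finite values required")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + multiplier * (q[2] - q[1])
}

#' Screen loci on the three windowed criteria
#'
#' Flags each SNP on whether its windowed U, windowed G'ST and windowed
#' delta-D' exceed the Tukey upper fence of the respective genome-wide
#' distribution; `screened` is the intersection of the three (only SNPs
#' fulfilling all three criteria go forward).
#'
#' @param stats A [locus_stats()] tibble.
#' @param multiplier Fence multiplier (default 1.5).
#' @param strict Use strict `>` at the fence (default); `FALSE` uses `>=`.
#' @return The input tibble with logical columns `pass_u`, `pass_gst`,
#'   `pass_delta_d`, `screened`, of class `scan_screen`; the fences are in
#'   `attr(, "thresholds")`.
#' @export
screen_loci <- function(stats, multiplier = 1.5, strict = TRUE) {
  need <- c("u_bar", "gst_bar", "delta_d_bar")
  stopifnot(all(need %in% names(stats)))
  if (nrow(stats) == 0L) {
    out <- mutate(stats, pass_u = logical(0), pass_gst = logical(0),
                  pass_delta_d = logical(0), screened = logical(0))
    attr(out, "thresholds") <- tibble(index = need, fence = numeric(3))
    class(out) <- c("scan_screen", class(stats))
    return(out)
  }
  fences <- vapply(need, function(cl) upper_fence(stats[[cl]], multiplier),
                   numeric(1))
  cmp <- if (strict) `>` else `>=`
  out <- mutate(stats,
                pass_u = cmp(.data$u_bar, fences[["u_bar"]]),
                pass_gst = cmp(.data$gst_bar, fences[["gst_bar"]]),
                pass_delta_d = cmp(.data$delta_d_bar,
                                   fences[["delta_d_bar"]]),
                screened = .data$pass_u & .data$pass_gst & .data$pass_delta_d)
  attr(out, "thresholds") <- tibble(index = need, fence = unname(fences),
                                    multiplier = multiplier)
  if (!inherits(out, "scan_screen")) {
    class(out) <- c("scan_screen", class(out))
  }
  out
}

#' Venn decomposition of the three criterion sets
#'
#' @param screen A [screen_loci()] result.
#' @return A tibble with one row per region of the three-set Venn diagram
#'   (`u`, `gst`, `delta_d` flags, `n` loci).
#' @export
venn_counts <- function(screen) {
  stopifnot(all(c("pass_u", "pass_gst", "pass_delta_d") %in% names(screen)))
  out <- count(as_tibble(screen), u = .data$pass_u, gst = .data$pass_gst,
               delta_d = .data$pass_delta_d, name = "n")
  grid <- tidyr::expand_grid(u = c(FALSE, TRUE), gst = c(FALSE, TRUE),
                             delta_d = c(FALSE, TRUE))
  out <- left_join(grid, out, by = c("u", "gst", "delta_d"))
  mutate(out, n = dplyr::coalesce(.data$n, 0L))
}

#' Link SNPs to nearby genes
#'
#' A SNP is linked to a gene when it overlaps one of its exons or lies
#' within `max_dist` bp of an exon boundary (inclusive at exactly
#' `max_dist`). SNP positions are 1-based; exon intervals are 0-based
#' half-open BED intervals, converted here, once.
#'
#' @param loci Tibble with `scaffold` and `position` columns (1-based).
#' @param exons Exon annotation tibble (see [read_exon_bed()]).
#' @param max_dist Maximum SNP-to-exon gap in bp (default 5000).
#' @return A tibble `scaffold`, `position`, `gene_id` (distinct pairs; a
#'   SNP may link to several genes).
#' @export
link_snps_to_genes <- function(loci, exons, max_dist = 5000) {
  stopifnot(max_dist >= 0)
  loci <- distinct(as_tibble(loci)[c("scaffold", "position")])
  if (nrow(loci) == 0L || nrow(exons) == 0L) {
    return(tibble(scaffold = character(), position = integer(),
                  gene_id = character()))
  }
  lv <- unique(c(loci$scaffold, exons$scaffold))
  snp_gr <- GenomicRanges::GRanges(
    factor(loci$scaffold, levels = lv),
    IRanges::IRanges(loci$position, loci$position)
  )
  exon_gr <- GenomicRanges::GRanges(
    factor(exons$scaffold, levels = lv),
    IRanges::IRanges(exons$start + 1L, exons$end)  # BED -> 1-based closed
  )
  # findOverlaps counts the positions strictly between ranges as the gap,
  # while the linkage distance here is point-to-boundary (SNP at end + d has
  # distance d); maxgap = d - 1 makes "within max_dist" inclusive, and
  # max_dist = 0 degrades to pure overlap (maxgap = -1, the no-gap sentinel)
  hits <- GenomicRanges::findOverlaps(snp_gr, exon_gr,
                                      maxgap = as.integer(max_dist) - 1L)
  out <- tibble(
    scaffold = loci$scaffold[S4Vectors::queryHits(hits)],
    position = loci$position[S4Vectors::queryHits(hits)],
    gene_id = exons$gene_id[S4Vectors::subjectHits(hits)]
  )
  arrange(distinct(out), .data$scaffold, .data$position, .data$gene_id)
}
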