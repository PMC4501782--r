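#' Segment the windowed-U curve into genomic islands
#'
#' Consecutive SNPs on a scaffold no more than `gap` bp apart are connected
#' by straight lines; every maximal sub-curve with windowed U strictly
#' above zero is a hitchhiking region ("genomic island"). Island boundaries
#' sit at linearly interpolated x-intercepts, at scaffold (or gap-break)
#' ends — with no extrapolation beyond observed SNPs — and at SNPs whose
#' value is exactly 0 (boundary points, not members). An isolated positive
#' SNP cut off by gaps on both sides yields a degenerate island with
#' `start == end` and zero area.
#'
#' @param stats Tibble with `scaffold`, `position` and `u_bar`, sorted by
#'   (scaffold, position) — typically a [locus_stats()] result.
#' @param gap Maximum inter-SNP distance in bp before the curve (and any
#'   island) is broken (default 4000).
#' @return A tibble of class `genomic_islands`: `island_id`, `scaffold`,
#'   `start`, `end` (bp, possibly fractional), `area` (bp x U), `n_snps`
#'   and `members` (list column of member SNP positions).
#' @export
segment_islands <- function(stats, gap = 4000) {
  stopifnot(all(c("scaffold", "position", "u_bar") %in% names(stats)),
            gap > 0)
  if (is.unsorted(order(stats$scaffold, stats$position)) ||
      any(order(stats$scaffold, stats$position) != seq_len(nrow(stats)))) {
    abort("input must be sorted by (scaffold, position)")
  }
  if (any(!is.finite(stats$u_bar))) abort("u_bar must be finite")

  res <- list()
  for (s in unique(stats$scaffold)) {
    i <- which(stats$scaffold == s)
    p <- as.numeric(stats$position[i])
    v <- stats$u_bar[i]
    seg_break <- c(0L, which(diff(p) > gap), length(p))
    for (b in seq_len(length(seg_break) - 1L)) {
      idx <- (seg_break[b] + 1L):seg_break[b + 1L]
      res <- c(res, segment_one(p[idx], v[idx], s))
    }
  }
  out <- if (length(res)) bind_rows(res) else {
    tibble(scaffold = character(), start = numeric(), end = numeric(),
           area = numeric(), n_snps = integer(), members = list())
  }
  out <- arrange(out, .data$scaffold, .data$start)
  out <- mutate(out, island_id = row_number(), .before = 1)
  class(out) <- c("genomic_islands", class(out))
  out
}

# islands of one gap-free segment of the piecewise-linear curve
segment_one <- function(p, v, scaffold) {
  islands <- list()
  nodes_x <- numeric(0); nodes_y <- numeric(0); members <- numeric(0)
  close_island <- function() {
    if (!length(nodes_x)) return(invisible())
    area <- if (length(nodes_x) > 1L) {
      sum(diff(nodes_x) * (head(nodes_y, -1) + tail(nodes_y, -1)) / 2)
    } else 0
    islands[[length(islands) + 1L]] <<- tibble(
      scaffold = scaffold, start = nodes_x[1],
      end = nodes_x[length(nodes_x)], area = area,
      n_snps = length(members), members = list(members)
    )
    nodes_x <<- numeric(0); nodes_y <<- numeric(0); members <<- numeric(0)
  }
  for (j in seq_along(p)) {
    if (v[j] > 0) {
      if (!length(nodes_x)) {            # open island
        if (j > 1L && v[j - 1L] < 0) {   # interpolated x-intercept
          x0 <- p[j - 1L] + (p[j] - p[j - 1L]) * (-v[j - 1L]) /
            (v[j] - v[j - 1L])
          nodes_x <- x0; nodes_y <- 0
        } else if (j > 1L && v[j - 1L] == 0) {
          nodes_x <- p[j - 1L]; nodes_y <- 0
        }                                # else: segment edge, start at SNP
      }
      nodes_x <- c(nodes_x, p[j]); nodes_y <- c(nodes_y, v[j])
      members <- c(members, p[j])
    } else if (length(nodes_x)) {        # close island
      if (v[j] == 0) {
        nodes_x <- c(nodes_x, p[j]); nodes_y <- c(nodes_y, 0)
      } else {
        vm <- v[j - 1L]
        x0 <- p[j - 1L] + (p[j] - p[j - 1L]) * vm / (vm - v[j])
        nodes_x <- c(nodes_x, x0); nodes_y <- c(nodes_y, 0)
      }
      close_island()
    }
  }
  close_island()                         # segment end: no extrapolation
  islands
}

#' Rank genomic islands by area
#'
#' Drops islands containing fewer than `min_screened` screened SNPs (by
#' default at least two are required) and ranks the rest by area,
#' descending; ties break by (scaffold, start).
#'
#' @param islands A [segment_islands()] result.
#' @param screen A [screen_loci()] result (provides the `screened` flags).
#' @param min_screened Minimum screened member SNPs (default 2).
#' @return The filtered islands tibble with `n_screened` and `rank`
#'   columns, ordered by rank.
#' @export
rank_islands <- function(islands, screen, min_screened = 2) {
  stopifnot(all(c("scaffold", "position", "screened") %in% names(screen)))
  scr <- filter(as_tibble(screen), .data$screened)
  key <- paste(scr$scaffold, scr$position)
  out <- mutate(islands,
                n_screened = map_int(seq_len(dplyr::n()), function(i) {
                  sum(paste(islands$scaffold[i],
                            islands$members[[i]]) %in% key)
                }))
  out <- filter(out, .data$n_screened >= min_screened)
  out <- arrange(out, dplyr::desc(.data$area), .data$scaffold, .data$start)
  mutate(out, rank = row_number())
}

#' Candidate genes of ranked islands
#'
#' The candidate genes of an island are the union of genes linked to its
#' screened member SNPs.
#'
#' @param islands A [rank_islands()] result.
#' @param screen A [screen_loci()] result.
#' @param links A [link_snps_to_genes()] result.
#' @return `islands` with list column `candidate_genes` and `n_genes`.
#' @export
island_candidate_genes <- function(islands, screen, links) {
  scr <- filter(as_tibble(screen), .data$screened)
  scr_links <- inner_join(links, scr[c("scaffold", "position")],
                          by = c("scaffold", "position"))
  genes <- map(seq_len(nrow(islands)), function(i) {
    hit <- scr_links$scaffold == islands$scaffold[i] &
      scr_links$position %in% islands$members[[i]]
    sort(unique(scr_links$gene_id[hit]))
  })
  mutate(islands, candidate_genes = genes,
         n_genes = lengths(genes))
}

#' Top-N candidate-gene table
#'
#' @param islands An [island_candidate_genes()] result.
#' @param top_n Number of top-ranked islands to report (default 20).
#' @return A long tibble: `rank`, `scaffold`, `start`, `end`, `area`,
#'   `gene_id` (one row per island x gene).
#' @export
top_island_genes <- function(islands, top_n = 20) {
  top <- filter(islands, .data$rank <= top_n)
  purrr::map_dfr(seq_len(nrow(top)), function(i) {
    g <- top$candidate_genes[[i]]
    if (!length(g)) g <- NA_character_
    tibble(rank = top$rank[i], scaffold = top$scaffold[i],
           start = top$start[i], end = top$end[i], area = top$area[i],
           gene_id = g)
  })
}

#' Sliding-window allele-frequency difference profile
#'
#' For a region of one scaffold, the mean absolute focal-allele frequency
#' difference of each non-lowest altitude deme versus the lowest deme, in
#' sliding windows (defaults: 4-kbp window, 1-kbp step) — the per-island
#' cline visualization.
#'
#' @param stats A [locus_stats()] tibble (provides `f_l`, `f_m1`, `f_m2`,
#'   `f_h`).
#' @param scaffold Scaffold id.
#' @param start,end Region bounds in bp (`start < end`).
#' @param window,step Window size and step in bp.
#' @return A long tibble: `center`, `deme` (`M1`/`M2`/`H`), `mean_abs_diff`
#'   (`NA` for empty windows), `n_snps`.
#' @export
sliding_profile <- function(stats, scaffold, start, end,
                            window = 4000, step = 1000) {
  if (end <= start) abort("zero-width region")
  on_s <- stats$scaffold == scaffold
  p <- stats$position[on_s]
  diffs <- list(M1 = abs(stats$f_m1 - stats$f_l)[on_s],
                M2 = abs(stats$f_m2 - stats$f_l)[on_s],
                H = abs(stats$f_h - stats$f_l)[on_s])
  centers <- seq(start, end, by = step)
  purrr::map_dfr(centers, function(ct) {
    inside <- abs(p - ct) <= window / 2
    tibble(
      center = ct, deme = names(diffs),
      mean_abs_diff = map_dbl(diffs, function(d) {
        if (any(inside)) mean(d[inside]) else NA_real_
      }),
      n_snps = sum(inside)
    )
  })
}
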