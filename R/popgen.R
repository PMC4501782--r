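# Allele-count machinery -----------------------------------------------------

# counts[l, a] over alleles 0..3 for the given sample columns, plus called
# chromosome count per locus. Allele columns beyond a locus's allele count
# stay 0, so frequency vectors are zero-padded to width 4.
count_alleles <- function(geno, cols) {
  a1 <- geno$a1[, cols, drop = FALSE]
  a2 <- geno$a2[, cols, drop = FALSE]
  cnt <- vapply(0:3, function(a) {
    rowSums(a1 == a, na.rm = TRUE) + rowSums(a2 == a, na.rm = TRUE)
  }, numeric(nrow(a1)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
  chrom <- 2 * rowSums(!is.na(a1))
  list(counts = cnt, chrom = chrom)
}

freq_matrix <- function(geno, cols, what = "deme") {
  ac <- count_alleles(geno, cols)
  if (any(ac$chrom == 0)) {
    i <- which(ac$chrom == 0)[1]
    abort(paste0("no called genotypes for ", what, " at locus ",
                 geno$loci$scaffold[i], ":", geno$loci$position[i]))
  }
  ac$counts / ac$chrom
}

role_samples <- function(geno, design, role) {
  ids <- design$sample_id[design$role == role]
  cols <- match(ids, geno$samples)
  if (anyNA(cols)) {
    abort(paste0("samples in population map absent from genotypes: ",
                 paste(ids[is.na(cols)], collapse = ", ")))
  }
  cols
}

# the five frequency matrices the screen needs: four altitude demes plus the
# pooled reference group (pooling by allele *counts*, i.e. sample-size
# weighted, before dividing)
scan_freqs <- function(geno, design) {
  roles <- c(l = "lowest", m1 = "lower_middle", m2 = "higher_middle",
             h = "highest")
  out <- lapply(roles, function(r) {
    freq_matrix(geno, role_samples(geno, design, r), what = r)
  })
  out$ref <- freq_matrix(geno, role_samples(geno, design, "reference"),
                         what = "pooled reference")
  out
}

#' Per-deme allele frequencies
#'
#' Computes allele frequencies per locus for every deme of the design plus
#' the pooled reference group (`reference_pool`), pooled by allele counts so
#' that larger reference demes weigh proportionally.
#'
#' @param geno A [genotype_table()].
#' @param design A transect design (see [read_population_map()]).
#' @return A long tibble: `scaffold`, `position`, `group`, `allele_index`
#'   (0-based), `allele`, `freq`, `n_chrom`.
#' @export
deme_frequencies <- function(geno, design) {
  stopifnot(inherits(geno, "genotype_table"))
  groups <- c(setNames(as.list(unique(design$deme)), unique(design$deme)),
              list(reference_pool = NULL))
  k <- lengths(geno$loci$alleles)
  purrr::map_dfr(names(groups), function(g) {
    ids <- if (g == "reference_pool") {
      design$sample_id[design$role == "reference"]
    } else {
      design$sample_id[design$deme == g]
    }
    cols <- match(ids, geno$samples)
    if (anyNA(cols)) abort("samples in population map absent from genotypes")
    ac <- count_alleles(geno, cols)
    idx <- rep(seq_len(nrow(geno$loci)), k)
    a_idx <- unlist(lapply(k, seq_len)) - 1L
    tibble(
      scaffold = geno$loci$scaffold[idx],
      position = geno$loci$position[idx],
      group = g,
      allele_index = a_idx,
      allele = unlist(geno$loci$alleles),
      freq = ac$counts[cbind(idx, a_idx + 1L)] /
        ifelse(ac$chrom[idx] > 0, ac$chrom[idx], NA_real_),
      n_chrom = ac$chrom[idx]
    )
  })
}

# Scalar index functions ------------------------------------------------------

#' Unidirectionality index U of an altitudinal allele-frequency series
#'
#' For focal-allele frequencies in the lowest, lower-middle, higher-middle
#' and highest demes, `U = d + (d - s) / 2` where `d = |F_L - F_H|` and `s`
#' is the summed absolute difference along consecutive demes. U reaches 1
#' only for a full monotone cline (`d = 1`), is 0 for a flat series and -1
#' for a maximal zigzag; `U <= d` always, with equality iff the series is
#' monotone.
#'
#' @param f_l,f_m1,f_m2,f_h Focal-allele frequencies in \[0,1\]; vectorized.
#' @param method `"consistent"` (default) uses the reading whose range is
#'   \[-1, 1\]; `"halved"` divides the whole expression by two instead
#'   (range \[-1, 0.5\]).
#' @return Numeric vector of U values.
#' @export
u_index <- function(f_l, f_m1, f_m2, f_h,
                    method = c("consistent", "halved")) {
  method <- match.arg(method)
  f <- c(f_l, f_m1, f_m2, f_h)
  if (anyNA(f) || any(f < 0 | f > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  d <- abs(f_l - f_h)
  s <- abs(f_l - f_m1) + abs(f_m1 - f_m2) + abs(f_m2 - f_h)
  if (method == "consistent") d + (d - s) / 2 else (2 * d - s) / 2
}

#' Choose the focal allele of a locus
#'
#' The allele maximizing the lowest-vs-highest frequency difference; ties
#' break to the lowest allele index (REF first).
#'
#' @param f_low,f_high Numeric allele-frequency vectors of one locus (same
#'   length, summing to 1).
#' @return 0-based allele index.
#' @export
select_focal_allele <- function(f_low, f_high) {
  if (length(f_low) != length(f_high)) abort("frequency vectors differ in length")
  d <- abs(f_low - f_high)
  # tolerance guards the tie rule against floating-point asymmetry
  which(d >= max(d) - 1e-9)[1] - 1L
}

#' Hedrick's standardized G'ST between two demes
#'
#' `G_ST = (H_T - H_S) / H_T` with `H_S` the mean within-deme expected
#' heterozygosity and `H_T` from the unweighted mean frequency vector, then
#' standardized by its maximum given `H_S` for k = 2 demes:
#' `G'ST = G_ST (1 + H_S) / (1 - H_S)`. Returns 0 when `H_T = 0`
#' (monomorphic pair).
#'
#' @param p,q Allele-frequency vectors over the same allele set, each
#'   summing to 1.
#' @return G'ST in \[0, 1\].
#' @export
gst_prime_pair <- function(p, q) {
  if (length(p) != length(q)) abort("frequency vectors differ in length")
  hs <- ((1 - sum(p^2)) + (1 - sum(q^2))) / 2
  ht <- 1 - sum(((p + q) / 2)^2)
  if (ht <= 0) return(0)
  gst <- (ht - hs) / ht
  if (hs >= 1) return(0)
  gst * (1 + hs) / (1 - hs)
}

# row-wise Hedrick over frequency matrices (loci x alleles)
gst_prime_rows <- function(p, q) {
  hs <- ((1 - rowSums(p^2)) + (1 - rowSums(q^2))) / 2
  ht <- 1 - rowSums(((p + q) / 2)^2)
  out <- numeric(nrow(p))
  ok <- ht > 0 & hs < 1
  out[ok] <- (ht[ok] - hs[ok]) / ht[ok] * (1 + hs[ok]) / (1 - hs[ok])
  out
}

#' Derived-allele frequencies of a locus
#'
#' Biallelic loci: the derived allele is the minor allele of the pooled
#' reference group (ties to the lower index); `d_r` is its pooled-reference
#' frequency (in \[0, 0.5\]) and `d_h` its frequency in the highest deme.
#' Tri/tetra-allelic loci: the derived-allele frequency is one minus the
#' major-allele frequency, computed separately in each group (`derived_allele`
#' is `NA` then).
#'
#' @param ref_freq,high_freq Allele-frequency vectors of one locus in the
#'   pooled reference group and the highest deme.
#' @return One-row tibble: `derived_allele` (0-based or `NA`), `d_r`, `d_h`.
#' @export
derived_allele_freq <- function(ref_freq, high_freq) {
  if (length(ref_freq) != length(high_freq)) {
    abort("frequency vectors differ in length")
  }
  if (length(ref_freq) == 2L) {
    idx <- if (ref_freq[2] < ref_freq[1]) 2L else 1L
    tibble(derived_allele = idx - 1L, d_r = ref_freq[idx],
           d_h = high_freq[idx])
  } else {
    tibble(derived_allele = NA_integer_,
           d_r = 1 - max(ref_freq), d_h = 1 - max(high_freq))
  }
}

#' Derived-allele-frequency increment index
#'
#' `delta_d' = |d_h - d_r| * (1 - d_r)`: the absolute increase of the
#' putative derived allele in the highest deme, damped by the probability
#' `1 - d_r` that the reference minor allele is truly derived.
#'
#' @param d_h Derived-allele frequency in the highest deme, in \[0, 1\].
#' @param d_r Derived-allele frequency in the pooled reference group, in
#'   \[0, 0.5\].
#' @return Numeric vector in \[0, 1\].
#' @export
delta_d_prime <- function(d_h, d_r) {
  if (any(d_h < 0 | d_h > 1, na.rm = TRUE)) abort("d_h must lie in [0, 1]")
  if (any(d_r < 0 | d_r > 0.5, na.rm = TRUE)) {
    abort("d_r must lie in [0, 0.5] (reference minor-allele frequency)")
  }
  abs(d_h - d_r) * (1 - d_r)
}

# Windowing -------------------------------------------------------------------

#' Windowed means of per-SNP statistics
#'
#' For every SNP, the unweighted mean of each statistic over all SNPs on the
#' same scaffold within `half_width` bp of it (inclusive, focal SNP
#' included); windows never cross scaffolds and shrink at scaffold edges.
#'
#' @param x Tibble with `scaffold`, `position` and the statistic columns,
#'   sorted by (scaffold, position).
#' @param cols Character vector of statistic column names.
#' @param half_width Window half-width in bp (default 2000, i.e. a 4-kbp
#'   window).
#' @return `x` with an added `<col>_bar` column per statistic and
#'   `n_window`, the window SNP count.
#' @export
window_mean <- function(x, cols, half_width = 2000) {
  x <- as_tibble(x)
  stopifnot(half_width >= 0, all(cols %in% names(x)))
  if (is.unsorted(order(x$scaffold, x$position)) ||
      any(order(x$scaffold, x$position) != seq_len(nrow(x)))) {
    abort("input must be sorted by (scaffold, position)")
  }
  n <- nrow(x)
  lo <- integer(n); hi <- integer(n)
  for (s in unique(x$scaffold)) {
    i <- which(x$scaffold == s)
    p <- x$position[i]
    lo[i] <- i[1] - 1L + findInterval(p - half_width - 0.5, p) + 1L
    hi[i] <- i[1] - 1L + findInterval(p + half_width + 0.5, p)
  }
  x$n_window <- hi - lo + 1L
  for (cl in cols) {
    cs <- cumsum(c(0, x[[cl]]))
    x[[paste0(cl, "_bar")]] <- (cs[hi + 1L] - cs[lo]) / x$n_window
  }
  x
}

# Locus statistics ------------------------------------------------------------

#' Per-locus cline statistics with 4-kbp windowed means
#'
#' The workhorse of the scan: per SNP, the focal allele (largest
#' lowest-vs-highest frequency difference), the unidirectionality index U,
#' Hedrick's G'ST between the lowest and highest demes, the
#' derived-allele-frequency increment delta-D' against the pooled reference
#' group, and the windowed means of all three.
#'
#' @param geno A [genotype_table()].
#' @param design A transect design (see [read_population_map()]).
#' @param half_width Window half-width in bp (default 2000).
#' @param u_method U-index reading, see [u_index()].
#' @return A tibble of class `locus_stats`: `scaffold`, `position`,
#'   `n_alleles`, `focal_allele` (0-based), `f_l`, `f_m1`, `f_m2`, `f_h`,
#'   `u`, `gst`, `d_h`, `d_r`, `delta_d`, their `_bar` windowed means and
#'   `n_window`.
#' @export
locus_stats <- function(geno, design, half_width = 2000,
                        u_method = c("consistent", "halved")) {
  stopifnot(inherits(geno, "genotype_table"))
  u_method <- match.arg(u_method)
  fq <- scan_freqs(geno, design)
  n <- nrow(geno$loci)
  k <- lengths(geno$loci$alleles)

  diffs <- abs(fq$l - fq$h)
  # first-index tie rule, robust to floating-point asymmetry in the diffs
  dmax <- do.call(pmax, as.data.frame(diffs))
  focal <- max.col(diffs >= dmax - 1e-9, ties.method = "first")
  pick <- cbind(seq_len(n), focal)
  f_l <- fq$l[pick]; f_m1 <- fq$m1[pick]
  f_m2 <- fq$m2[pick]; f_h <- fq$h[pick]

  d <- abs(f_l - f_h)
  s <- abs(f_l - f_m1) + abs(f_m1 - f_m2) + abs(f_m2 - f_h)
  u <- if (u_method == "consistent") d + (d - s) / 2 else (2 * d - s) / 2

  gst <- gst_prime_rows(fq$l, fq$h)

  # derived allele: reference-pool minor allele (biallelic) or 1 - major
  bi <- k == 2L
  d_r <- numeric(n); d_h <- numeric(n)
  min_idx <- ifelse(fq$ref[, 2] < fq$ref[, 1], 2L, 1L)
  d_r[bi] <- fq$ref[cbind(which(bi), min_idx[bi])]
  d_h[bi] <- fq$h[cbind(which(bi), min_idx[bi])]
  if (any(!bi)) {
    for (i in which(!bi)) {
      d_r[i] <- 1 - max(fq$ref[i, seq_len(k[i])])
      d_h[i] <- 1 - max(fq$h[i, seq_len(k[i])])
    }
  }
  delta_d <- abs(d_h - d_r) * (1 - d_r)

  out <- tibble(
    scaffold = geno$loci$scaffold, position = geno$loci$position,
    n_alleles = k, focal_allele = focal - 1L,
    f_l = f_l, f_m1 = f_m1, f_m2 = f_m2, f_h = f_h,
    u = u, gst = gst, d_h = d_h, d_r = d_r, delta_d = delta_d
  )
  out <- window_mean(out, c("u", "gst", "delta_d"), half_width = half_width)
  class(out) <- c("locus_stats", class(out))
  out
}
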