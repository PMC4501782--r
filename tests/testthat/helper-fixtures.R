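# Shared fixture builders and independent oracles.

# genotype table from explicit per-deme genotype strings, e.g.
# calls = list(L = c("0/0", "0/1"), ...) per locus; `loci` is a tibble with
# scaffold, position, alleles (list)
make_geno <- function(loci, calls, samples, depth = NULL) {
  a1 <- matrix(NA_integer_, nrow(loci), length(samples))
  a2 <- matrix(NA_integer_, nrow(loci), length(samples))
  for (i in seq_len(nrow(loci))) {
    g <- strsplit(calls[[i]], "/", fixed = TRUE)
    a1[i, ] <- suppressWarnings(as.integer(vapply(g, `[`, "", 1)))
    a2[i, ] <- suppressWarnings(as.integer(vapply(g, `[`, "", 2)))
  }
  genotype_table(loci, a1, a2, samples, depth = depth)
}

biallelic_loci <- function(n, scaffold = "scf1", spacing = 1000L) {
  tibble::tibble(
    scaffold = scaffold,
    position = spacing * seq_len(n),
    alleles = replicate(n, c("A", "G"), simplify = FALSE)
  )
}

# 4 altitude demes (2 diploids each) + 2 reference demes (2 each)
tiny_design <- function(n_per_deme = 2) {
  demes <- tibble::tibble(
    deme = c("L", "M1", "M2", "H", "R1", "R2"),
    role = c("lowest", "lower_middle", "higher_middle", "highest",
             "reference", "reference"),
    altitude_m = c(380, 600, 1000, 1250, 220, 240)
  )
  altiscan::transect_design(tibble::tibble(
    sample_id = unlist(lapply(demes$deme,
                              function(d) paste0(d, "_", seq_len(n_per_deme)))),
    deme = rep(demes$deme, each = n_per_deme),
    role = rep(demes$role, each = n_per_deme),
    altitude_m = rep(demes$altitude_m, each = n_per_deme)
  ))
}

small_sim <- function(seed = 1, ...) {
  simulate_scan_dataset(sim_config(
    n_scaffolds = 2, scaffold_length = 50000, seed = seed, ...
  ))
}

# --- independent oracles ----------------------------------------------------

# Hedrick's standardized G'ST straight from its published definition,
# computed term by term (independent of the vectorized implementation)
hedrick_oracle <- function(p, q) {
  hs_p <- 1 - sum(vapply(p, function(x) x^2, numeric(1)))
  hs_q <- 1 - sum(vapply(q, function(x) x^2, numeric(1)))
  hs <- (hs_p + hs_q) / 2
  pbar <- (p + q) / 2
  ht <- 1 - sum(vapply(pbar, function(x) x^2, numeric(1)))
  if (ht == 0) return(0)
  gst <- (ht - hs) / ht
  k <- 2
  gst * (k - 1 + hs) / ((k - 1) * (1 - hs))
}

# one-tailed Fisher p by full enumeration of tables with fixed margins
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  w <- choose(c1, xs) * choose(n - c1, r1 - xs)
  sum(w[xs >= a]) / sum(w)
}

# area of the positive part of the gap-broken piecewise-linear curve by
# dense numerical integration (0.25-bp grid)
island_area_oracle <- function(scaffold, position, u_bar, gap = 4000) {
  total <- 0
  for (s in unique(scaffold)) {
    p <- position[scaffold == s]
    v <- u_bar[scaffold == s]
    brk <- c(0L, which(diff(p) > gap), length(p))
    for (b in seq_len(length(brk) - 1L)) {
      idx <- (brk[b] + 1L):brk[b + 1L]
      if (length(idx) < 2L) next
      xs <- seq(p[idx[1]], p[idx[length(idx)]], by = 0.25)
      ys <- pmax(0, approx(p[idx], v[idx], xout = xs)$y)
      total <- total + sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
    }
  }
  total
}
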