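test_that("deme allele frequencies count chromosomes, pooling references", {
  # one locus; L: {AA, AA, AA, AG, GG} -> F(A) = 0.7
  loci <- biallelic_loci(1)
  design <- tiny_design(n_per_deme = 5)[1:30, ]
  design <- altiscan::transect_design(design)
  calls <- list(c("0/0", "0/0", "0/0", "0/1", "1/1",   # L
                  rep("0/0", 5), rep("0/0", 5), rep("0/0", 5),
                  rep("0/0", 5),                        # R1: F(A) = 1.0
                  rep("0/1", 5)))                       # R2: F(A) = 0.5
  g <- make_geno(loci, calls, design$sample_id)
  fr <- deme_frequencies(g, design)
  fA_L <- fr$freq[fr$group == "L" & fr$allele == "A"]
  expect_equal(fA_L, 0.7)
  # pooled reference: equal deme sizes, (10*1.0 + 10*0.5) / 20
  fA_ref <- fr$freq[fr$group == "reference_pool" & fr$allele == "A"]
  expect_equal(fA_ref, 0.75)
  expect_equal(fr$n_chrom[fr$group == "reference_pool"][1], 20)
})

test_that("unequal reference demes pool by chromosome counts", {
  # 8 + 4 diploids with F(A) = 1.0 and 0.5 -> (16*1 + 8*0.5)/24 = 5/6
  df <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:32),
    deme = c(rep("L", 5), rep("M1", 5), rep("M2", 5), rep("H", 5),
             rep("Ra", 8), rep("Rb", 4)),
    role = c(rep(c("lowest", "lower_middle", "higher_middle", "highest"),
                 each = 5), rep("reference", 12)),
    altitude_m = c(rep(c(380, 600, 1000, 1250), each = 5), rep(200, 8),
                   rep(210, 4))
  )
  design <- altiscan::transect_design(df)
  calls <- list(c(rep("0/0", 20), rep("0/0", 8), rep("0/1", 4)))
  g <- make_geno(biallelic_loci(1), calls, design$sample_id)
  fr <- deme_frequencies(g, design)
  expect_equal(fr$freq[fr$group == "reference_pool" & fr$allele == "A"],
               (16 * 1 + 8 * 0.5) / 24)
})

test_that("a deme with no called genotypes at a locus is an error", {
  design <- tiny_design()
  calls <- list(c("./.", "./.", rep("0/1", 10)))
  g <- make_geno(biallelic_loci(1), calls, design$sample_id)
  expect_error(locus_stats(g, design), "lowest")
})

test_that("U index matches hand-evaluated cases and its stated reading", {
  expect_equal(u_index(0, 1 / 3, 2 / 3, 1), 1)     # monotone full cline
  expect_equal(u_index(0.5, 0.5, 0.5, 0.5), 0)     # flat
  expect_equal(u_index(0, 1, 0, 0), -1)            # maximal zigzag
  expect_equal(u_index(0.2, 0.1, 0.6, 0.9), 0.6)   # 0.7 + (0.7 - 0.9)/2
  # alternative whole-expression-halved reading peaks at 0.5
  expect_equal(u_index(0, 1 / 3, 2 / 3, 1, method = "halved"), 0.5)
  expect_error(u_index(-0.1, 0, 0, 0), "\\[0, 1\\]")
})

test_that("U is invariant to allele complement and altitude reversal", {
  set.seed(42)
  for (i in 1:200) {
    f <- runif(4)
    u <- u_index(f[1], f[2], f[3], f[4])
    expect_equal(u, u_index(1 - f[1], 1 - f[2], 1 - f[3], 1 - f[4]),
                 tolerance = 1e-12)
    expect_equal(u, u_index(f[4], f[3], f[2], f[1]), tolerance = 1e-12)
    expect_lte(u, abs(f[1] - f[4]) + 1e-12)
    # U equals |F_L - F_H| iff the series is monotone
    mono <- all(diff(f) >= 0) || all(diff(f) <= 0)
    if (mono) expect_equal(u, abs(f[1] - f[4]), tolerance = 1e-12)
  }
})

test_that("focal allele maximizes the lowest-highest difference", {
  expect_equal(select_focal_allele(c(0.9, 0.1), c(0.2, 0.8)), 0L)  # tie -> 0
  expect_equal(select_focal_allele(c(0.5, 0.3, 0.2), c(0.1, 0.3, 0.6)), 0L)
  expect_equal(select_focal_allele(c(0.5, 0.5), c(0.5, 0.5)), 0L)
  expect_equal(select_focal_allele(c(0.2, 0.5, 0.3), c(0.2, 0.1, 0.7)), 1L)
})

test_that("Hedrick's G'ST matches its closed form and endpoints", {
  expect_equal(gst_prime_pair(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(gst_prime_pair(c(1, 0), c(0, 1)), 1)
  expect_equal(gst_prime_pair(c(0.2, 0.8), c(0.8, 0.2)), 0.698824,
               tolerance = 1e-6)
  expect_equal(gst_prime_pair(c(1, 0), c(1, 0)), 0)  # monomorphic pair
  expect_error(gst_prime_pair(c(1, 0), c(1, 0, 0)), "length")
})

test_that("G'ST agrees with the definition-level oracle on random vectors", {
  set.seed(7)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    p <- runif(k); p <- p / sum(p)
    q <- runif(k); q <- q / sum(q)
    expect_equal(gst_prime_pair(p, q), hedrick_oracle(p, q),
                 tolerance = 1e-12)
  }
})

test_that("derived-allele identification follows the reference pool", {
  r <- derived_allele_freq(c(0.8, 0.2), c(0.1, 0.9))
  expect_equal(r$derived_allele, 1L)
  expect_equal(r$d_r, 0.2); expect_equal(r$d_h, 0.9)

  tri <- derived_allele_freq(c(0.7, 0.2, 0.1), c(0.2, 0.5, 0.3))
  expect_true(is.na(tri$derived_allele))
  expect_equal(tri$d_r, 0.3); expect_equal(tri$d_h, 0.5)

  tie <- derived_allele_freq(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(tie$derived_allele, 0L)   # tie breaks to the lower index
  expect_equal(tie$d_r, 0.5)

  # for biallelic loci the 1 - major rule equals the minor-allele rule
  set.seed(1)
  for (i in 1:50) {
    fr <- runif(1); fh <- runif(1)
    r2 <- derived_allele_freq(c(fr, 1 - fr), c(fh, 1 - fh))
    expect_equal(r2$d_r, 1 - max(c(fr, 1 - fr)), tolerance = 1e-12)
  }
})

test_that("delta-D' evaluates its closed form with domain checks", {
  expect_equal(delta_d_prime(1, 0), 1)
  expect_equal(delta_d_prime(0.3, 0.3), 0)
  expect_equal(delta_d_prime(0.9, 0.2), 0.56)
  expect_error(delta_d_prime(0.5, 0.6), "0.5")
  expect_error(delta_d_prime(1.2, 0.1), "\\[0, 1\\]")
})

test_that("windowed means respect membership, bounds and the zero window", {
  x <- tibble::tibble(scaffold = "s", position = c(1000L, 2500L, 6000L),
                      v = c(0.2, 0.6, 1.0))
  w <- window_mean(x, "v", half_width = 2000)
  expect_equal(w$v_bar, c(mean(c(0.2, 0.6)), mean(c(0.2, 0.6)), 1.0))
  expect_equal(w$n_window, c(2L, 2L, 1L))

  w0 <- window_mean(x, "v", half_width = 0)
  expect_equal(w0$v_bar, x$v)

  const <- tibble::tibble(scaffold = "s", position = 1:10 * 100L,
                          v = rep(0.4, 10))
  expect_equal(window_mean(const, "v")$v_bar, rep(0.4, 10))

  set.seed(3)
  r <- tibble::tibble(scaffold = "s", position = sort(sample.int(1e5, 200)),
                      v = rnorm(200))
  wr <- window_mean(r, "v", half_width = 3000)
  expect_true(all(wr$v_bar >= min(r$v) - 1e-12 &
                    wr$v_bar <= max(r$v) + 1e-12))

  expect_error(window_mean(r[c(2, 1, 3:200), ], "v"), "sorted")
})

test_that("windows never cross scaffold boundaries", {
  x <- tibble::tibble(scaffold = rep(c("a", "b"), each = 2),
                      position = c(100L, 200L, 150L, 250L),
                      v = c(0, 1, 10, 20))
  w <- window_mean(x, "v", half_width = 1000)
  expect_equal(w$v_bar, c(0.5, 0.5, 15, 15))
})

test_that("diversity summaries recover hand-computed He, Ho and P", {
  design <- tiny_design()
  # locus 1: L = {AG, AG} -> He = 0.5, Ho = 1; locus 2: L monomorphic
  calls <- list(rep("0/1", 12), rep("0/0", 12))
  g <- make_geno(biallelic_loci(2), calls, design$sample_id)
  ds <- diversity_summary(g, design)
  L <- ds$demes[ds$demes$deme == "L", ]
  expect_equal(L$he, mean(c(0.5, 0)))
  expect_equal(L$ho, mean(c(1, 0)))
  expect_equal(L$p_poly, 0.5)
  expect_equal(nrow(ds$tests), 6)
  expect_true(all(ds$tests$p_bonferroni >= ds$tests$p_value - 1e-12,
                  na.rm = TRUE))
})

test_that("multilocus G'ST reduces to the single-locus value when loci agree", {
  design <- tiny_design()
  p <- c(0.25, 0.75)
  # demes L and H fixed patterns replicated over 3 identical loci
  calls <- rep(list(c("0/1", "0/0",          # L: F(A) = 0.75
                      "0/0", "0/0", "0/0", "0/0",
                      "1/1", "0/1",          # H: F(A) = 0.25
                      "0/0", "0/0", "0/0", "0/0")), 3)
  g <- make_geno(biallelic_loci(3), calls, design$sample_id)
  m <- multilocus_gst_matrix(g, design)
  lh <- m$gst_prime[m$deme_a == "L" & m$deme_b == "H"]
  expect_equal(lh, gst_prime_pair(c(0.75, 0.25), c(0.25, 0.75)),
               tolerance = 1e-12)
  # identical demes differ by nothing
  expect_equal(m$gst_prime[m$deme_a == "M1" & m$deme_b == "M2"], 0)
})
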