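test_that("the same seed reproduces the dataset exactly", {
  a <- small_sim(seed = 5)
  b <- small_sim(seed = 5)
  expect_identical(a$genotypes$loci, b$genotypes$loci)
  expect_identical(a$genotypes$a1, b$genotypes$a1)
  expect_identical(a$genotypes$depth, b$genotypes$depth)
  expect_identical(a$truth, b$truth)
  expect_identical(a$go_map, b$go_map)
})

test_that("selected loci carry the monotone cline and unit hitchhike weight", {
  sim <- small_sim(seed = 2)
  sel <- sim$truth[sim$truth$is_selected, ]
  expect_equal(nrow(sel), 2)
  expect_equal(sel$w, rep(1, 2))
  for (i in seq_len(nrow(sel))) {
    expect_equal(unlist(sel[i, c("f_l", "f_m1", "f_m2", "f_h")]),
                 c(f_l = 0, f_m1 = 1 / 3, f_m2 = 2 / 3, f_h = 1))
  }
  # a perfect 0 -> 1 cline attains the U maximum on expected frequencies
  expect_equal(u_index(sel$f_l[1], sel$f_m1[1], sel$f_m2[1], sel$f_h[1]), 1)
})

test_that("hitchhike weight decays exponentially with distance", {
  sim <- small_sim(seed = 2)
  tr <- sim$truth
  sel <- tr[tr$is_selected, ]
  lambda <- sim$config$lambda
  for (s in unique(sel$scaffold)) {
    on_s <- tr$scaffold == s
    d <- vapply(tr$position[on_s],
                function(p) min(abs(p - sel$position[sel$scaffold == s])),
                numeric(1))
    expect_equal(tr$w[on_s], exp(-d / lambda), tolerance = 1e-12)
  }
  # closed form at the decay length: w(lambda) = exp(-1)
  near <- which.min(abs(abs(tr$position - sel$position[1]) - lambda)[
    tr$scaffold == sel$scaffold[1]])
  d_near <- abs(tr$position[tr$scaffold == sel$scaffold[1]][near] -
                  sel$position[1])
  expect_equal(tr$w[tr$scaffold == sel$scaffold[1]][near],
               exp(-d_near / lambda), tolerance = 1e-12)
  expect_equal(exp(-1), 0.3678794, tolerance = 1e-6)
})

test_that("simulated frequencies and calls are valid", {
  sim <- small_sim(seed = 7, multiallelic_fraction = 0.2)
  tr <- sim$truth
  f <- as.matrix(tr[, c("f_l", "f_m1", "f_m2", "f_h", "f_ref")])
  expect_true(all(f >= 0 & f <= 1))
  g <- sim$genotypes
  k <- lengths(g$loci$alleles)
  expect_true(all(k >= 2 & k <= 4))
  expect_true(any(k > 2))
  expect_true(all(g$a2 < k[row(g$a2)], na.rm = TRUE))
  expect_true(all(g$a1 <= g$a2, na.rm = TRUE))
})

test_that("higher neighbor correlation rho tightens the frequency chain", {
  cor_at <- function(rho, seed) {
    sim <- simulate_scan_dataset(sim_config(
      n_scaffolds = 2, scaffold_length = 50000, rho = rho, seed = seed,
      selected_loci = tibble::tibble(scaffold = character(),
                                     position = integer(),
                                     f_low = numeric(), f_high = numeric())
    ))
    tr <- sim$truth
    mean(c(cor(tr$f_l, tr$f_m1), cor(tr$f_m1, tr$f_m2),
           cor(tr$f_m2, tr$f_h)))
  }
  lo <- mean(vapply(1:3, function(s) cor_at(0.1, s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) cor_at(0.9, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("fixture bundles round-trip through the readers", {
  sim <- small_sim(seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim, dir)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))

  g <- read_genotype_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(g$loci$position, sim$genotypes$loci$position)
  expect_equal(unname(g$a1), unname(sim$genotypes$a1))
  expect_equal(unname(g$a2), unname(sim$genotypes$a2))

  d <- read_population_map(file.path(dir, "popmap.tsv"))
  expect_equal(as.data.frame(d), as.data.frame(sim$design))

  ex <- read_exon_bed(file.path(dir, "exons.bed"))
  expect_equal(ex, sim$exons)

  gm <- read_go_map(file.path(dir, "go_map.tsv"))
  expect_equal(gm, sim$go_map)

  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(sim$genotypes$loci))
})

test_that("invalid selected-locus placement is rejected", {
  expect_error(sim_config(n_scaffolds = 1, scaffold_length = 1000,
                          selected_loci = tibble::tibble(
                            scaffold = "scf01", position = 5000L,
                            f_low = 0, f_high = 1)),
               "outside scaffold")
  expect_error(sim_config(selected_loci = tibble::tibble(
    scaffold = "nope", position = 10L, f_low = 0, f_high = 1)),
    "unknown scaffold")
})
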