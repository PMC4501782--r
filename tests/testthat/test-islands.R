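curve4 <- function() {
  tibble::tibble(scaffold = "s",
                 position = c(1000L, 2000L, 3000L, 4000L),
                 u_bar = c(-0.1, 0.5, 0.4, -0.2))
}

test_that("islands start and end at interpolated x-intercepts", {
  isl <- segment_islands(curve4())
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 1000 + 1000 * 0.1 / 0.6, tolerance = 1e-9)
  expect_equal(isl$end, 3000 + 1000 * 0.4 / 0.6, tolerance = 1e-9)
  expect_equal(isl$members[[1]], c(2000, 3000))
  # trapezoid area: 208.33 + 450 + 133.33
  expect_equal(isl$area, 0.5 * (1000 * 5 / 6) * 0.5 + 450 +
                 0.5 * (1000 * 2 / 3) * 0.4, tolerance = 1e-9)
  expect_equal(isl$area, 791.6667, tolerance = 1e-4)
})

test_that("gaps beyond 4 kbp break islands; zero values terminate them", {
  two <- tibble::tibble(scaffold = "s", position = c(2000L, 7000L),
                        u_bar = c(0.3, 0.3))
  isl <- segment_islands(two)          # 5000 > 4000: two degenerate islands
  expect_equal(nrow(isl), 2)
  expect_equal(isl$start, isl$end)
  expect_equal(isl$area, c(0, 0))

  joined <- tibble::tibble(scaffold = "s", position = c(2000L, 6000L),
                           u_bar = c(0.3, 0.3))
  expect_equal(nrow(segment_islands(joined)), 1)
  expect_equal(segment_islands(joined)$area, 0.3 * 4000)

  z <- tibble::tibble(scaffold = "s",
                      position = c(1000L, 2000L, 3000L),
                      u_bar = c(0.4, 0, 0.4))
  zi <- segment_islands(z)
  expect_equal(nrow(zi), 2)            # the exact zero splits the region
  expect_equal(zi$end[1], 2000)
  expect_equal(zi$start[2], 2000)
  expect_equal(zi$n_snps, c(1L, 1L))   # the zero SNP is no member

  flat <- tibble::tibble(scaffold = "s", position = c(1000L, 2000L),
                         u_bar = c(-0.5, 0))
  expect_equal(nrow(segment_islands(flat)), 0)
})

test_that("segmentation is invariant to flanking non-positive SNPs", {
  base <- curve4()
  padded <- dplyr::bind_rows(
    tibble::tibble(scaffold = "s", position = 500L, u_bar = -0.3),
    base,
    tibble::tibble(scaffold = "s", position = 4500L, u_bar = -0.7)
  )
  a <- segment_islands(base)
  b <- segment_islands(padded)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$area, b$area)
  expect_error(segment_islands(base[c(2, 1, 3, 4), ]), "sorted")
})

test_that("total island area equals the dense integral of the positive part", {
  set.seed(21)
  stats <- tibble::tibble(
    scaffold = rep(c("a", "b"), each = 120),
    position = as.integer(rep(sort(sample.int(150000, 120)), 2)),
    u_bar = rnorm(240, 0, 0.3)
  ) |> dplyr::arrange(scaffold, position)
  isl <- segment_islands(stats)
  expect_equal(sum(isl$area),
               island_area_oracle(stats$scaffold, stats$position,
                                  stats$u_bar),
               tolerance = 1e-6)
})

test_that("ranking keeps only well-supported islands, largest area first", {
  stats <- dplyr::bind_rows(
    curve4(),
    tibble::tibble(scaffold = "t", position = c(1000L, 1500L, 2000L),
                   u_bar = c(0.9, 0.9, 0.9)),
    tibble::tibble(scaffold = "u", position = c(1000L, 2000L),
                   u_bar = c(0.2, 0.2))
  )
  screen <- dplyr::mutate(stats, screened = u_bar > 0.3)
  isl <- segment_islands(stats)
  ranked <- rank_islands(isl, screen, min_screened = 2)
  expect_equal(nrow(ranked), 2)                 # "u" has no screened SNPs
  expect_equal(ranked$scaffold, c("t", "s"))    # area 900 beats 791.7
  expect_equal(ranked$rank, 1:2)
  expect_equal(ranked$n_screened, c(3L, 2L))
  # islands of equal area order by (scaffold, start)
  eq2 <- dplyr::bind_rows(
    tibble::tibble(scaffold = "a", position = c(1000L, 2000L),
                   u_bar = c(0.5, 0.5)),
    tibble::tibble(scaffold = "b", position = c(1000L, 2000L),
                   u_bar = c(0.5, 0.5))
  )
  scr2 <- dplyr::mutate(eq2, screened = TRUE)
  r2 <- rank_islands(segment_islands(eq2), scr2, min_screened = 2)
  expect_equal(r2$scaffold, c("a", "b"))
})

test_that("island candidate genes are the union over screened members", {
  stats <- tibble::tibble(scaffold = "s",
                          position = c(1000L, 1500L, 2000L),
                          u_bar = c(0.5, 0.5, 0.5))
  screen <- dplyr::mutate(stats, screened = c(TRUE, TRUE, FALSE))
  links <- tibble::tibble(
    scaffold = "s", position = c(1000L, 1000L, 1500L, 2000L),
    gene_id = c("geneA", "geneB", "geneA", "geneC")
  )
  isl <- rank_islands(segment_islands(stats), screen)
  withg <- island_candidate_genes(isl, screen, links)
  # geneC only links to the unscreened member; geneA counted once
  expect_equal(withg$candidate_genes[[1]], c("geneA", "geneB"))
  expect_equal(withg$n_genes, 2L)
  top <- top_island_genes(withg, top_n = 20)
  expect_equal(nrow(top), 2)
  expect_equal(top$rank, c(1L, 1L))
})

test_that("top-N reporting truncates the ranked list", {
  set.seed(5)
  stats <- tibble::tibble(
    scaffold = sprintf("c%02d", rep(1:30, each = 2)),
    position = rep(c(1000L, 2000L), 30),
    u_bar = rep(runif(30, 0.1, 1), each = 2)
  )
  screen <- dplyr::mutate(stats, screened = TRUE)
  ranked <- rank_islands(segment_islands(stats), screen)
  withg <- island_candidate_genes(
    ranked, screen,
    tibble::tibble(scaffold = stats$scaffold, position = stats$position,
                   gene_id = paste0("g_", stats$scaffold))
  )
  expect_equal(nrow(ranked), 30)
  top <- top_island_genes(withg, top_n = 20)
  expect_equal(length(unique(top$rank)), 20)
  expect_true(all(top$rank <= 20))
})

test_that("sliding profiles average |F_deme - F_L| within each window", {
  stats <- tibble::tibble(
    scaffold = "s", position = c(1000L, 1800L),
    f_l = c(0.1, 0.2), f_m1 = c(0.1, 0.2),
    f_m2 = c(0.3, 0.6), f_h = c(0.3, 0.6)
  )
  pr <- sliding_profile(stats, "s", 500, 2500, window = 4000, step = 1000)
  # both SNPs fall in every window: H diffs 0.2 and 0.4 -> mean 0.3
  expect_equal(unique(pr$mean_abs_diff[pr$deme == "H"]), 0.3)
  expect_equal(unique(pr$mean_abs_diff[pr$deme == "M1"]), 0)  # equals lowest
  expect_equal(unique(pr$n_snps), 2L)
  # empty windows give NA
  pr2 <- sliding_profile(stats, "s", 20000, 21000, window = 1000)
  expect_true(all(is.na(pr2$mean_abs_diff)))
  expect_error(sliding_profile(stats, "s", 100, 100), "zero-width")
})
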