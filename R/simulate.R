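#' Configuration for the transect simulator
#'
#' Defaults emulate a desk-scale version of the study design the scan is
#' built for: a linear stepping-stone transect of four altitude demes (5
#' diploid individuals each, at 380/600/1000/1250 m) plus four pooled
#' low-altitude reference demes (4 individuals each), mean inter-SNP spacing
#' 484 bp, and one selected locus mid-scaffold with a full 0 to 1 frequency
#' cline and exponentially decaying hitchhiking (lambda = 2 kbp).
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Scaffold length in bp.
#' @param snp_spacing Mean inter-SNP spacing in bp (exponential draws).
#' @param n_per_altitude_deme Diploid individuals per altitude deme.
#' @param n_per_reference_deme Diploid individuals per reference deme.
#' @param n_reference_demes Number of reference demes (pooled downstream).
#' @param f_model Balding-Nichols divergence of a deme from its ancestor,
#'   in (0,1); controls neutral between-deme differentiation.
#' @param rho Neighbor correlation of the stepping-stone chain, in \[0,1).
#'   Deme i+1 is drawn around deme i with divergence `f_model * (1 - rho)`.
#' @param selected_loci Tibble with columns `scaffold`, `position`, `f_low`,
#'   `f_high` giving cline endpoints of the selected allele. `NULL` (default)
#'   places one locus at the midpoint of every scaffold with a 0 to 1 cline.
#'   An empty tibble disables selection.
#' @param lambda Hitchhiking decay length in bp: a neutral locus at distance
#'   d from the nearest selected locus has its frequencies pulled toward the
#'   cline with weight `w = exp(-d / lambda)`.
#' @param multiallelic_fraction Fraction of loci given a third allele
#'   (a further 1/100 of that fraction gets a fourth).
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (mean and size); `depth_mean = 0` disables depth simulation.
#' @param gene_spacing,exon_length Exon tiling: one gene every
#'   `gene_spacing` bp, each contributing one exon of `exon_length` bp.
#' @param n_go_terms Number of GO terms in the generated annotation.
#' @param enriched_go_prob,background_go_prob Probability that the first
#'   ("truly enriched") GO term tags a gene near a selected locus versus any
#'   other gene; remaining terms tag all genes at the background rate.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 4,
                       scaffold_length = 250000,
                       snp_spacing = 484,
                       n_per_altitude_deme = 5,
                       n_per_reference_deme = 4,
                       n_reference_demes = 4,
                       f_model = 0.05,
                       rho = 0.8,
                       selected_loci = NULL,
                       lambda = 2000,
                       multiallelic_fraction = 0.016,
                       depth_mean = 30,
                       depth_dispersion = 10,
                       gene_spacing = 5000,
                       exon_length = 2000,
                       n_go_terms = 30,
                       enriched_go_prob = 0.9,
                       background_go_prob = 0.05,
                       seed = 1L) {
  if (is.null(selected_loci)) {
    selected_loci <- tibble(
      scaffold = sprintf("scf%02d", seq_len(n_scaffolds)),
      position = as.integer(round(scaffold_length / 2)),
      f_low = 0, f_high = 1
    )
  }
  selected_loci <- as_tibble(selected_loci)
  cfg <- list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    snp_spacing = snp_spacing,
    n_per_altitude_deme = as.integer(n_per_altitude_deme),
    n_per_reference_deme = as.integer(n_per_reference_deme),
    n_reference_demes = as.integer(n_reference_demes),
    f_model = f_model, rho = rho,
    selected_loci = selected_loci,
    lambda = lambda,
    multiallelic_fraction = multiallelic_fraction,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    gene_spacing = as.integer(gene_spacing),
    exon_length = as.integer(exon_length),
    n_go_terms = as.integer(n_go_terms),
    enriched_go_prob = enriched_go_prob,
    background_go_prob = background_go_prob,
    seed = as.integer(seed)
  )
  stopifnot(cfg$snp_spacing > 0, cfg$lambda > 0,
            cfg$f_model > 0, cfg$f_model < 1,
            cfg$rho >= 0, cfg$rho < 1,
            cfg$multiallelic_fraction >= 0, cfg$multiallelic_fraction <= 1,
            cfg$enriched_go_prob >= 0, cfg$enriched_go_prob <= 1,
            cfg$background_go_prob >= 0, cfg$background_go_prob <= 1)
  if (nrow(selected_loci)) {
    scfs <- sprintf("scf%02d", seq_len(cfg$n_scaffolds))
    if (!all(selected_loci$scaffold %in% scfs)) {
      abort("selected locus on unknown scaffold")
    }
    if (any(selected_loci$position < 1 |
            selected_loci$position > cfg$scaffold_length)) {
      abort("selected locus position outside scaffold")
    }
    stopifnot(all(selected_loci$f_low >= 0 & selected_loci$f_low <= 1),
              all(selected_loci$f_high >= 0 & selected_loci$f_high <= 1))
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw around centre p with divergence F (vectorized).
# Centres are clamped away from {0,1} so the Beta shapes stay positive.
rbn <- function(p, f) {
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a transect scan dataset with known truth
#'
#' Generates a complete input bundle for the scan: genotypes, a transect
#' design, exon and GO annotation, and a per-locus truth table. Neutral loci
#' follow a Balding-Nichols stepping-stone chain along the four altitude
#' demes; selected loci carry a monotone frequency cline between their
#' configured endpoints; neutral loci near a selected locus are pulled toward
#' the cline with exponentially decaying weight (hitchhiking). Reference
#' demes are drawn independently around the ancestral (or low-endpoint)
#' frequency.
#'
#' @param config A [sim_config()].
#' @return A list of class `scan_simulation` with elements `genotypes`
#'   ([genotype_table()]), `design` (transect design tibble), `exons`,
#'   `go_map`, `truth` (per-locus tibble: `scaffold`, `position`,
#'   `is_selected`, `w`, expected frequencies `f_l`, `f_m1`, `f_m2`, `f_h`,
#'   `f_ref`), and `config`.
#' @export
simulate_scan_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scfs <- sprintf("scf%02d", seq_len(config$n_scaffolds))
  sel <- config$selected_loci

  # SNP positions: exponential spacings, selected positions force-included
  pos_list <- map(scfs, function(s) {
    gaps <- rexp(ceiling(3 * config$scaffold_length / config$snp_spacing),
                 rate = 1 / config$snp_spacing)
    p <- cumsum(pmax(1, round(gaps)))
    p <- p[p <= config$scaffold_length]
    p <- sort(unique(c(p, sel$position[sel$scaffold == s])))
    p
  })
  loci <- tibble(
    scaffold = rep(scfs, lengths(pos_list)),
    position = as.integer(unlist(pos_list))
  )
  n <- nrow(loci)
  sel_key <- paste(sel$scaffold, sel$position)
  is_sel <- paste(loci$scaffold, loci$position) %in% sel_key

  # distance to nearest selected locus on the same scaffold -> hitchhike w
  d_near <- rep(Inf, n)
  for (s in unique(sel$scaffold)) {
    on_s <- loci$scaffold == s
    sp <- sel$position[sel$scaffold == s]
    d_near[on_s] <- map_dbl(loci$position[on_s],
                            function(p) min(abs(p - sp)))
  }
  w <- ifelse(is.finite(d_near), exp(-d_near / config$lambda), 0)
  w[is_sel] <- 1

  # neutral stepping-stone frequencies of the (future) alt allele
  p0 <- runif(n, 0.05, 0.95)
  f_chain <- config$f_model * (1 - config$rho)
  neu <- matrix(NA_real_, n, 4)
  neu[, 1] <- rbn(p0, config$f_model)
  for (j in 2:4) neu[, j] <- rbn(neu[, j - 1], f_chain)
  n_ref_demes <- config$n_reference_demes
  neu_ref <- matrix(rbn(rep(p0, n_ref_demes), config$f_model), n, n_ref_demes)

  # cline targets (per locus, from the nearest selected locus)
  cline <- matrix(0, n, 4)
  cline_ref <- numeric(n)
  if (nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      on_s <- loci$scaffold == sel$scaffold[i]
      sp_all <- sel$position[sel$scaffold == sel$scaffold[i]]
      nearest <- abs(loci$position - sel$position[i]) ==
        d_near & on_s & (d_near < Inf)
      tgt <- seq(sel$f_low[i], sel$f_high[i], length.out = 4)
      cline[nearest, ] <- matrix(tgt, sum(nearest), 4, byrow = TRUE)
      cline_ref[nearest] <- sel$f_low[i]
    }
  }

  freq <- (1 - w) * neu + w * cline
  ref_center <- (1 - w) * p0 + w * cline_ref
  freq_ref <- matrix(NA_real_, n, n_ref_demes)
  for (r in seq_len(n_ref_demes)) {
    drawn <- neu_ref[, r]
    freq_ref[, r] <- (1 - w) * drawn + w * rbn(cline_ref, config$f_model)
  }
  # selected loci: cline exactly, references tight around the low endpoint
  if (any(is_sel)) {
    freq[is_sel, ] <- cline[is_sel, , drop = FALSE]
    for (r in seq_len(n_ref_demes)) {
      freq_ref[is_sel, r] <- rbn(cline_ref[is_sel], f_chain)
    }
  }
  freq <- pmin(pmax(freq, 0), 1)
  freq_ref <- pmin(pmax(freq_ref, 0), 1)

  # allele sets; loci are (ref, alt) with `freq` = alt-allele frequency;
  # a small fraction gains a third (and rarely fourth) low-frequency allele
  nucs <- c("A", "C", "G", "T")
  ref_nuc <- sample(nucs, n, replace = TRUE)
  alt_nuc <- map_chr(ref_nuc, function(r) sample(setdiff(nucs, r), 1))
  u_multi <- runif(n)
  k_alleles <- 2L + (u_multi < config$multiallelic_fraction) +
    (u_multi < config$multiallelic_fraction / 100)
  k_alleles[is_sel] <- 2L
  f3 <- ifelse(k_alleles >= 3L, runif(n, 0.01, 0.10), 0)
  f4 <- ifelse(k_alleles >= 4L, runif(n, 0.005, 0.03), 0)
  alleles <- lapply(seq_len(n), function(i) {
    extra <- sample(setdiff(nucs, c(ref_nuc[i], alt_nuc[i])),
                    k_alleles[i] - 2L)
    c(ref_nuc[i], alt_nuc[i], extra)
  })

  # deme layout
  alt_demes <- tibble(
    deme = c("L", "M1", "M2", "H"),
    role = c("lowest", "lower_middle", "higher_middle", "highest"),
    altitude_m = c(380, 600, 1000, 1250),
    n_ind = config$n_per_altitude_deme
  )
  ref_demes <- tibble(
    deme = sprintf("R%d", seq_len(n_ref_demes)),
    role = "reference",
    altitude_m = 200 + 20 * seq_len(n_ref_demes),
    n_ind = config$n_per_reference_deme
  )
  demes <- bind_rows(alt_demes, ref_demes)
  design <- transect_design(tibble(
    sample_id = unlist(map2(demes$deme, demes$n_ind,
                            function(d, k) sprintf("%s_%02d", d, seq_len(k)))),
    deme = rep(demes$deme, demes$n_ind),
    role = rep(demes$role, demes$n_ind),
    altitude_m = rep(demes$altitude_m, demes$n_ind)
  ))

  # genotypes: two chromosome draws per sample from the deme's allele
  # frequency vector (alt freq from `freq`, extra alleles carved out pro rata)
  deme_freq_alt <- cbind(freq, freq_ref)
  deme_of_col <- c(alt_demes$deme, ref_demes$deme)
  n_smp <- nrow(design)
  a1 <- matrix(NA_integer_, n, n_smp)
  a2 <- matrix(NA_integer_, n, n_smp)
  scale_main <- 1 - f3 - f4
  for (j in seq_len(n_smp)) {
    dcol <- match(design$deme[j], deme_of_col)
    p_alt <- deme_freq_alt[, dcol] * scale_main
    p_ref <- (1 - deme_freq_alt[, dcol]) * scale_main
    # cumulative bounds over allele indices 0..3: ref, alt, extra1, extra2
    c1 <- p_ref; c2 <- p_ref + p_alt; c3 <- c2 + f3
    draw <- function() {
      u <- runif(n)
      (u > c1) + (u > c2) + (u > c3)
    }
    g1 <- draw(); g2 <- draw()
    a1[, j] <- pmin(g1, g2)
    a2[, j] <- pmax(g1, g2)
  }
  depth <- NULL
  if (config$depth_mean > 0) {
    depth <- matrix(rnbinom(n * n_smp, size = config$depth_dispersion,
                            mu = config$depth_mean), n, n_smp)
  }
  geno <- genotype_table(
    tibble(scaffold = loci$scaffold, position = loci$position,
           alleles = alleles),
    a1, a2, design$sample_id, depth = depth
  )

  # exon tiling and GO annotation with a known enriched term
  exons <- purrr::map_dfr(scfs, function(s) {
    starts <- seq(0L, config$scaffold_length - config$exon_length,
                  by = config$gene_spacing)
    tibble(scaffold = s, start = starts,
           end = starts + config$exon_length,
           gene_id = sprintf("%s_g%04d", s, seq_along(starts)))
  })
  near_sel <- rep(FALSE, nrow(exons))
  if (nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      hit <- exons$scaffold == sel$scaffold[i] &
        sel$position[i] >= exons$start - 5000 &
        sel$position[i] <= exons$end + 5000
      near_sel <- near_sel | hit
    }
  }
  go_ids <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  go_names <- c("response to temperature stimulus",
                sprintf("synthetic term %02d",
                        seq_len(max(0, config$n_go_terms - 1))))
  go_rows <- purrr::map_dfr(seq_len(config$n_go_terms), function(t) {
    pr <- if (t == 1L) {
      ifelse(near_sel, config$enriched_go_prob, config$background_go_prob)
    } else {
      rep(config$background_go_prob, nrow(exons))
    }
    keep <- runif(nrow(exons)) < pr
    tibble(gene_id = exons$gene_id[keep], go_id = go_ids[t],
           go_name = go_names[t])
  })
  go_map <- arrange(go_rows, .data$gene_id, .data$go_id)

  ord <- order(loci$scaffold, loci$position)
  truth <- tibble(
    scaffold = loci$scaffold, position = loci$position,
    is_selected = is_sel, w = w,
    f_l = freq[, 1], f_m1 = freq[, 2], f_m2 = freq[, 3], f_h = freq[, 4],
    f_ref = rowMeans(freq_ref)
  )[ord, ]

  structure(
    list(genotypes = geno, design = design, exons = exons, go_map = go_map,
         truth = truth, config = config),
    class = "scan_simulation"
  )
}

#' @export
print.scan_simulation <- function(x, ...) {
  cat("<scan_simulation> ", nrow(x$genotypes$loci), " loci, ",
      length(x$genotypes$samples), " samples, ",
      sum(x$truth$is_selected), " selected loci, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as an on-disk fixture bundle
#'
#' Writes `genotypes.vcf`, `popmap.tsv`, `exons.bed`, `go_map.tsv` and
#' `truth.tsv` into `out_dir`; the first four are exactly the formats the
#' readers in this package consume.
#'
#' @param dataset A [simulate_scan_dataset()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the five file paths.
#' @export
write_fixture_bundle <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "scan_simulation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("genotypes.vcf", "popmap.tsv", "exons.bed",
                                "go_map.tsv", "truth.tsv"))
  write_genotype_vcf(dataset$genotypes, paths[1])
  readr::write_tsv(dataset$design, paths[2], progress = FALSE)
  readr::write_tsv(dataset$exons, paths[3], col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(dataset$go_map, paths[4], progress = FALSE)
  readr::write_tsv(dataset$truth, paths[5], progress = FALSE)
  invisible(paths)
}
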