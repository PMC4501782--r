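#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x file (via vcfR) into a [genotype_table()]. The REF+ALT
#' allele order of each record is preserved and multiallelic records are kept
#' as single loci (tri- and tetra-allelic SNPs are first-class citizens of the
#' scan). Per-sample `DP` is carried along when present.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return A [genotype_table()].
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- ifelse(is.na(fix[, "ALT"]) | fix[, "ALT"] == ".", "", fix[, "ALT"])
  alleles <- map2(fix[, "REF"], strsplit(alt, ",", fixed = TRUE),
                  function(r, a) c(r, a[nzchar(a)]))
  n_all <- lengths(alleles)
  if (any(n_all > 4L)) {
    i <- which(n_all > 4L)[1]
    abort(paste0("record ", fix[i, "CHROM"], ":", fix[i, "POS"], " has ",
                 n_all[i], " alleles; at most 4 are supported"))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  samples <- colnames(gt)
  parse_side <- function(side) {
    out <- suppressWarnings(
      matrix(as.integer(sub("^([0-9.]+)[/|]([0-9.]+)$", side, gt)),
             nrow = nrow(gt))
    )
    out
  }
  a1 <- parse_side("\\1")
  a2 <- parse_side("\\2")
  dp <- NULL
  fmt_has_dp <- any(grepl("DP", vcf@gt[, "FORMAT"], fixed = TRUE))
  if (fmt_has_dp) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    storage.mode(dp) <- "integer"
  }
  loci <- tibble(
    scaffold = fix[, "CHROM"],
    position = as.integer(fix[, "POS"]),
    alleles = alleles
  )
  genotype_table(loci, a1, a2, samples, depth = dp)
}

#' Write a genotype table as VCF v4.2
#'
#' Plain-text emission; GT (and DP when depths are present) per sample.
#'
#' @param x A [genotype_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=altiscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples), collapse = "\t"), con)
  has_dp <- !is.null(x$depth)
  fmt <- if (has_dp) "GT:DP" else "GT"
  gt <- matrix(paste0(x$a1, "/", x$a2), nrow = nrow(x$a1))
  gt[is.na(x$a1)] <- "./."
  if (has_dp) gt <- matrix(paste0(gt, ":", x$depth), nrow = nrow(gt))
  ref <- map_chr(x$loci$alleles, 1)
  alt <- map_chr(x$loci$alleles, ~ paste(.x[-1], collapse = ","))
  body <- paste(
    x$loci$scaffold, x$loci$position, ".", ref, alt, ".", "PASS", ".", fmt,
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}

#' Read a transect population map
#'
#' The map is a TSV with columns `sample_id`, `deme`, `role`, `altitude_m`,
#' where `role` is one of `lowest`, `lower_middle`, `higher_middle`,
#' `highest`, `reference`. Exactly one deme must carry each of the four
#' altitude roles, with strictly increasing altitudes, and at least one
#' reference deme must be present (reference demes are pooled downstream).
#'
#' @param path Path to the TSV.
#' @return A tibble of class `transect_design` (one row per sample).
#' @export
read_population_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         sample_id = readr::col_character(),
                         deme = readr::col_character(),
                         role = readr::col_character(),
                         altitude_m = readr::col_double()
                       ))
  transect_design(x)
}

#' Validate a transect design
#'
#' @param x Data frame with columns `sample_id`, `deme`, `role`, `altitude_m`.
#' @return `x` as a validated `transect_design` tibble.
#' @export
transect_design <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "deme", "role", "altitude_m")
  if (!all(need %in% names(x))) {
    abort(paste0("population map must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(x$sample_id[duplicated(x$sample_id)]),
                       collapse = ", ")))
  }
  alt_roles <- c("lowest", "lower_middle", "higher_middle", "highest")
  ok_roles <- c(alt_roles, "reference")
  if (!all(x$role %in% ok_roles)) {
    abort(paste0("unknown role(s): ",
                 paste(setdiff(unique(x$role), ok_roles), collapse = ", ")))
  }
  per_deme <- distinct(x, .data$deme, .data$role, .data$altitude_m)
  if (anyDuplicated(per_deme$deme)) {
    abort("each deme must have a single role and altitude")
  }
  for (r in alt_roles) {
    demes_r <- per_deme$deme[per_deme$role == r]
    if (length(demes_r) == 0L) abort(paste0("missing altitude role: ", r))
    if (length(demes_r) > 1L) {
      abort(paste0("role ", r, " assigned to more than one deme: ",
                   paste(demes_r, collapse = ", ")))
    }
  }
  if (!any(per_deme$role == "reference")) {
    abort("missing role: reference (at least one reference deme required)")
  }
  alts <- per_deme$altitude_m[match(alt_roles, per_deme$role)]
  if (any(diff(alts) <= 0)) {
    abort("altitudes must increase strictly from lowest to highest role")
  }
  class(x) <- c("transect_design", class(x))
  x
}

#' Read exon annotation from a BED4 file
#'
#' BED intervals are 0-based half-open and kept in that convention; the
#' conversion to the 1-based SNP coordinate system happens once, at the
#' SNP-gene linkage step. The `name` column is the gene id; several exons may
#' share a gene.
#'
#' @param path Path to a BED4(+) file.
#' @return A tibble with columns `scaffold`, `start`, `end`, `gene_id`,
#'   sorted by (scaffold, start).
#' @export
read_exon_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (ncol(x) < 4L) abort("BED4 required: chrom, start, end, gene id")
  x <- tibble(scaffold = as.character(x[[1]]), start = as.integer(x[[2]]),
              end = as.integer(x[[3]]), gene_id = as.character(x[[4]]))
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(paste0("BED interval with start >= end at line ", bad[1], " (",
                 x$scaffold[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]],
                 ")"))
  }
  arrange(x, .data$scaffold, .data$start, .data$end)
}

#' Read a gene-to-GO-term map
#'
#' TSV with columns `gene_id`, `go_id`, `go_name`; duplicated rows are
#' dropped. Genes absent from the annotation are permitted (the map may be a
#' superset of the genes the scan sees).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `go_id`, `go_name`.
#' @export
read_go_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (nrow(x) == 0L) abort("empty GO map")
  need <- c("gene_id", "go_id", "go_name")
  if (!all(need %in% names(x))) {
    abort(paste0("GO map must have columns: ", paste(need, collapse = ", ")))
  }
  nm <- distinct(x, .data$go_id, .data$go_name)
  if (anyDuplicated(nm$go_id)) {
    abort("a go_id maps to more than one go_name")
  }
  distinct(select(x, dplyr::all_of(need)))
}

#' Write a results table as TSV
#'
#' Numeric columns are rounded to 6 significant digits; row order is kept as
#' given. Optional `header` lines are written as `#`-prefixed comments before
#' the column names (provenance stamps from [run_scan()]).
#'
#' @param x A data frame.
#' @param path Output path.
#' @param header Optional character vector of comment lines.
#' @return Invisibly, `path`.
#' @export
write_scan_table <- function(x, path, header = NULL) {
  x <- mutate(as_tibble(x),
              across(dplyr::where(is.double), ~ signif(.x, 6)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  close(con); on.exit()
  readr::write_tsv(x, path, append = !is.null(header),
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read back a table written by [write_scan_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_scan_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
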