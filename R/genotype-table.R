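#' Construct a genotype table
#'
#' The container for per-sample diploid SNP calls used throughout the scan.
#' Loci are held as a tibble of scaffold coordinates plus an allele list
#' (REF first, then ALT alleles, 2--4 per locus); calls are two integer
#' matrices of 0-based allele indices (`NA` = missing call), with the pair
#' stored unordered (`a1 <= a2`). Read depths are optional.
#'
#' @param loci Tibble with columns `scaffold` (character), `position`
#'   (1-based integer bp) and `alleles` (list of character vectors).
#' @param a1,a2 Integer matrices, loci x samples, of 0-based allele indices.
#' @param samples Character vector of sample ids (column names of the call
#'   matrices).
#' @param depth Optional integer matrix, loci x samples, of read depths.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(loci, a1, a2, samples, depth = NULL) {
  loci <- as_tibble(loci)
  stopifnot(all(c("scaffold", "position", "alleles") %in% names(loci)))
  n_loci <- nrow(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (nrow(a1) != n_loci || nrow(a2) != n_loci ||
      ncol(a1) != length(samples) || ncol(a2) != length(samples)) {
    abort("call matrices must be n_loci x n_samples")
  }
  if (anyDuplicated(samples)) abort("duplicate sample ids")

  ord <- order(loci$scaffold, loci$position)
  if (is.unsorted(ord) || any(ord != seq_len(n_loci))) {
    loci <- loci[ord, ]
    a1 <- a1[ord, , drop = FALSE]
    a2 <- a2[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- as.matrix(depth)[ord, , drop = FALSE]
  }
  dup <- duplicated(loci[c("scaffold", "position")])
  if (any(dup)) {
    abort(paste0("positions must be strictly increasing within a scaffold; ",
                 "duplicated: ", loci$scaffold[dup][1], ":",
                 loci$position[dup][1]))
  }
  n_all <- lengths(loci$alleles)
  if (any(n_all < 2L | n_all > 4L)) {
    bad <- which(n_all < 2L | n_all > 4L)[1]
    abort(paste0("locus ", loci$scaffold[bad], ":", loci$position[bad],
                 " has ", n_all[bad], " alleles (2-4 required)"))
  }
  # normalize the unordered pair and validate indices
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  hi <- pmax(a1, a2, na.rm = FALSE)
  bad_idx <- sweep(hi, 1, n_all, ">=")
  if (any(bad_idx, na.rm = TRUE)) {
    i <- which(rowSums(bad_idx, na.rm = TRUE) > 0)[1]
    abort(paste0("call with allele index >= allele count at ",
                 loci$scaffold[i], ":", loci$position[i]))
  }
  if (xor(is.na(a1), is.na(a2)) |> any()) {
    abort("half-missing genotype calls are not supported")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(a1))) abort("depth matrix dimension mismatch")
    if (any(depth < 0, na.rm = TRUE)) abort("negative read depths")
    colnames(depth) <- samples
  }
  colnames(a1) <- colnames(a2) <- samples
  structure(
    list(loci = loci, a1 = a1, a2 = a2, depth = depth,
         samples = as.character(samples)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  k <- lengths(x$loci$alleles)
  cat("<genotype_table> ", nrow(x$loci), " loci x ", length(x$samples),
      " samples\n", sep = "")
  cat("  scaffolds: ", length(unique(x$loci$scaffold)),
      "; alleles per locus: ", paste0(names(table(k)), "x", table(k),
                                      collapse = ", "),
      "; depths: ", if (is.null(x$depth)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$loci), length(x$samples))

#' Long-format view of a genotype table
#'
#' @param x A [genotype_table()].
#' @param ... Unused.
#' @return A tibble with one row per (locus, sample): scaffold, position,
#'   sample, allele indices `a1`/`a2` and `depth` (NA when absent).
#' @export
as_tibble.genotype_table <- function(x, ...) {
  n_loci <- nrow(x$loci)
  n_smp <- length(x$samples)
  tibble(
    scaffold = rep(x$loci$scaffold, times = n_smp),
    position = rep(x$loci$position, times = n_smp),
    sample = rep(x$samples, each = n_loci),
    a1 = as.vector(x$a1),
    a2 = as.vector(x$a2),
    depth = if (is.null(x$depth)) NA_integer_ else as.vector(x$depth)
  )
}

#' Subset a genotype table by locus
#'
#' @param x A [genotype_table()].
#' @param keep Logical or integer index over loci.
#' @return A `genotype_table` with the selected loci.
#' @export
subset_loci <- function(x, keep) {
  stopifnot(inherits(x, "genotype_table"))
  genotype_table(
    x$loci[keep, ],
    x$a1[keep, , drop = FALSE],
    x$a2[keep, , drop = FALSE],
    x$samples,
    depth = if (is.null(x$depth)) NULL else x$depth[keep, , drop = FALSE]
  )
}
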