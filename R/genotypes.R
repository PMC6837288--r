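#' Genotype matrix with population labels
#'
#' Container for diploid genotype dosages at biallelic SNPs. Dosages count
#' copies of the alternate allele (0, 1, 2); missing genotypes are `NA`.
#'
#' @param dosages integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param sample_ids character vector, one id per row, no duplicates.
#' @param pop_labels character vector, one population label per sample.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, one row
#'   per site (column of `dosages`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, pop_labels, sites) {
  dosages <- as.matrix(dosages)
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length must equal nrow(dosages)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample_ids")
  if (length(pop_labels) != nrow(dosages))
    stop("pop_labels length must equal nrow(dosages)")
  if (!is.data.frame(sites) ||
      !all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop("sites must be a data.frame with chrom, pos, ref, alt")
  if (nrow(sites) != ncol(dosages))
    stop("site count must equal ncol(dosages)")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing dosages must be 0, 1 or 2")
  structure(
    list(dosages = dosages, sample_ids = as.character(sample_ids),
         pop_labels = as.character(pop_labels), sites = sites),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "sites\n")
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$pop_labels)),
                                    table(x$pop_labels)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Per-population allele counts at every site
#'
#' Complete-case summary per site and population: number of called diploids,
#' alternate-allele count and heterozygote count.
#'
#' @param geno a [genotype_matrix()].
#' @param pops populations to tabulate (default: all, in order of first
#'   appearance).
#' @return list with `pops` and, per statistic, a sites x populations matrix:
#'   `n_called`, `alt`, `het`.
#' @export
allele_counts <- function(geno, pops = unique(geno$pop_labels)) {
  d <- geno$dosages
  out_n <- out_alt <- out_het <- matrix(
    0L, ncol(d), length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    rows <- geno$pop_labels == p
    sub <- d[rows, , drop = FALSE]
    out_n[, p] <- colSums(!is.na(sub))
    out_alt[, p] <- colSums(sub, na.rm = TRUE)
    out_het[, p] <- colSums(sub == 1L, na.rm = TRUE)
  }
  list(pops = pops, n_called = out_n, alt = out_alt, het = out_het)
}
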