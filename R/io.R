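#' Read biallelic SNP genotypes from a VCF with a population map
#'
#' Loads GT fields from a VCF (v4.x), keeping biallelic single-nucleotide
#' rows only; multi-allelic and non-SNP rows are skipped and counted.
#' Genotypes are converted to alternate-allele dosages; `./.` becomes
#' missing. Every VCF sample must appear in the population map.
#'
#' @param vcf_path path to a VCF file (plain or gzipped).
#' @param popmap_path TSV with two columns: sample id, population label (no
#'   header).
#' @return a [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf_genotypes <- function(vcf_path, popmap_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  popmap <- utils::read.table(popmap_path, header = FALSE,
                              col.names = c("sample", "pop"),
                              stringsAsFactors = FALSE)
  fix <- vcfR::getFIX(vcf)
  is_snp <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_from_map <- setdiff(samples, popmap$sample)
  if (length(missing_from_map))
    stop("samples absent from popmap: ",
         paste(missing_from_map, collapse = ", "))
  dos <- matrix(NA_integer_, length(samples), nrow(gt))
  gt_clean <- gsub("\\|", "/", gt)
  dos_site <- matrix(NA_integer_, nrow(gt), length(samples))
  dos_site[gt_clean == "0/0"] <- 0L
  dos_site[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos_site[gt_clean == "1/1"] <- 2L
  dos <- t(dos_site)
  rownames(dos) <- samples
  sites <- data.frame(chrom = fix[is_snp, "CHROM"],
                      pos = as.integer(fix[is_snp, "POS"]),
                      ref = fix[is_snp, "REF"], alt = fix[is_snp, "ALT"],
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, samples,
                       popmap$pop[match(samples, popmap$sample)], sites)
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Emits GT-only records (unphased); missing dosages become `./.`.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf_genotypes <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$sample_ids),
                     collapse = "\t")), con)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (s in seq_len(nrow(geno$sites))) {
    d <- geno$dosages[, s]
    gts <- ifelse(is.na(d), "./.", gt_map[as.character(d)])
    writeLines(paste(c(geno$sites$chrom[s], geno$sites$pos[s], ".",
                       geno$sites$ref[s], geno$sites$alt[s], ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a population map TSV
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_popmap <- function(geno, path) {
  utils::write.table(data.frame(geno$sample_ids, geno$pop_labels), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write PBS scan results as TSV
#'
#' Columns: chrom, pos, fst_ab, fst_ac, fst_bc, pbs, outlier; undefined
#' statistics are written as `NA`.
#'
#' @param scan data.frame from [pbs_scan()].
#' @param path output path.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a cline dataset TSV
#'
#' Columns: `locality`, `elevation_m`, `allele_H_count`, `total_alleles`.
#'
#' @param path TSV path.
#' @return a [cline_dataset()].
#' @export
read_cline_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("locality", "elevation_m", "allele_H_count", "total_alleles")
  if (!all(need %in% names(d)))
    stop("cline TSV must have columns: ", paste(need, collapse = ", "))
  out <- cline_dataset(d$elevation_m, d$allele_H_count, d$total_alleles,
                       d$locality)
  extra <- setdiff(names(d), need)
  for (e in extra) out[[e]] <- d[[e]]
  out
}

#' @rdname read_cline_tsv
#' @param data a [cline_dataset()].
#' @export
write_cline_tsv <- function(data, path) {
  out <- data.frame(locality = data$locality, elevation_m = data$elevation,
                    allele_H_count = data$k, total_alleles = data$total)
  extra <- setdiff(names(data), c("locality", "elevation", "k", "total"))
  for (e in extra) out[[e]] <- data[[e]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a site-frequency spectrum in the flat-text dialect
#'
#' The interoperable flat format: a header line with the spectrum dimensions
#' and `folded`/`unfolded`, one line of row-major values, one line of 0/1
#' mask flags (1 = masked).
#'
#' @param sfs matrix with attribute `mask`.
#' @param path file path.
#' @export
write_sfs <- function(sfs, path) {
  mask <- attr(sfs, "mask")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(sfs), ncol(sfs))
  folded <- if (isTRUE(attr(sfs, "folded")) || any(mask[nrow(mask), ]))
    "folded" else "unfolded"
  lines <- c(paste(c(dim(sfs), folded), collapse = " "),
             paste(format(t(sfs), digits = 17, trim = TRUE, scientific = FALSE),
                   collapse = " "),
             paste(as.integer(t(mask)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1])
  d2 <- as.integer(hdr[2])
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  msk <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  out <- matrix(vals, d1, d2, byrow = TRUE)
  attr(out, "mask") <- matrix(msk == 1L, d1, d2, byrow = TRUE)
  attr(out, "folded") <- identical(hdr[3], "folded")
  out
}

#' Read a gene set (one id per line)
#' @param path text file path.
#' @return character vector of ids.
#' @export
read_gene_set <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' Write a JSON sidecar with run metadata
#'
#' Every pipeline output gets a `<file>.json` sidecar recording the package
#' version, seed and configuration used, so that runs are reproducible from
#' their artifacts.
#'
#' @param path path of the artifact the sidecar describes.
#' @param config list of run parameters (seed included).
#' @export
write_json_sidecar <- function(path, config) {
  meta <- list(
    package = "altadapt",
    version = as.character(utils::packageVersion("altadapt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paste0(path, ".json"))
}

#' Run a pipeline stage from a configuration list
#'
#' Dispatches the analysis stages on a `subcommand` field and writes the
#' stage's artifacts plus JSON sidecars into `out_dir`. Available
#' subcommands: `simulate-data` (synthetic VCF + popmap), `scan` (PBS scan
#' TSV), `simulate-null` (neutral PBS null TSV), `fit-demography` (folded
#' 2D-SFS text + fit JSON), `fit-cline` (posterior samples TSV + summary
#' JSON), `geneset-test` (result JSON + null TSV).
#'
#' @param config named list; must contain `subcommand`, `out_dir` and the
#'   stage's parameters (see the package vignette). A `seed` entry seeds the
#'   RNG and is recorded in every sidecar.
#' @return invisible character vector of files written.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand
  out_dir <- config$out_dir
  if (is.null(sub) || is.null(out_dir))
    stop("config must contain subcommand and out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  files <- character(0)
  wp <- function(f) file.path(out_dir, f)

  if (sub == "simulate-data") {
    model <- do.call(demographic_model, config$model)
    ds <- gen_scan_dataset(model, unlist(config$sample_diploids),
                           config$n_neutral,
                           config$n_selected %||% 0,
                           config$displacement %||% 0)
    write_vcf_genotypes(ds$geno, wp("genotypes.vcf"))
    write_popmap(ds$geno, wp("popmap.tsv"))
    writeLines(ds$truth, wp("truth.txt"))
    files <- c(wp("genotypes.vcf"), wp("popmap.tsv"), wp("truth.txt"))
  } else if (sub == "scan") {
    geno <- read_vcf_genotypes(config$vcf, config$popmap)
    null_pbs <- if (!is.null(config$null_tsv))
      utils::read.table(config$null_tsv, header = TRUE)$pbs else NULL
    scan <- pbs_scan(geno, config$focal, config$out1, config$out2,
                     max_missing = config$max_missing %||% 0.5,
                     threshold_q = config$threshold_q %||% 0.999,
                     null_pbs = null_pbs)
    write_scan_tsv(scan, wp("scan.tsv"))
    files <- wp("scan.tsv")
  } else if (sub == "simulate-null") {
    model <- if (is.null(config$model)) deer_mouse_model()
      else do.call(demographic_model, config$model)
    null <- simulate_null_pbs(model, config$n_snps,
                              unlist(config$sample_diploids))
    utils::write.table(data.frame(pbs = null$pbs), wp("null_pbs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- wp("null_pbs.tsv")
  } else if (sub == "fit-demography") {
    geno <- read_vcf_genotypes(config$vcf, config$popmap)
    sfs <- build_folded_2dsfs(geno, config$pop_a, config$pop_b,
                              unlist(config$projection),
                              max_missing = config$max_missing %||% 0.25)
    fit <- fit_demography(sfs, config$model_family %||% "one_mig",
                          n_restarts = config$n_restarts %||% 25,
                          mc_sims = config$mc_sims %||% 2000)
    write_sfs(sfs, wp("folded_2dsfs.fs"))
    jsonlite::write_json(
      list(family = fit$family, par = as.list(fit$par),
           theta = fit$theta_hat, loglik = fit$loglik,
           converged = fit$converged),
      wp("demography_fit.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    files <- c(wp("folded_2dsfs.fs"), wp("demography_fit.json"))
  } else if (sub == "fit-cline") {
    data <- read_cline_tsv(config$cline_tsv)
    fit <- fit_cline(data, variant = config$variant %||% "free_none",
                     chain_length = config$chain_length %||% 1e5,
                     burn_in = config$burn_in %||% 1e4)
    utils::write.table(fit$samples, wp("cline_posterior.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(variant = fit$variant, map = as.list(fit$map),
           ci = as.data.frame(fit$ci), acceptance = fit$acceptance,
           aicc = fit$aicc),
      wp("cline_summary.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    files <- c(wp("cline_posterior.tsv"), wp("cline_summary.json"))
  } else if (sub == "geneset-test") {
    counts <- as.matrix(utils::read.table(config$counts_tsv, header = TRUE,
                                          row.names = 1, sep = "\t",
                                          check.names = FALSE))
    groups <- utils::read.table(config$groups_tsv, header = FALSE,
                                stringsAsFactors = FALSE)[[2]]
    cand <- read_gene_set(config$gene_set)
    res <- geneset_shift_test(counts, groups, cand,
                              contrast = config$contrast %||% c("HH", "LL"),
                              n_perm = config$n_perm %||% 1000)
    utils::write.table(data.frame(null_d = res$null_d),
                       wp("geneset_null.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(set_size = res$set_size, D = res$D, sign = res$sign,
           q99 = res$q99, decision = res$decision,
           p_permutation = res$p_permutation,
           p_asymptotic = res$p_asymptotic),
      wp("geneset_result.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    files <- c(wp("geneset_null.tsv"), wp("geneset_result.json"))
  } else {
    stop("unknown subcommand: ", sub)
  }
  for (f in files) write_json_sidecar(f, config)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
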