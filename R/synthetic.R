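#' Synthetic exome-scan genotype dataset
#'
#' Generates a genotype matrix with the statistical structure the PBS scan
#' assumes: neutral SNPs are drawn from the structured coalescent under the
#' supplied demographic model (mixing the two migration-rate classes), and
#' "selected" SNPs are produced by displacing the focal deme's allele
#' frequency of additional neutral draws by a fixed amount and re-sampling
#' genotypes binomially — PBS responds to allele-frequency differentiation
#' directly, so this injects a selection-like signal without committing to a
#' selection model. Truth labels are recorded per site.
#'
#' @param model a [demographic_model()].
#' @param sample_diploids named diploid sample sizes per deme.
#' @param n_neutral,n_selected site counts.
#' @param displacement focal-deme allele-frequency displacement in `[0, 1]`
#'   applied to selected sites (toward fixation of the derived allele).
#' @param focal focal deme name (default: first sampled deme).
#' @param pos_spacing base-pair spacing between consecutive sites.
#' @param seed optional seed (recorded in the output).
#' @return list with `geno` (a [genotype_matrix()]) and `truth` (character
#'   vector, `"neutral"`/`"selected"`).
#' @export
gen_scan_dataset <- function(model, sample_diploids, n_neutral,
                             n_selected = 0, displacement = 0,
                             focal = NULL, pos_spacing = 10000,
                             seed = NULL) {
  if (displacement < 0 || displacement > 1)
    stop("displacement must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  dip <- .match_samples(model, sample_diploids)
  demes <- names(dip)[dip > 0]
  if (is.null(focal)) focal <- demes[1]
  hap <- dip * 2L

  draw_haplotypes <- function(n) {
    if (n == 0)
      return(matrix(0L, 0, sum(hap)))
    n_high <- stats::rbinom(1, n, model$p_high)
    out <- list()
    for (cls in c("high", "low")) {
      nn <- if (cls == "high") n_high else n - n_high
      if (nn == 0) next
      a <- .sim_args(model, cls)
      out[[cls]] <- .sim_haplotypes_cpp(a$deme_sizes, a$mig, a$split_times,
                                        a$split_from, a$split_to,
                                        a$split_parent_sizes, hap,
                                        as.integer(nn), FALSE)
    }
    do.call(rbind, out)
  }

  hap_to_dosage <- function(h) {
    # columns are haploids grouped by deme; pair consecutive into diploids
    odd <- seq(1, ncol(h), by = 2)
    h[, odd, drop = FALSE] + h[, odd + 1, drop = FALSE]
  }

  neutral <- hap_to_dosage(draw_haplotypes(n_neutral))

  selected <- matrix(0L, 0, sum(dip))
  if (n_selected > 0 && displacement == 0) {
    # zero displacement is a no-op: the draws are used as they are, so the
    # "selected" sites are exactly exchangeable with neutral ones
    selected <- hap_to_dosage(draw_haplotypes(n_selected))
  } else if (n_selected > 0) {
    base <- draw_haplotypes(n_selected)
    col0 <- c(0, cumsum(hap))
    freqs <- sapply(seq_along(hap), function(d) {
      if (hap[d] == 0) return(rep(0, n_selected))
      rowMeans(base[, (col0[d] + 1):(col0[d] + hap[d]), drop = FALSE])
    })
    freqs <- matrix(freqs, nrow = n_selected)
    colnames(freqs) <- names(hap)
    freqs[, focal] <- pmin(1, freqs[, focal] + displacement)
    selected <- matrix(0L, n_selected, sum(dip))
    dcol0 <- c(0, cumsum(dip))
    for (d in seq_along(dip)) {
      if (dip[d] == 0) next
      cols <- (dcol0[d] + 1):(dcol0[d] + dip[d])
      selected[, cols] <- stats::rbinom(n_selected * dip[d], 2,
                                        rep(freqs[, d], dip[d]))
    }
  }

  dos <- rbind(neutral, selected)
  n_sites <- nrow(dos)
  samp_ids <- unlist(lapply(names(dip)[dip > 0], function(d)
    paste0(d, "_", seq_len(dip[d]))))
  pop_labels <- rep(names(dip)[dip > 0], dip[dip > 0])
  sites <- data.frame(chrom = "1",
                      pos = seq_len(n_sites) * pos_spacing,
                      ref = "A", alt = "T")
  g <- genotype_matrix(t(dos), samp_ids, pop_labels, sites)
  truth <- c(rep("neutral", n_neutral), rep("selected", n_selected))
  list(geno = g, truth = truth,
       config = list(displacement = displacement, focal = focal,
                     seed = seed))
}

#' Synthetic allele-frequency transect along an elevational cline
#'
#' Draws per-locality focal-allele counts `k ~ Binomial(total, p(x))` with
#' `p` given by [cline_frequency()] at the supplied elevations.
#'
#' @param elevations locality elevations (m).
#' @param params cline parameters (see [cline_frequency()]).
#' @param alleles_per_site total alleles per locality (scalar or vector).
#' @param seed optional seed.
#' @return a [cline_dataset()] with attribute `config`.
#' @export
gen_cline_dataset <- function(elevations, params, alleles_per_site,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- rep_len(alleles_per_site, length(elevations))
  p <- cline_frequency(elevations, params)
  k <- stats::rbinom(length(elevations), total, p)
  out <- cline_dataset(elevations, k, total)
  attr(out, "config") <- list(params = params, seed = seed)
  out
}

#' Synthetic negative-binomial expression counts with a shifted gene set
#'
#' Gene baseline means are log-normal; counts are negative binomial with a
#' common dispersion. A designated candidate gene set carries a concerted
#' log2 fold-change between genotype groups: group codes are LL = 0,
#' HL = 0.5, HH = 1, so `shift` equals the injected HH-vs-LL log2
#' fold-change (heterozygotes halfway, an additive allele-dosage effect).
#'
#' @param n_genes total genes.
#' @param group_sizes named sample counts, e.g. `c(LL = 3, HL = 8, HH = 8)`
#'   (the study's genotype-group sizes).
#' @param candidate_size size of the shifted candidate set.
#' @param shift injected HH-vs-LL log2 fold-change.
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param meanlog,sdlog log-normal parameters of baseline means.
#' @param seed optional seed.
#' @return list with `counts` (genes x samples, gene ids `g1..`),
#'   `groups`, `candidate_ids`, `config`.
#' @export
gen_expression_counts <- function(n_genes = 5000,
                                  group_sizes = c(LL = 3, HL = 8, HH = 8),
                                  candidate_size = 80, shift = 0,
                                  dispersion = 0.1, meanlog = 4,
                                  sdlog = 1.2, seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(names(group_sizes), group_sizes)
  code <- c(LL = 0, HL = 0.5, HH = 1)[groups]
  code[is.na(code)] <- 0
  mu0 <- stats::rlnorm(n_genes, meanlog, sdlog)
  cand <- paste0("g", sample.int(n_genes, candidate_size))
  genes <- paste0("g", seq_len(n_genes))
  is_cand <- genes %in% cand
  lfc_gene <- ifelse(is_cand, shift, 0)
  mu <- outer(mu0, rep(1, length(groups))) *
    2^(lfc_gene %o% code)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / dispersion),
                   n_genes, length(groups),
                   dimnames = list(genes,
                                   paste0(groups, "_",
                                          seq_along(groups))))
  list(counts = counts, groups = groups, candidate_ids = cand,
       config = list(n_genes = n_genes, group_sizes = group_sizes,
                     candidate_size = candidate_size, shift = shift,
                     dispersion = dispersion, seed = seed))
}
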