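#' Weir-Cockerham FST variance components at one or more sites
#'
#' Computes the two-population Weir & Cockerham (1984) variance components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), and the per-site estimator
#' `theta = a / (a + b + c)`. All arguments are vectorized over sites.
#'
#' `theta` is `NA` (undefined) when the site is monomorphic across both
#' populations, when `a + b + c = 0`, or when the average sample size does not
#' exceed one diploid.
#'
#' @param n1,n2 called diploids per population.
#' @param alt1,alt2 alternate-allele counts (0 .. 2n).
#' @param het1,het2 heterozygote counts.
#' @return data.frame with columns `a`, `b`, `c`, `theta`.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
weir_fst_site <- function(n1, alt1, het1, n2, alt2, het2) {
  .check_counts(n1, alt1, het1)
  .check_counts(n2, alt2, het2)
  p1 <- alt1 / (2 * n1)
  p2 <- alt2 / (2 * n2)
  h1 <- het1 / n1
  h2 <- het2 / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- a / denom
  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  theta[mono | denom == 0 | nbar <= 1 | !is.finite(denom)] <- NA_real_
  data.frame(a = a, b = b, c = cc, theta = theta)
}

.check_counts <- function(n, alt, het) {
  if (any(n < 0) || any(alt < 0) || any(het < 0))
    stop("negative counts")
  if (any(alt > 2 * n))
    stop("alt count exceeds 2 * n_called")
  if (any(het > n) || any(het > alt) || any(het > 2 * n - alt))
    stop("heterozygote count inconsistent with allele counts")
  invisible(TRUE)
}

#' Multi-site FST summaries
#'
#' Headline estimate is the mean and standard error of per-site `theta` over
#' sites where it is defined; the ratio-of-sums (variance-component weighted)
#' estimator `sum(a) / sum(a + b + c)` is returned alongside.
#'
#' @param components data.frame from [weir_fst_site()].
#' @return list with `mean_theta`, `sem_theta`, `weighted_theta`, `n_sites`.
#' @export
multi_site_fst <- function(components) {
  ok <- !is.na(components$theta)
  if (!any(ok)) stop("no sites with defined theta")
  th <- components$theta[ok]
  sem <- if (length(th) > 1) stats::sd(th) / sqrt(length(th)) else 0
  list(mean_theta = mean(th), sem_theta = sem,
       weighted_theta = sum(components$a[ok]) /
         sum(components$a[ok] + components$b[ok] + components$c[ok]),
       n_sites = length(th))
}

#' Population branch statistic from three pairwise FST values
#'
#' Branch lengths are `T = -ln(1 - FST)` and the focal-population branch is
#' `PBS = (T_ab + T_ac - T_bc) / 2`, where population `a` is focal and `b`,
#' `c` are the two outgroups. Negative FST is floored at 0 before the log
#' transform (undefined variance partitions are treated likewise); FST at or
#' above `1 - clamp` is clamped to keep branch lengths finite. PBS itself is
#' not floored: negative values are retained.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise FST values (vectorized).
#' @param clamp upper clamp distance from 1 (default `1e-12`).
#' @return data.frame with `t_ab`, `t_ac`, `t_bc`, `pbs`.
#' @references Yi X et al. (2010) Sequencing of 50 human exomes reveals
#'   adaptation to high altitude. Science 329:75-78.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, clamp = 1e-12) {
  fix <- function(f) {
    f[is.na(f)] <- 0
    f[f < 0] <- 0
    if (any(f > 1 + 1e-9)) stop("FST above 1")
    pmin(f, 1 - clamp)
  }
  t_ab <- -log(1 - fix(fst_ab))
  t_ac <- -log(1 - fix(fst_ac))
  t_bc <- -log(1 - fix(fst_bc))
  data.frame(t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
             pbs = (t_ab + t_ac - t_bc) / 2)
}

#' Linkage disequilibrium as squared genotype correlation
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' observations, the `r^2` of vcftools' `--geno-r2`.
#'
#' @param dosages1,dosages2 dosage vectors of equal length (`NA` = missing).
#' @return `r^2` in `[0, 1]`, or `NA` if fewer than two complete pairs remain
#'   or either site is monomorphic among them.
#' @export
ld_r2 <- function(dosages1, dosages2) {
  if (length(dosages1) != length(dosages2))
    stop("dosage vectors must have equal length")
  ok <- !is.na(dosages1) & !is.na(dosages2)
  x <- dosages1[ok]
  y <- dosages2[ok]
  if (length(x) < 2) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Levene's exact conditional test: given the allele counts, the two-sided
#' p-value is the sum of probabilities of all heterozygote counts (with the
#' same allele-count margins and parity) whose conditional probability does
#' not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact two-sided p-value.
#' @references Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact
#'   tests of Hardy-Weinberg equilibrium. Am J Hum Genet 76:887-893.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped diploid required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Empirical quantile threshold (left-continuous ECDF convention)
#'
#' The smallest observed value `v` such that `ecdf(v) >= q`; with the sorted
#' sample this is element `ceiling(q * n)`.
#'
#' @param values non-empty numeric vector.
#' @param q quantile level in (0, 1).
#' @return threshold value.
#' @export
quantile_threshold <- function(values, q) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  sort(values)[max(1L, ceiling(q * length(values)))]
}

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability `P(X >= overlap)` of the overlap between a gene set
#' and a category drawn from a finite universe — the one-sided Fisher exact
#' test for a 2x2 table.
#'
#' @param overlap observed overlap.
#' @param set_size,category_size,universe_size set sizes.
#' @return one-sided p-value.
#' @export
hypergeom_enrichment <- function(overlap, set_size, category_size,
                                 universe_size) {
  if (overlap > min(set_size, category_size))
    stop("overlap exceeds the smaller set")
  if (set_size > universe_size || category_size > universe_size)
    stop("set sizes exceed universe")
  if (any(c(overlap, set_size, category_size, universe_size) < 0))
    stop("negative counts")
  stats::phyper(overlap - 1, category_size, universe_size - category_size,
                set_size, lower.tail = FALSE)
}

#' PBS selection scan over a genotype matrix
#'
#' Per-site pipeline: complete-case allele counts per population, pairwise
#' Weir-Cockerham FST, PBS for the focal population, and an outlier flag
#' against either the empirical PBS distribution or a supplied neutral null.
#'
#' A site is usable when every population has at least one called diploid and
#' per-population missingness is at most `max_missing`. Undefined FST is
#' floored at 0 inside [pbs()].
#'
#' @param geno a [genotype_matrix()].
#' @param focal focal population label (branch tested for divergence).
#' @param out1,out2 the two outgroup population labels.
#' @param max_missing per-population missingness ceiling (default 0.5).
#' @param hwe_p if non-`NULL`, drop sites whose pooled-sample HWE exact test
#'   p-value is below this cutoff.
#' @param threshold_q quantile for the outlier flag (default 0.999).
#' @param null_pbs optional numeric vector of simulated neutral PBS values;
#'   when given, the threshold is taken from this null instead of the
#'   empirical distribution.
#' @return data.frame (one row per usable site): `chrom`, `pos`, `fst_ab`,
#'   `fst_ac`, `fst_bc`, `pbs`, `outlier`, plus attribute `threshold`.
#' @export
pbs_scan <- function(geno, focal, out1, out2, max_missing = 0.5,
                     hwe_p = NULL, threshold_q = 0.999, null_pbs = NULL) {
  pops <- c(focal, out1, out2)
  if (!all(pops %in% geno$pop_labels))
    stop("populations not present: ",
         paste(setdiff(pops, geno$pop_labels), collapse = ", "))
  ac <- allele_counts(geno, pops)
  n_pop <- vapply(pops, function(p) sum(geno$pop_labels == p), 0L)
  use <- rep(TRUE, nrow(ac$n_called))
  for (p in pops)
    use <- use & ac$n_called[, p] >= 1 &
      (1 - ac$n_called[, p] / n_pop[[p]]) <= max_missing
  if (!is.null(hwe_p)) {
    n_tot <- rowSums(ac$n_called)
    het_tot <- rowSums(ac$het)
    alt_tot <- rowSums(ac$alt)
    hom_alt <- (alt_tot - het_tot) / 2
    pvals <- vapply(seq_along(n_tot), function(i) {
      hwe_exact_test(n_tot[i] - het_tot[i] - hom_alt[i], het_tot[i],
                     hom_alt[i])
    }, 0)
    use <- use & pvals >= hwe_p
  }
  idx <- which(use)
  f <- function(pa, pb)
    weir_fst_site(ac$n_called[idx, pa], ac$alt[idx, pa], ac$het[idx, pa],
                  ac$n_called[idx, pb], ac$alt[idx, pb], ac$het[idx, pb])$theta
  fst_ab <- f(focal, out1)
  fst_ac <- f(focal, out2)
  fst_bc <- f(out1, out2)
  pb <- pbs(fst_ab, fst_ac, fst_bc)
  thr_src <- if (is.null(null_pbs)) pb$pbs else null_pbs
  thr <- quantile_threshold(thr_src, threshold_q)
  out <- data.frame(chrom = geno$sites$chrom[idx], pos = geno$sites$pos[idx],
                    fst_ab = fst_ab, fst_ac = fst_ac, fst_bc = fst_bc,
                    pbs = pb$pbs, outlier = pb$pbs > thr)
  attr(out, "threshold") <- thr
  attr(out, "threshold_source") <-
    if (is.null(null_pbs)) "empirical" else "simulated"
  out
}
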