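# Independent oracles used across the test files. These deliberately use
# different code paths (scalar, equation-by-equation, brute force) from the
# package implementations they check.

# Literal scalar transcription of the Weir & Cockerham (1984) two-population
# variance components, written equation by equation from the published
# definitions (r = 2 populations). Inputs: diploid sample sizes, alternate
# allele frequencies, heterozygote frequencies.
wc84_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nC <- (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nC) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Full enumeration of the Levene conditional distribution of heterozygote
# counts given the allele-count margins, using plain products of integers
# (no log-factorial shortcut); returns the exact two-sided p-value.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  weight <- sapply(hets, function(h) {
    nAA <- (nA - h) / 2
    naa <- (na - h) / 2
    # multinomial arrangement count x 2^h, computed multiplicatively
    exp(sum(log(seq_len(n))) - sum(log(seq_len(max(nAA, 1))[seq_len(nAA)])) -
          sum(log(seq_len(max(h, 1))[seq_len(h)])) -
          sum(log(seq_len(max(naa, 1))[seq_len(naa)])) + h * log(2))
  })
  prob <- weight / sum(weight)
  obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Brute-force two-sample K-S D: evaluate both ECDFs at every pooled point.
ks_d_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# Tabulate joint derived-allele counts from a simulate_snps() result into an
# unfolded 2D count matrix (first two sampled demes).
count_sfs_2d <- function(derived, n1, n2) {
  raw <- matrix(0, n1 + 1, n2 + 1)
  for (i in seq_len(nrow(derived)))
    raw[derived[i, 1] + 1, derived[i, 2] + 1] <-
      raw[derived[i, 1] + 1, derived[i, 2] + 1] + 1
  raw
}

# Small genotype_matrix fixture: `freqs` is a sites x pops matrix of allele
# frequencies; dosages drawn binomially.
make_geno <- function(freqs, n_per_pop, pops = colnames(freqs),
                      pos = NULL) {
  n_sites <- nrow(freqs)
  dos <- NULL
  labels <- character()
  for (j in seq_along(pops)) {
    d <- matrix(stats::rbinom(n_sites * n_per_pop[j], 2,
                              rep(freqs[, j], each = n_per_pop[j])),
                nrow = n_per_pop[j])
    dos <- rbind(dos, d)
    labels <- c(labels, rep(pops[j], n_per_pop[j]))
  }
  if (is.null(pos)) pos <- seq_len(n_sites) * 10000L
  genotype_matrix(dos, paste0("s", seq_len(nrow(dos))), labels,
                  data.frame(chrom = "1", pos = pos, ref = "A", alt = "T"))
}

# Frozen oracle: expected joint branch-length SFS for a two-deme
# isolation-with-migration configuration (demes of 1000 diploids, ancestral
# 1000, split 2000 generations ago, symmetric migration of 1 migrant per
# generation, 6+6 sampled haploids), computed once with an independent
# established coalescent simulator (50,000 replicates, branch mode) and
# normalized over segregating cells. Stored column-major.
msp_im_sfs <- matrix(c(
  0.000000, 0.199969, 0.063529, 0.024601, 0.009321, 0.003320, 0.000754,
  0.200734, 0.055197, 0.031209, 0.017697, 0.009514, 0.004408, 0.001774,
  0.063739, 0.031395, 0.021271, 0.015191, 0.010174, 0.006082, 0.002855,
  0.024079, 0.017654, 0.015062, 0.012141, 0.010032, 0.007140, 0.004486,
  0.009225, 0.009801, 0.010107, 0.010028, 0.009141, 0.008053, 0.006610,
  0.003338, 0.004376, 0.005916, 0.007262, 0.008294, 0.008526, 0.009809,
  0.000821, 0.001680, 0.002875, 0.004554, 0.006680, 0.009575, 0.000000),
  nrow = 7, ncol = 7)
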