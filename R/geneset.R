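#' Filter genes by mean library-size-normalized count
#'
#' Retains genes whose mean normalized count — raw count divided by library
#' size and rescaled by the mean library size — is at least `min_mean_norm`
#' reads per individual (default 10, the usual low-expression cutoff for
#' 3'-tag count data).
#'
#' @param counts integer matrix, genes x samples.
#' @param min_mean_norm retention threshold (default 10).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_mean_norm = 10) {
  if (ncol(counts) < 1) stop("need at least one sample")
  lib <- colSums(counts)
  norm <- sweep(counts, 2, lib, "/") * mean(lib)
  keep <- rowMeans(norm) >= min_mean_norm
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no genes pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' TMM effective scaling factors
#'
#' Per-sample scaling factors combining library size with the
#' trimmed-mean-of-M-values composition correction (Robinson & Oshlack
#' 2010: reference = library whose upper quartile is closest to the mean
#' upper quartile, 30% M-trim, 5% A-trim, via \code{edgeR::calcNormFactors},
#' the implementation used on the original TagSeq data). The returned
#' factors are `library size x TMM factor`, rescaled to geometric mean 1;
#' dividing each column by its factor puts all libraries on the
#' geometric-mean effective depth. A library exactly double another (same
#' composition) therefore gets double the factor.
#'
#' @param counts integer matrix, genes x samples (>= 2 samples).
#' @return numeric vector of per-sample effective scaling factors
#'   (geometric mean 1).
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  f <- as.numeric(edgeR::calcNormFactors(as.matrix(counts), method = "TMM"))
  eff <- colSums(counts) * f
  eff / exp(mean(log(eff)))
}

#' Log2 fold-changes between genotype groups
#'
#' Per gene, `log2((mean_a + prior) / (mean_b + prior))` of effective-library
#' normalized counts (library size times TMM factor, rescaled to the mean
#' effective size), where `a` and `b` are the two genotype groups of the
#' contrast. The prior count (default 0.5) keeps all values finite.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups factor/character vector of genotype labels per sample.
#' @param contrast length-2 character vector `c(group_a, group_b)`; the
#'   returned value is positive when expression is higher in `group_a`.
#' @param prior_count pseudocount added to both group means (in
#'   geometric-mean-library count units).
#' @param norm_factors optional precomputed effective scaling factors as
#'   returned by [tmm_factors()] (default: computed).
#' @return named numeric vector of log2 fold-changes (one per gene) with
#'   attribute `mean_norm` (mean normalized abundance).
#' @export
log_fold_change <- function(counts, groups, contrast, prior_count = 0.5,
                            norm_factors = NULL) {
  if (length(contrast) != 2) stop("contrast must name two groups")
  if (!all(contrast %in% groups))
    stop("contrast groups absent: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  norm <- sweep(counts, 2, norm_factors, "/")
  ma <- rowMeans(norm[, groups == contrast[1], drop = FALSE])
  mb <- rowMeans(norm[, groups == contrast[2], drop = FALSE])
  out <- log2((ma + prior_count) / (mb + prior_count))
  names(out) <- rownames(counts)
  attr(out, "mean_norm") <- rowMeans(norm)
  out
}

# exact two-sample K-S D on raw vectors (handles ties)
.ks_d <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pool <- c(x, y)
  z <- c(rep(1L, n), rep(0L, m))
  o <- order(pool)
  pool <- pool[o]
  z <- z[o]
  fx <- cumsum(z) / n
  fy <- cumsum(1 - z) / m
  keep <- c(pool[-1] != pool[-length(pool)], TRUE)  # last index of each value
  max(abs(fx[keep] - fy[keep]))
}

# asymptotic two-sided two-sample K-S p-value (Kolmogorov distribution,
# evaluated at sqrt(n*m/(n+m)) * D)
.ks_p_asymptotic <- function(d, n, m) {
  lambda <- sqrt(n * m / (n + m)) * d
  if (lambda < 1e-3) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Signed two-sample Kolmogorov-Smirnov shift statistic
#'
#' `D = sup |F_candidate - F_background|` between the log fold-change
#' distributions of a candidate gene set and the transcriptome background
#' (candidates excluded), signed by the difference of medians, with the
#' asymptotic two-sided p-value.
#'
#' @param candidate_lfc,background_lfc numeric vectors; if both are named,
#'   shared names raise an error (the background must exclude candidates).
#' @return list with `D`, `sign` (+1, -1 or 0) and `p_asymptotic`.
#' @export
ks_shift <- function(candidate_lfc, background_lfc) {
  if (!length(candidate_lfc) || !length(background_lfc))
    stop("both vectors must be non-empty")
  if (!is.null(names(candidate_lfc)) && !is.null(names(background_lfc)) &&
      length(intersect(names(candidate_lfc), names(background_lfc))))
    stop("background must exclude candidate genes")
  d <- .ks_d(candidate_lfc, background_lfc)
  list(D = d,
       sign = sign(stats::median(candidate_lfc) -
                     stats::median(background_lfc)),
       p_asymptotic = .ks_p_asymptotic(d, length(candidate_lfc),
                                       length(background_lfc)))
}

#' Permutation null distribution of the K-S D statistic
#'
#' Draws `n_perm` uniform random gene sets of size `set_size` from all
#' genes and scores each against the remaining genes, giving the null
#' distribution of D under no concerted shift; the decision threshold is its
#' 99% quantile (left-continuous ECDF convention).
#'
#' @param all_lfc named numeric vector of log fold-changes for every
#'   retained gene.
#' @param set_size candidate-set size to match.
#' @param n_perm number of random draws (default 1000, >= 100).
#' @return list with `null_d` (length `n_perm`) and `q99`.
#' @export
permutation_null <- function(all_lfc, set_size, n_perm = 1000) {
  n <- length(all_lfc)
  if (set_size >= n) stop("set_size must be smaller than the gene count")
  if (n_perm < 100) stop("n_perm must be at least 100")
  o <- order(all_lfc)
  sorted <- all_lfc[o]
  keep <- c(sorted[-1] != sorted[-n], TRUE)
  rank_of <- integer(n)
  rank_of[o] <- seq_len(n)
  null_d <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, set_size)
    z <- logical(n)
    z[rank_of[idx]] <- TRUE
    fx <- cumsum(z) / set_size
    fy <- cumsum(!z) / (n - set_size)
    null_d[b] <- max(abs(fx[keep] - fy[keep]))
  }
  list(null_d = null_d, q99 = quantile_threshold(null_d, 0.99))
}

#' Gene-set expression-shift test with a permutation null
#'
#' Full pipeline for detecting a concerted shift in a candidate gene set's
#' expression between genotype groups: low-expression filtering, TMM
#' normalization, per-gene log2 fold-changes for the contrast, the signed
#' K-S D of the candidate set against the background (candidates excluded),
#' and a permutation null from equal-size random gene sets. The decision
#' flag is `D > q99` of the null.
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids).
#' @param groups genotype label per sample (e.g. `"LL"`, `"HL"`, `"HH"`).
#' @param candidate_ids gene ids of the candidate set.
#' @param contrast length-2 groups, as in [log_fold_change()].
#' @param n_perm permutation draws (default 1000).
#' @param min_mean_norm expression filter threshold (default 10).
#' @param prior_count fold-change pseudocount (default 0.5).
#' @return object of class `geneset_shift`.
#' @export
geneset_shift_test <- function(counts, groups, candidate_ids,
                               contrast = c("HH", "LL"), n_perm = 1000,
                               min_mean_norm = 10, prior_count = 0.5) {
  if (is.null(rownames(counts))) stop("counts must have gene-id rownames")
  filtered <- filter_low_expression(counts, min_mean_norm)
  dropped <- setdiff(candidate_ids, rownames(filtered))
  kept_ids <- intersect(candidate_ids, rownames(filtered))
  if (length(kept_ids) < 2)
    stop("fewer than 2 candidate genes retained after filtering")
  lfc <- log_fold_change(filtered, groups, contrast,
                         prior_count = prior_count)
  is_cand <- names(lfc) %in% kept_ids
  obs <- ks_shift(lfc[is_cand], lfc[!is_cand])
  # draw the permutation null on name-sorted fold-changes so the result does
  # not depend on the input gene order
  null <- permutation_null(lfc[order(names(lfc))], sum(is_cand), n_perm)
  structure(
    list(set_size = sum(is_cand), dropped_ids = dropped, D = obs$D,
         sign = obs$sign, p_asymptotic = obs$p_asymptotic,
         null_d = null$null_d, q99 = null$q99,
         p_permutation = mean(null$null_d >= obs$D),
         decision = obs$D > null$q99, contrast = contrast,
         n_perm = n_perm, lfc = lfc, candidate = is_cand),
    class = "geneset_shift")
}

#' @export
print.geneset_shift <- function(x, ...) {
  dir <- if (x$sign > 0) "upward" else if (x$sign < 0) "downward" else "no"
  cat(sprintf(
    "geneset_shift: %d candidate genes, contrast %s vs %s\n", x$set_size,
    x$contrast[1], x$contrast[2]))
  cat(sprintf(
    "D = %.4f (%s shift), null 99%% quantile = %.4f -> %s\n", x$D, dir,
    x$q99, if (x$decision) "concerted shift detected" else "no call"))
  cat(sprintf("permutation p = %.4g, asymptotic K-S p = %.4g\n",
              x$p_permutation, x$p_asymptotic))
  if (length(x$dropped_ids))
    cat("candidates dropped by the expression filter:",
        length(x$dropped_ids), "\n")
  invisible(x)
}

#' @export
summary.geneset_shift <- function(object, ...) print(object, ...)

#' @export
plot.geneset_shift <- function(x, ...) {
  graphics::hist(x$null_d, breaks = 30, main = "Permutation null of K-S D",
                 xlab = "D", xlim = range(c(x$null_d, x$D, x$q99)), ...)
  graphics::abline(v = x$q99, lty = 2)
  graphics::abline(v = x$D, lwd = 2)
  invisible(x)
}

#' Directional contrast of positive vs negative regulators
#'
#' Compares mean log fold-change between two disjoint gene sets (e.g. known
#' positive vs negative regulators of a pathway) with a label-permutation
#' p-value; all label assignments are enumerated when feasible, otherwise
#' random shuffles are used.
#'
#' @param lfc named numeric vector of per-gene log fold-changes.
#' @param positive_ids,negative_ids disjoint gene-id sets (each >= 2 genes).
#' @param n_perm permutation budget (default 10000).
#' @return list with `mean_pos`, `se_pos`, `mean_neg`, `se_neg`,
#'   `difference`, `p_permutation`, `exact` (enumeration used?).
#' @export
directional_contrast <- function(lfc, positive_ids, negative_ids,
                                 n_perm = 10000) {
  if (length(intersect(positive_ids, negative_ids)))
    stop("positive and negative sets overlap")
  pos <- lfc[intersect(positive_ids, names(lfc))]
  neg <- lfc[intersect(negative_ids, names(lfc))]
  if (length(pos) < 2 || length(neg) < 2)
    stop("each set needs at least 2 genes with fold-changes")
  se <- function(v) stats::sd(v) / sqrt(length(v))
  obs <- mean(pos) - mean(neg)
  vals <- c(pos, neg)
  n1 <- length(pos)
  n <- length(vals)
  n_comb <- choose(n, n1)
  if (n_comb <= n_perm) {
    combs <- utils::combn(n, n1)
    diffs <- apply(combs, 2, function(ii)
      mean(vals[ii]) - mean(vals[-ii]))
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    exact <- TRUE
  } else {
    diffs <- replicate(n_perm, {
      ii <- sample.int(n, n1)
      mean(vals[ii]) - mean(vals[-ii])
    })
    p <- (1 + sum(abs(diffs) >= abs(obs) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
  }
  list(mean_pos = mean(pos), se_pos = se(pos), mean_neg = mean(neg),
       se_neg = se(neg), difference = obs, p_permutation = p, exact = exact)
}

#' Naive per-gene differential expression with FDR control
#'
#' Exact Poisson-style test per gene: conditional on the gene's total count,
#' the group-a sum is binomial with probability given by the groups' share
#' of effective library size; two-sided exact p-values are
#' Benjamini-Hochberg adjusted. This is a deliberately simple screen and is
#' not equivalent to a negative-binomial GLM analysis; it ignores biological
#' overdispersion and will overstate significance for dispersed genes.
#'
#' @inheritParams log_fold_change
#' @return data.frame with `gene`, `lfc`, `p`, `fdr`.
#' @export
de_test_naive <- function(counts, groups, contrast, prior_count = 0.5) {
  nf <- tmm_factors(counts)
  a <- groups == contrast[1]
  b <- groups == contrast[2]
  pr <- sum(nf[a]) / sum(nf[a | b])
  ka <- rowSums(counts[, a, drop = FALSE])
  tot <- ka + rowSums(counts[, b, drop = FALSE])
  p <- vapply(seq_along(ka), function(i) {
    if (tot[i] == 0) return(1)
    stats::binom.test(ka[i], tot[i], pr)$p.value
  }, 0)
  data.frame(gene = rownames(counts),
             lfc = log_fold_change(counts, groups, contrast,
                                   prior_count = prior_count,
                                   norm_factors = nf),
             p = p, fdr = stats::p.adjust(p, "BH"), row.names = NULL)
}
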