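#' Folded two-dimensional SFS from genotypes
#'
#' Builds the joint minor-allele-frequency spectrum for two populations.
#' Sites failing the per-population missingness ceiling are dropped; the
#' remaining sites are projected down to the requested haploid sample sizes
#' with hypergeometric weights (fractional cell contributions), then folded
#' with fixed and fold-redundant cells masked.
#'
#' @param geno a [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @param projection haploid sample sizes `c(n1, n2)` to project down to.
#' @param max_missing per-population missing-data ceiling per site
#'   (default 0.25).
#' @param L_callable optional number of callable sites behind the SNP set,
#'   stored for theta calibration.
#' @return folded matrix `(n1+1) x (n2+1)` with attributes `mask`,
#'   `projection`, `sites_used`, `L_callable`.
#' @export
build_folded_2dsfs <- function(geno, pop_a, pop_b, projection,
                               max_missing = 0.25, L_callable = NA) {
  ac <- allele_counts(geno, c(pop_a, pop_b))
  n_pop <- c(sum(geno$pop_labels == pop_a), sum(geno$pop_labels == pop_b))
  if (any(projection > 2 * n_pop))
    stop("projection larger than the number of sampled alleles")
  m1 <- projection[1]
  m2 <- projection[2]
  chrom_a <- 2 * ac$n_called[, pop_a]
  chrom_b <- 2 * ac$n_called[, pop_b]
  ok <- (1 - ac$n_called[, pop_a] / n_pop[1]) <= max_missing &
    (1 - ac$n_called[, pop_b] / n_pop[2]) <= max_missing &
    chrom_a >= m1 & chrom_b >= m2
  idx <- which(ok)
  raw <- matrix(0, m1 + 1, m2 + 1)
  for (s in idx) {
    w1 <- stats::dhyper(0:m1, ac$alt[s, pop_a], chrom_a[s] - ac$alt[s, pop_a],
                        m1)
    w2 <- stats::dhyper(0:m2, ac$alt[s, pop_b], chrom_b[s] - ac$alt[s, pop_b],
                        m2)
    raw <- raw + outer(w1, w2)
  }
  out <- fold_sfs(raw)
  attr(out, "projection") <- c(m1, m2)
  attr(out, "sites_used") <- length(idx)
  attr(out, "L_callable") <- L_callable
  out
}

#' Poisson composite log-likelihood of an observed SFS
#'
#' Treats unmasked SFS cells as independent Poisson counts with mean
#' `theta * expected_normalized`, the standard composite likelihood for
#' SFS-based demographic inference. Fractional observed cells (from
#' projection) are handled through the log-gamma function.
#'
#' @param obs observed SFS matrix with attribute `mask` (see
#'   [build_folded_2dsfs()]).
#' @param expected_normalized model-expected SFS of identical shape and mask.
#' @param theta scale parameter (> 0).
#' @return composite log-likelihood (may be `-Inf` when a cell with expected
#'   mass 0 carries observations).
#' @export
composite_loglik <- function(obs, expected_normalized, theta) {
  if (!all(dim(obs) == dim(expected_normalized)))
    stop("shape mismatch between observed and expected SFS")
  if (theta <= 0) stop("theta must be positive")
  mask <- attr(obs, "mask")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(obs), ncol(obs))
  n <- obs[!mask]
  e <- theta * expected_normalized[!mask]
  if (any(e == 0 & n > 0)) return(-Inf)
  use <- e > 0
  sum(n[use] * log(e[use]) - e[use] - lgamma(n[use] + 1))
}

# ---- scaled two-deme isolation-with-migration families ---------------------
# Units follow the diffusion convention: sizes nu relative to the ancestral
# population, time T in units of 2*N_anc generations, migration M = 2*N_anc*m
# (per-lineage backward hop rate in scaled time). Internally N_ref = 1/2
# diploid so that one simulator "generation" equals one scaled time unit.

.scaled_im_args <- function(nu1, nu2, T, M12) {
  mig <- matrix(0, 2, 2)
  mig[1, 2] <- mig[2, 1] <- M12
  list(deme_sizes = c(0.5 * nu1, 0.5 * nu2), mig = mig,
       split_times = T, split_from = 2L, split_to = 1L,
       split_parent_sizes = 0.5)
}

.expected_im_sfs <- function(par, family, n_hap, n_sims, eval_seed) {
  one_class <- function(M) {
    a <- .scaled_im_args(par[["nu1"]], par[["nu2"]], par[["T"]], M)
    .branch_sfs_cpp(a$deme_sizes, a$mig, a$split_times,
                    as.integer(a$split_from), as.integer(a$split_to),
                    a$split_parent_sizes, as.integer(n_hap),
                    as.integer(n_sims), TRUE)
  }
  set.seed(eval_seed)
  res <- switch(family,
    no_mig = one_class(0),
    one_mig = one_class(par[["M"]]),
    two_mig_classes = {
      hi <- one_class(par[["M_high"]])
      lo <- one_class(par[["M_low"]])
      P <- par[["P"]]
      list(mean = P * hi$mean + (1 - P) * lo$mean,
           var_mean = P^2 * hi$var_mean + (1 - P)^2 * lo$var_mean)
    })
  out <- .finish_sfs(res$mean, fold = TRUE, normalize = FALSE)
  mask <- attr(out, "mask")
  total <- sum(out[!mask])
  out[!mask] <- out[!mask] / total
  # floor unmasked cells: finite Monte-Carlo runs can miss rare cells, and a
  # structural zero would send the Poisson likelihood to -Inf
  out[!mask] <- pmax(out[!mask], 1e-8)
  out[!mask] <- out[!mask] / sum(out[!mask])
  v <- res$var_mean / total^2
  v[mask] <- 0
  attr(out, "var_norm") <- v
  out
}

# Second-order (Jensen) bias correction for the Monte-Carlo composite
# log-likelihood: E[n log Ehat] = n log E - n Var(Ehat)/(2 E^2) + O(sims^-2),
# so the estimated deficit is added back.  The per-cell variance ratio is
# capped at 1, where the Taylor expansion stops being meaningful.  The
# correction makes likelihoods computed at modest simulation budgets
# comparable across parameter regions whose Monte-Carlo noise differs.
.mc_bias_correction <- function(obs, e_norm) {
  mask <- attr(e_norm, "mask")
  v <- attr(e_norm, "var_norm")
  if (is.null(v)) return(0)
  n <- obs[!mask]
  e <- e_norm[!mask]
  sum(n * pmin(v[!mask] / e^2, 1)) / 2
}

.family_params <- function(family) {
  switch(family,
    no_mig = c("nu1", "nu2", "T"),
    one_mig = c("nu1", "nu2", "T", "M"),
    two_mig_classes = c("nu1", "nu2", "T", "M_high", "M_low", "P"),
    stop("unknown model family"))
}

# uniform prior bounds on the natural scale (study priors)
.family_bounds <- function(family) {
  lo <- c(nu1 = 0.1, nu2 = 0.1, T = 0.01, M = 1e-3, M_high = 1e-3,
          M_low = 1e-3, P = 0.5)
  hi <- c(nu1 = 10, nu2 = 10, T = 10, M = 10, M_high = 10, M_low = 10,
          P = 1)
  p <- .family_params(family)
  list(lo = lo[p], hi = hi[p])
}

.to_unconstrained <- function(par, b) {
  z <- log(par - b$lo) - log(b$hi - par)  # logit over the prior box
  names(z) <- names(par)
  z
}

.to_natural <- function(z, b) {
  p <- b$lo + (b$hi - b$lo) * stats::plogis(z)
  names(p) <- names(b$lo)
  p
}

#' Fit an isolation-with-migration model to a folded 2D-SFS
#'
#' Maximizes the Poisson composite likelihood over the demographic
#' parameters with Nelder-Mead restarts drawn from the study's uniform
#' priors. The model-expected SFS is computed by coalescent Monte Carlo with
#' common random numbers within each restart (the same stream is replayed at
#' every likelihood evaluation, making the objective deterministic); `theta`
#' is profiled analytically as `sum(obs) / sum(expected)`.
#'
#' Families: `no_mig` (sizes and split time only), `one_mig` (one symmetric
#' migration rate `M = 2*N_anc*m`), `two_mig_classes` (high and low rates
#' with mixture proportion `P` of loci in the high class).
#'
#' @param obs folded 2D-SFS from [build_folded_2dsfs()] (or compatible).
#' @param model_family one of `"no_mig"`, `"one_mig"`, `"two_mig_classes"`.
#' @param n_restarts random prior draws screened as candidate starts
#'   (default 25).
#' @param mc_sims genealogies per likelihood evaluation (default 2000).
#' @param starts optional list of named parameter vectors used as additional
#'   starts that are always polished (e.g. a nested fit's solution).
#' @param n_polish number of best-scoring candidates refined by Nelder-Mead
#'   (default 3; user-supplied `starts` are always refined).
#' @param maxit Nelder-Mead iteration cap per polish run.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @return object of class `demog_fit`.
#' @export
fit_demography <- function(obs, model_family = c("one_mig", "no_mig",
                                                 "two_mig_classes"),
                           n_restarts = 25, mc_sims = 2000, starts = NULL,
                           n_polish = 3, maxit = 300, reltol = 1e-6) {
  model_family <- match.arg(model_family)
  b <- .family_bounds(model_family)
  pnames <- .family_params(model_family)
  n_hap <- dim(obs) - 1
  mask <- attr(obs, "mask")
  n_tot <- sum(obs[!mask])

  objective_at <- function(z, eval_seed, sims) {
    par <- .to_natural(z, b)
    e_norm <- .expected_im_sfs(par, model_family, n_hap, sims, eval_seed)
    theta <- n_tot / sum(e_norm[!attr(e_norm, "mask")])
    -(composite_loglik(obs, e_norm, theta) +
        .mc_bias_correction(obs, e_norm))
  }
  objective <- function(z, eval_seed) objective_at(z, eval_seed, mc_sims)

  n_user <- if (is.null(starts)) 0L else length(starts)
  start_list <- list()
  if (n_user > 0)
    start_list <- lapply(starts, function(s) unlist(s)[pnames])
  # random starts are drawn log-uniformly over the prior box (uniformly for
  # the mixture proportion) so that small sizes, times and rates are as well
  # represented among the starts as large ones; the box itself is the
  # study's uniform prior
  for (i in seq_len(n_restarts)) {
    s <- exp(stats::runif(length(pnames), log(b$lo), log(b$hi)))
    names(s) <- pnames
    if ("P" %in% pnames)
      s[["P"]] <- stats::runif(1, b$lo[["P"]], b$hi[["P"]])
    start_list[[length(start_list) + 1]] <- s
  }

  # screen every candidate under one shared random-number stream (at a
  # larger simulation budget than the polish stage, since screening is a
  # single evaluation per candidate and region-dependent Monte-Carlo bias
  # would otherwise distort the ranking), then polish the most promising
  screen_seed <- sample.int(.Machine$integer.max, 1)
  screen <- vapply(start_list, function(s)
    objective_at(.to_unconstrained(s, b), screen_seed, 4 * mc_sims), 0)
  polish_idx <- unique(c(seq_len(n_user),
                         order(screen)[seq_len(min(n_polish,
                                                   length(start_list)))]))

  runs <- list()
  for (r in polish_idx) {
    eval_seed <- sample.int(.Machine$integer.max, 1)
    fit <- tryCatch(
      stats::optim(.to_unconstrained(start_list[[r]], b),
                   objective, eval_seed = eval_seed,
                   method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(fit))
      runs[[length(runs) + 1]] <-
        list(par = .to_natural(fit$par, b), nll = fit$value,
             converged = fit$convergence == 0, eval_seed = eval_seed)
  }
  if (!length(runs)) stop("all restarts failed")
  # final ranking and refinement at a larger simulation budget: the
  # low-budget likelihood is biased differently across parameter regions,
  # so finalists are re-scored (and briefly re-polished) under one
  # high-precision stream before choosing the winner
  hi_sims <- 8 * mc_sims
  hi_seed <- sample.int(.Machine$integer.max, 1)
  for (r in seq_along(runs)) {
    z0 <- .to_unconstrained(runs[[r]]$par, b)
    refit <- tryCatch(
      stats::optim(z0, objective_at, eval_seed = hi_seed, sims = hi_sims,
                   method = "Nelder-Mead",
                   control = list(maxit = ceiling(maxit / 4),
                                  reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(refit)) {
      runs[[r]]$par <- .to_natural(refit$par, b)
      runs[[r]]$nll <- refit$value
      runs[[r]]$converged <- runs[[r]]$converged && refit$convergence == 0
      runs[[r]]$eval_seed <- hi_seed
    } else {
      runs[[r]]$nll <- objective_at(z0, hi_seed, hi_sims)
      runs[[r]]$eval_seed <- hi_seed
    }
  }
  nlls <- vapply(runs, `[[`, 0, "nll")
  best <- runs[[which.min(nlls)]]

  e_norm <- .expected_im_sfs(best$par, model_family, n_hap, hi_sims,
                             best$eval_seed)
  theta_hat <- n_tot / sum(e_norm[!attr(e_norm, "mask")])
  structure(
    list(family = model_family, par = best$par, loglik = -best$nll,
         theta_hat = theta_hat, converged = best$converged,
         any_converged = any(vapply(runs, `[[`, TRUE, "converged")),
         eval_seed = best$eval_seed, mc_sims = mc_sims,
         n_restarts = length(start_list),
         restarts = data.frame(
           nll = nlls,
           converged = vapply(runs, `[[`, TRUE, "converged")),
         sample_haploids = n_hap),
    class = "demog_fit")
}

#' @export
print.demog_fit <- function(x, ...) {
  cat("demog_fit:", x$family, "family,",
      sprintf("composite logLik %.3f (theta = %.2f)\n", x$loglik,
              x$theta_hat))
  print(round(x$par, 4))
  if (!x$any_converged)
    cat("warning: no restart reported convergence\n")
  invisible(x)
}

#' @export
coef.demog_fit <- function(object, ...) c(object$par, theta = object$theta_hat)

#' @export
logLik.demog_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par) + 1, class = "logLik")
}

#' @export
summary.demog_fit <- function(object, ...) {
  cat(sprintf("Isolation-with-migration composite-likelihood fit (%s)\n",
              object$family))
  cat(sprintf("restarts: %d; best logLik %.3f; converged: %s\n",
              object$n_restarts, object$loglik, object$converged))
  print(round(coef(object), 4))
  invisible(object)
}

#' Likelihood-ratio comparison of nested SFS fits
#'
#' Plain likelihood-ratio test on the composite likelihoods: statistic
#' `2 * (LL_complex - LL_simple)` against a chi-square upper tail. Composite
#' likelihoods violate the independence assumptions behind the chi-square
#' reference, so the p-value is anti-conservative and should be read as a
#' heuristic ranking device.
#'
#' @param fit_simple,fit_complex nested [fit_demography()] results.
#' @param df degrees of freedom (parameter-count difference).
#' @param tol slack allowed before declaring the nesting violated.
#' @return list with `statistic` and `p_value`.
#' @export
likelihood_ratio <- function(fit_simple, fit_complex, df, tol = 0.01) {
  order_ <- c(no_mig = 1, one_mig = 2, two_mig_classes = 3)
  if (order_[fit_simple$family] >= order_[fit_complex$family])
    stop("families are not nested in the given order")
  delta <- fit_complex$loglik - fit_simple$loglik
  if (delta < -tol)
    stop("simple model fits better than the complex one beyond tolerance")
  stat <- max(0, 2 * delta)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Convert scaled demographic estimates to natural units
#'
#' Theta calibrates the ancestral size `N_anc = theta / (4 mu L)`; relative
#' sizes, scaled times and scaled migration rates then convert as
#' `N_e = nu * N_anc`, `t = T * 2 * N_anc` generations, and
#' migrants/generation `= M / 2` (with `M = 2 N_anc m`).
#'
#' @param theta composite-likelihood scale estimate.
#' @param mu per-base per-generation mutation rate.
#' @param L_callable number of callable sites behind the SNP set.
#' @param nu named vector of relative sizes (optional).
#' @param T scaled split time(s) (optional).
#' @param M scaled migration rate(s) `2*N_anc*m` (optional).
#' @return list with `N_anc` and, when supplied, `N_e`, `t_generations`,
#'   `migrants_per_generation`.
#' @export
calibrate <- function(theta, mu, L_callable, nu = NULL, T = NULL, M = NULL) {
  if (any(c(theta, mu, L_callable) <= 0))
    stop("theta, mu and L_callable must be positive")
  n_anc <- theta / (4 * mu * L_callable)
  out <- list(N_anc = n_anc)
  if (!is.null(nu)) out$N_e <- nu * n_anc
  if (!is.null(T)) out$t_generations <- T * 2 * n_anc
  if (!is.null(M)) out$migrants_per_generation <- M / 2
  out
}

# greedy pool of SNPs spaced at least `min_spacing_bp` apart, per chromosome
.spaced_sites <- function(sites, min_spacing_bp) {
  keep <- integer(0)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    idx <- idx[order(sites$pos[idx])]
    last <- -Inf
    for (i in idx) {
      if (sites$pos[i] - last >= min_spacing_bp) {
        keep <- c(keep, i)
        last <- sites$pos[i]
      }
    }
  }
  sort(keep)
}

.subset_sites <- function(geno, idx) {
  genotype_matrix(geno$dosages[, idx, drop = FALSE], geno$sample_ids,
                  geno$pop_labels, geno$sites[idx, , drop = FALSE])
}

#' Bootstrap confidence intervals for demographic parameters
#'
#' Nonparametric SNP bootstrap: a pool of SNPs spaced at least
#' `min_spacing_bp` apart is resampled with replacement, the folded 2D-SFS
#' rebuilt and the model refit (few restarts, seeded at the point estimate);
#' percentile intervals are taken across replicates.
#'
#' @param geno a [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @param projection haploid projection sizes, as in [build_folded_2dsfs()].
#' @param point_fit the [fit_demography()] result to bootstrap.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param min_spacing_bp minimum SNP spacing in the pool (default 10 kb).
#' @param n_restarts restarts per refit (default 5).
#' @param mc_sims genealogies per likelihood evaluation during refits.
#' @param level confidence level (default 0.95).
#' @param max_missing per-population missingness ceiling.
#' @return list with `ci` (data.frame: parameter, lower, upper), `estimates`
#'   (replicate x parameter matrix) and `pool_size`.
#' @export
bootstrap_ci <- function(geno, pop_a, pop_b, projection, point_fit,
                         n_boot = 100, min_spacing_bp = 10000,
                         n_restarts = 5, mc_sims = 1000, level = 0.95,
                         max_missing = 0.25) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  pool <- .spaced_sites(geno$sites, min_spacing_bp)
  if (length(pool) < 2) stop("too few SNPs satisfy the spacing rule")
  reps <- matrix(NA_real_, n_boot, length(point_fit$par) + 1,
                 dimnames = list(NULL, c(names(point_fit$par), "theta")))
  for (bidx in seq_len(n_boot)) {
    idx <- sample(pool, length(pool), replace = TRUE)
    sfs <- build_folded_2dsfs(.subset_sites(geno, idx), pop_a, pop_b,
                              projection, max_missing = max_missing)
    fit <- fit_demography(sfs, point_fit$family, n_restarts = n_restarts,
                          mc_sims = mc_sims,
                          starts = list(point_fit$par))
    reps[bidx, ] <- c(fit$par, fit$theta_hat)
  }
  alpha <- (1 - level) / 2
  ci <- data.frame(
    parameter = colnames(reps),
    lower = apply(reps, 2, stats::quantile, alpha),
    upper = apply(reps, 2, stats::quantile, 1 - alpha),
    row.names = NULL)
  list(ci = ci, estimates = reps, pool_size = length(pool))
}
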