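#' Allele-frequency cline dataset
#'
#' Per-locality allele counts along an elevational transect: at locality `i`,
#' `k[i]` copies of the focal (high-elevation) allele were observed among
#' `total[i]` sampled alleles at elevation `elevation[i]` (m a.s.l.).
#'
#' @param elevation elevations in metres.
#' @param k focal-allele counts.
#' @param total total alleles sampled (2 x diploids).
#' @param locality optional locality names.
#' @return data.frame of class `cline_dataset`.
#' @export
cline_dataset <- function(elevation, k, total, locality = NULL) {
  if (any(k < 0) || any(k > total)) stop("need 0 <= k <= total")
  if (is.null(locality)) locality <- paste0("loc", seq_along(elevation))
  out <- data.frame(locality = locality, elevation = as.numeric(elevation),
                    k = as.integer(k), total = as.integer(total))
  class(out) <- c("cline_dataset", "data.frame")
  out
}

#' Expected allele frequency under an equilibrium sigmoid cline
#'
#' The core is the hyperbolic-tangent cline
#' `p(x) = pmin + (pmax - pmin) * (1 + tanh(2 (x - center) / width)) / 2`,
#' with `center` the elevation of the frequency midpoint and `width` the
#' inverse of the maximal slope. Optional exponential tails replace the
#' sigmoid beyond `center - delta_l` (left) and/or `center + delta_r`
#' (right): the tail matches the sigmoid's value at the junction and decays
#' exponentially with initial slope `tau` times the sigmoid slope there
#' (`0 < tau <= 1`).
#'
#' @param x elevations (vectorized).
#' @param params named list or vector with `center`, `width` and optionally
#'   `pmin`, `pmax` (defaults 0 and 1), `delta_l`/`tau_l`, `delta_r`/`tau_r`,
#'   or shared `delta`/`tau` applied to both sides.
#' @return expected frequencies in `[0, 1]`.
#' @export
cline_frequency <- function(x, params) {
  p <- as.list(params)
  center <- p$center
  width <- p$width
  if (is.null(center) || is.null(width) || width <= 0)
    stop("params must contain center and positive width")
  pmin_ <- if (is.null(p$pmin)) 0 else p$pmin
  pmax_ <- if (is.null(p$pmax)) 1 else p$pmax
  if (pmin_ > pmax_) stop("pmin must not exceed pmax")
  dl <- if (!is.null(p$delta)) p$delta else p$delta_l
  tl <- if (!is.null(p$tau)) p$tau else p$tau_l
  dr <- if (!is.null(p$delta)) p$delta else p$delta_r
  tr <- if (!is.null(p$tau)) p$tau else p$tau_r

  core <- function(z) (1 + tanh(2 * (z - center) / width)) / 2
  slope <- function(z) (1 - tanh(2 * (z - center) / width)^2) / width
  u <- core(x)
  if (!is.null(dl)) {
    if (dl < 0 || tl <= 0 || tl > 1) stop("invalid left tail parameters")
    x0 <- center - dl
    A <- core(x0)
    left <- x < x0
    u[left] <- A * exp(tl * slope(x0) / A * (x[left] - x0))
  }
  if (!is.null(dr)) {
    if (dr < 0 || tr <= 0 || tr > 1) stop("invalid right tail parameters")
    x1 <- center + dr
    B <- core(x1)
    right <- x > x1
    u[right] <- 1 - (1 - B) * exp(-tr * slope(x1) / (1 - B) * (x[right] - x1))
  }
  pmin_ + (pmax_ - pmin_) * u
}

#' Binomial log-likelihood of a cline dataset
#'
#' `sum(k * log(p) + (total - k) * log(1 - p))` with expected frequencies
#' clamped to `[eps, 1 - eps]` so that fixed localities under boundary
#' parameters contribute a large negative but finite value.
#'
#' @param data a [cline_dataset()].
#' @param params cline parameters (see [cline_frequency()]).
#' @param eps clamp (default `1e-9`).
#' @return log-likelihood.
#' @export
cline_loglik <- function(data, params, eps = 1e-9) {
  p <- pmin(pmax(cline_frequency(data$elevation, params), eps), 1 - eps)
  sum(data$k * log(p) + (data$total - data$k) * log(1 - p))
}

# variant bookkeeping --------------------------------------------------------

.cline_variants <- function() {
  v <- expand.grid(scaling = c("fixed", "free"),
                   tails = c("none", "left", "right", "mirror", "both"),
                   stringsAsFactors = FALSE)
  paste(v$scaling, v$tails, sep = "_")
}

.cline_param_names <- function(variant) {
  parts <- strsplit(variant, "_")[[1]]
  nm <- c("center", "width")
  if (parts[1] == "free") nm <- c(nm, "pmin", "pmax")
  nm <- c(nm, switch(parts[2],
                     none = character(),
                     left = c("delta_l", "tau_l"),
                     right = c("delta_r", "tau_r"),
                     mirror = c("delta", "tau"),
                     both = c("delta_l", "tau_l", "delta_r", "tau_r")))
  nm
}

.cline_bounds <- function(data) {
  r <- range(data$elevation)
  span <- diff(r)
  list(
    lo = c(center = r[1] - span, width = span / 1000, pmin = 0, pmax = 0,
           delta = 0, tau = 1e-6, delta_l = 0, tau_l = 1e-6, delta_r = 0,
           tau_r = 1e-6),
    hi = c(center = r[2] + span, width = 20 * span, pmin = 1, pmax = 1,
           delta = 2 * span, tau = 1, delta_l = 2 * span, tau_l = 1,
           delta_r = 2 * span, tau_r = 1))
}

.cline_start <- function(data, nm) {
  freq <- data$k / data$total
  span <- diff(range(data$elevation))
  start <- c(center = stats::weighted.mean(data$elevation,
                                           data$total * freq * (1 - freq) +
                                             1e-6),
             width = span / 2, pmin = max(0.001, min(freq) * 0.9),
             pmax = min(0.999, max(0.01, max(freq))), delta = span / 4,
             tau = 0.5, delta_l = span / 4, tau_l = 0.5, delta_r = span / 4,
             tau_r = 0.5)
  start[nm]
}

#' Fit an equilibrium cline by Metropolis-Hastings MCMC
#'
#' Gaussian random-walk Metropolis-Hastings on the natural parameter scale
#' with flat priors inside broad bounds (proposals outside the bounds, or
#' violating `pmin <= pmax`, are rejected). Parameters are updated one at a
#' time per sweep; proposal scales are tuned during burn-in toward a 20-40%
#' acceptance rate and then frozen. The MAP estimate is the highest
#' log-likelihood sample; credible intervals are equal-tail posterior
#' quantiles.
#'
#' Model variants combine frequency scaling (`fixed`: frequencies run from 0
#' to 1; `free`: `pmin` and `pmax` estimated) with exponential tails
#' (`none`, `left`, `right`, `mirror` = shared tail both sides, `both` =
#' independent tails), e.g. `"free_none"` (the default reported model).
#'
#' @param data a [cline_dataset()] (>= 3 localities with distinct
#'   elevations).
#' @param variant model variant string (see Details).
#' @param chain_length total MCMC sweeps (default 1e5).
#' @param burn_in sweeps discarded (default 1e4).
#' @param level credible level (default 0.95).
#' @return object of class `cline_fit`.
#' @export
fit_cline <- function(data, variant = "free_none", chain_length = 1e5,
                      burn_in = 1e4, level = 0.95) {
  if (length(unique(data$elevation)) < 3)
    stop("need at least 3 localities with distinct elevations")
  if (burn_in >= chain_length) stop("chain_length must exceed burn_in")
  nm <- .cline_param_names(variant)
  bounds <- .cline_bounds(data)
  lo <- bounds$lo[nm]
  hi <- bounds$hi[nm]
  cur <- .cline_start(data, nm)
  k <- length(nm)
  scales <- (hi - lo) / 20
  scales[!is.finite(scales)] <- 1

  ll <- function(par) cline_loglik(data, as.list(par))
  cur_ll <- ll(cur)
  if (!is.finite(cur_ll)) cur_ll <- -1e300

  n_keep <- chain_length - burn_in
  samples <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, nm))
  lls <- numeric(n_keep)
  acc <- att <- stats::setNames(numeric(k), nm)
  tune_block <- 200L

  for (it in seq_len(chain_length)) {
    for (j in seq_len(k)) {
      prop <- cur
      prop[j] <- cur[j] + stats::rnorm(1, 0, scales[j])
      att[j] <- att[j] + 1
      ok <- prop[j] >= lo[j] && prop[j] <= hi[j]
      if (ok && all(c("pmin", "pmax") %in% nm))
        ok <- prop[["pmin"]] <= prop[["pmax"]]
      if (ok) {
        prop_ll <- ll(prop)
        if (is.finite(prop_ll) &&
            log(stats::runif(1)) < prop_ll - cur_ll) {
          cur <- prop
          cur_ll <- prop_ll
          acc[j] <- acc[j] + 1
        }
      }
    }
    if (it <= burn_in && it %% tune_block == 0) {
      rate <- acc / pmax(att, 1)
      scales[rate < 0.2] <- scales[rate < 0.2] * 0.7
      scales[rate > 0.4] <- scales[rate > 0.4] * 1.4
      acc[] <- 0
      att[] <- 0
    }
    if (it > burn_in) {
      samples[it - burn_in, ] <- cur
      lls[it - burn_in] <- cur_ll
    }
  }

  best <- which.max(lls)
  alpha <- (1 - level) / 2
  ci <- apply(samples, 2, stats::quantile, c(alpha, 1 - alpha))
  acc_rate <- sum(acc) / max(1, sum(att))
  n_par <- k
  n_loc <- nrow(data)
  aicc <- if (n_loc > n_par + 1)
    -2 * lls[best] + 2 * n_par + 2 * n_par * (n_par + 1) /
      (n_loc - n_par - 1) else NA_real_

  structure(
    list(variant = variant, samples = samples, loglik = lls,
         map = samples[best, ], map_loglik = lls[best], ci = ci,
         acceptance = acc_rate, aicc = aicc, data = data,
         chain_length = chain_length, burn_in = burn_in, level = level,
         flag_zero_acceptance = acc_rate == 0),
    class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline_fit (%s): MAP center %.1f m, width %.1f m\n",
              x$variant, x$map[["center"]], x$map[["width"]]))
  cat(sprintf("logLik %.2f; AICc %.2f; acceptance %.2f\n", x$map_loglik,
              x$aicc, x$acceptance))
  invisible(x)
}

#' @export
summary.cline_fit <- function(object, ...) {
  cat(sprintf("Equilibrium cline fit, variant %s\n", object$variant))
  cat(sprintf("chain %d (burn-in %d), acceptance %.2f\n",
              object$chain_length, object$burn_in, object$acceptance))
  tab <- cbind(MAP = object$map, mean = colMeans(object$samples),
               t(object$ci))
  print(round(tab, 4))
  cat(sprintf("MAP logLik %.3f, AICc %.3f\n", object$map_loglik,
              object$aicc))
  invisible(tab)
}

#' @export
coef.cline_fit <- function(object, ...) object$map

#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$elevation else
    if (is.data.frame(newdata)) newdata$elevation else newdata
  cline_frequency(x, as.list(object$map))
}

#' @export
residuals.cline_fit <- function(object, ...) {
  p <- predict(object)
  with(object$data, (k - total * p) / sqrt(total * p * (1 - p)))
}

#' @export
simulate.cline_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  out <- replicate(nsim, stats::rbinom(length(p), object$data$total, p))
  colnames(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.cline_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  freq <- d$k / d$total
  grid <- seq(min(d$elevation), max(d$elevation), length.out = n_grid)
  graphics::plot(d$elevation, freq, xlab = "elevation (m a.s.l.)",
                 ylab = "allele frequency", ylim = c(0, 1), pch = 19, ...)
  graphics::lines(grid, cline_frequency(grid, as.list(x$map)), lwd = 2)
  graphics::abline(v = x$map[["center"]], lty = 2)
  invisible(x)
}

#' Compare cline model variants by AICc
#'
#' Fits each variant by MCMC and ranks them by
#' `AICc = -2 LL_MAP + 2k + 2k(k+1) / (N - k - 1)` with `N` the number of
#' localities. Variants with too few localities for the correction
#' (`N <= k + 1`) are skipped with a warning. Ties are ordered by variant
#' name for stability.
#'
#' @param data a [cline_dataset()].
#' @param variants character vector of variant names (default: all 10).
#' @param ... passed to [fit_cline()] (e.g. `chain_length`).
#' @return list with `table` (data.frame: variant, k, loglik, aicc, delta)
#'   and `fits` (named list of `cline_fit` objects).
#' @export
select_cline_model <- function(data, variants = .cline_variants(), ...) {
  if (!length(variants)) stop("need at least one variant")
  fits <- list()
  rows <- list()
  for (v in variants) {
    k <- length(.cline_param_names(v))
    if (nrow(data) <= k + 1) {
      warning("skipping variant ", v, ": too few localities for AICc")
      next
    }
    f <- fit_cline(data, variant = v, ...)
    fits[[v]] <- f
    rows[[v]] <- data.frame(variant = v, k = k, loglik = f$map_loglik,
                            aicc = f$aicc)
  }
  if (!length(rows)) stop("no variant could be fitted")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc, tab$variant), ]
  tab$delta <- tab$aicc - min(tab$aicc)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
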