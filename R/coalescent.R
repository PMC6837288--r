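#' Demographic model for the structured coalescent simulator
#'
#' Describes a set of present-day demes with diploid effective sizes, ordered
#' split events (backwards in time the derived deme merges into its parent),
#' and symmetric migration expressed in migrants per generation. Two
#' migration-rate classes are supported: a proportion `p_high` of loci
#' evolves under `mig_high` and `1 - p_high` under `mig_low`, modelling
#' genomic heterogeneity in effective gene flow.
#'
#' Internally, "M migrants per generation" between demes i and j is converted
#' to a backward per-lineage hop rate `M / N_i` per generation for lineages
#' in deme i (the fraction of deme i replaced by migrants each generation).
#'
#' @param deme_sizes named numeric vector of present-day diploid sizes.
#' @param split_times split times in generations, strictly increasing.
#' @param split_from,split_to deme names: at each time, `from` merges into
#'   `to` (backwards in time).
#' @param split_parent_sizes optional diploid size taken by the parent deme
#'   from the split backwards (`NA` = unchanged).
#' @param mig_high symmetric matrix (deme x deme) of migrants/generation for
#'   the high-migration class; a single number is recycled to all off-diagonal
#'   pairs.
#' @param mig_low same for the low class (default: equal to `mig_high`).
#' @param p_high proportion of loci in the high class, in `[0, 1]`.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(deme_sizes, split_times = numeric(),
                              split_from = character(),
                              split_to = character(),
                              split_parent_sizes = NULL,
                              mig_high = 0, mig_low = NULL, p_high = 1) {
  nd <- length(deme_sizes)
  if (is.null(names(deme_sizes))) names(deme_sizes) <- paste0("pop", seq_len(nd))
  if (any(deme_sizes <= 0)) stop("deme sizes must be positive")
  if (length(split_times) != length(split_from) ||
      length(split_times) != length(split_to))
    stop("split event vectors must have equal length")
  if (is.unsorted(split_times, strictly = TRUE))
    stop("split times must be strictly increasing toward the past")
  if (length(split_times) != nd - 1)
    stop("need exactly ", nd - 1, " splits so a single ancestral deme remains")
  if (is.null(split_parent_sizes))
    split_parent_sizes <- rep(NA_real_, length(split_times))
  expand <- function(m) {
    if (is.matrix(m)) {
      if (!all(dim(m) == nd)) stop("migration matrix dimension mismatch")
      mm <- m
    } else {
      mm <- matrix(m, nd, nd)
    }
    diag(mm) <- 0
    if (any(mm < 0)) stop("migration rates must be >= 0")
    if (any(abs(mm - t(mm)) > 1e-12)) stop("migration must be symmetric")
    dimnames(mm) <- list(names(deme_sizes), names(deme_sizes))
    mm
  }
  if (is.null(mig_low)) mig_low <- mig_high
  if (p_high < 0 || p_high > 1) stop("p_high must be in [0, 1]")
  structure(
    list(deme_sizes = deme_sizes,
         split_times = as.numeric(split_times),
         split_from = match(split_from, names(deme_sizes)),
         split_to = match(split_to, names(deme_sizes)),
         split_parent_sizes = as.numeric(split_parent_sizes),
         mig_high = expand(mig_high), mig_low = expand(mig_low),
         p_high = p_high),
    class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model with", length(x$deme_sizes), "demes\n")
  cat("sizes (diploids):",
      paste(sprintf("%s=%g", names(x$deme_sizes), x$deme_sizes),
            collapse = ", "), "\n")
  if (length(x$split_times))
    cat("splits (gen):",
        paste(sprintf("%s->%s @ %g", names(x$deme_sizes)[x$split_from],
                      names(x$deme_sizes)[x$split_to], x$split_times),
              collapse = "; "), "\n")
  cat(sprintf("migration classes: P(high) = %g\n", x$p_high))
  invisible(x)
}

# backward per-lineage hop-rate matrix for one rate class
.backward_rates <- function(model, rate_class = c("high", "low")) {
  rate_class <- match.arg(rate_class)
  mig <- if (rate_class == "high") model$mig_high else model$mig_low
  sweep(mig, 1, model$deme_sizes, "/")
}

.sim_args <- function(model, rate_class) {
  list(deme_sizes = as.numeric(model$deme_sizes),
       mig = .backward_rates(model, rate_class),
       split_times = model$split_times,
       split_from = as.integer(model$split_from),
       split_to = as.integer(model$split_to),
       split_parent_sizes = model$split_parent_sizes)
}

#' Simulate independent single-SNP genealogies
#'
#' Draws independent genealogies from the structured coalescent under one
#' migration-rate class and places one mutation per genealogy on a branch
#' chosen proportionally to its length, so every simulated site segregates in
#' the total sample. Randomness is driven by R's RNG: call `set.seed()` for
#' reproducibility.
#'
#' @param model a [demographic_model()].
#' @param sample_diploids named integer vector of sampled diploids per deme
#'   (names matching the model's demes; 0 allowed).
#' @param n_snps number of independent SNPs (one per genealogy).
#' @param rate_class `"high"` or `"low"` migration class.
#' @param genotypes if `TRUE`, haploids are paired at random into diploids
#'   within each deme and heterozygote counts are returned.
#' @param mutation_model `"infinite_sites"` (default): genealogies carry a
#'   Poisson number of mutations proportional to their total branch length,
#'   so the marginal site-frequency distribution matches the neutral
#'   infinite-sites expectation; `"one_per_tree"`: exactly one site per
#'   genealogy (ms `-s 1` semantics, which mildly over-weights short
#'   genealogies).
#' @return list with `derived` (SNP x deme derived haploid counts), `tmrca`
#'   (generations), `n_haploids`, and if requested `het` (SNP x deme
#'   heterozygote counts).
#' @export
simulate_snps <- function(model, sample_diploids, n_snps,
                          rate_class = c("high", "low"), genotypes = TRUE,
                          mutation_model = c("infinite_sites",
                                             "one_per_tree")) {
  rate_class <- match.arg(rate_class)
  mutation_model <- match.arg(mutation_model)
  hap <- .match_samples(model, sample_diploids) * 2L
  if (sum(hap > 0) < 1) stop("need samples in at least one deme")
  a <- .sim_args(model, rate_class)
  res <- .sim_snps_cpp(a$deme_sizes, a$mig, a$split_times, a$split_from,
                       a$split_to, a$split_parent_sizes, hap,
                       as.integer(n_snps), genotypes,
                       mutation_model == "one_per_tree")
  colnames(res$derived) <- names(model$deme_sizes)
  if (genotypes) colnames(res$het) <- names(model$deme_sizes)
  res$n_haploids <- hap
  res
}

.match_samples <- function(model, sample_diploids) {
  nms <- names(model$deme_sizes)
  out <- integer(length(nms))
  names(out) <- nms
  if (is.null(names(sample_diploids))) {
    if (length(sample_diploids) != length(nms))
      stop("unnamed sample_diploids must cover every deme")
    out[] <- as.integer(sample_diploids)
  } else {
    if (!all(names(sample_diploids) %in% nms))
      stop("unknown deme in sample_diploids")
    out[names(sample_diploids)] <- as.integer(sample_diploids)
  }
  out
}

#' Neutral PBS null distribution from coalescent simulation
#'
#' For each SNP a migration-rate class is drawn Bernoulli(`p_high`), a
#' genealogy is simulated, one segregating site is placed on it, haploids are
#' paired at random into diploids, pairwise FST is computed and the focal
#' population's PBS recorded. The first deme of `sample_diploids` is focal.
#'
#' @inheritParams simulate_snps
#' @param fst_estimator `"wc"` (Weir-Cockerham, as used on the real data) or
#'   `"hudson"`.
#' @param seed optional integer seed recorded in the metadata; when `NULL`
#'   the current RNG stream is used and no seed is recorded.
#' @return object of class `pbs_null`: list with `pbs` (length `n_snps`) and
#'   `meta`.
#' @export
simulate_null_pbs <- function(model, n_snps, sample_diploids,
                              fst_estimator = c("wc", "hudson"),
                              seed = NULL) {
  fst_estimator <- match.arg(fst_estimator)
  if (!is.null(seed)) set.seed(seed)
  if (length(sample_diploids) != 3 && sum(sample_diploids > 0) != 3)
    stop("PBS null requires samples from three demes")
  n_high <- stats::rbinom(1, n_snps, model$p_high)
  pieces <- list()
  cls <- character(0)
  if (n_high > 0) {
    pieces$high <- simulate_snps(model, sample_diploids, n_high, "high",
                                 genotypes = (fst_estimator == "wc"))
    cls <- c(cls, rep("high", n_high))
  }
  if (n_snps - n_high > 0) {
    pieces$low <- simulate_snps(model, sample_diploids, n_snps - n_high,
                                "low", genotypes = (fst_estimator == "wc"))
    cls <- c(cls, rep("low", n_snps - n_high))
  }
  derived <- do.call(rbind, lapply(pieces, `[[`, "derived"))
  demes <- names(.match_samples(model, sample_diploids))[
    .match_samples(model, sample_diploids) > 0]
  focal <- demes[1]
  o1 <- demes[2]
  o2 <- demes[3]
  hap <- .match_samples(model, sample_diploids) * 2L

  fst_pair <- function(pa, pb) {
    if (fst_estimator == "wc") {
      het <- do.call(rbind, lapply(pieces, `[[`, "het"))
      weir_fst_site(hap[pa] / 2, derived[, pa], het[, pa],
                    hap[pb] / 2, derived[, pb], het[, pb])$theta
    } else {
      .hudson_fst(derived[, pa], hap[pa], derived[, pb], hap[pb])
    }
  }
  pb <- pbs(fst_pair(focal, o1), fst_pair(focal, o2), fst_pair(o1, o2))
  structure(
    list(pbs = pb$pbs, rate_class = cls,
         meta = list(n_snps = n_snps, focal = focal, outgroups = c(o1, o2),
                     estimator = fst_estimator, p_high = model$p_high,
                     seed = seed)),
    class = "pbs_null")
}

#' @export
print.pbs_null <- function(x, ...) {
  cat("pbs_null:", length(x$pbs), "simulated neutral SNPs",
      sprintf("(focal: %s; estimator: %s)\n", x$meta$focal,
              x$meta$estimator))
  cat(sprintf("mean PBS %.4f; 99.9%% threshold %.4f\n",
              mean(x$pbs), quantile_threshold(x$pbs, 0.999)))
  invisible(x)
}

# Hudson's FST estimator from haploid sample frequencies
.hudson_fst <- function(alt1, n1, alt2, n2) {
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Monte-Carlo expected site-frequency spectrum
#'
#' Expected (frequency-normalized) SFS from the mean branch lengths
#' subtending each allele-count class over independent genealogies — the
#' branch-length analogue of the diffusion expectation, exact up to
#' Monte-Carlo error. Supports one or two demes; the folded spectrum is
#' indexed by minor-allele counts with fixed and fold-redundant cells masked.
#'
#' @inheritParams simulate_snps
#' @param sample_haploids named haploid sample sizes (1 or 2 demes > 0).
#' @param n_sims number of genealogies (>= 1000 recommended).
#' @param fold return the folded spectrum?
#' @param normalize divide by the total over unmasked cells?
#' @return matrix `(n1+1) x (n2+1)` (or `(n+1) x 1`) with attribute `mask`
#'   (logical, `TRUE` = masked cell).
#' @export
expected_sfs_mc <- function(model, sample_haploids, n_sims,
                            rate_class = c("high", "low"), fold = TRUE,
                            normalize = TRUE) {
  rate_class <- match.arg(rate_class)
  hapall <- integer(length(model$deme_sizes))
  names(hapall) <- names(model$deme_sizes)
  if (is.null(names(sample_haploids)) &&
      length(sample_haploids) == length(hapall)) {
    hapall[] <- as.integer(sample_haploids)
  } else {
    hapall[names(sample_haploids)] <- as.integer(sample_haploids)
  }
  used <- which(hapall > 0)
  if (length(used) > 2) stop("SFS supported for 1 or 2 sampled demes")
  a <- .sim_args(model, rate_class)
  raw <- .branch_sfs_cpp(a$deme_sizes, a$mig, a$split_times, a$split_from,
                         a$split_to, a$split_parent_sizes,
                         hapall[used], as.integer(n_sims), fold)$mean
  .finish_sfs(raw, fold, normalize)
}

.finish_sfs <- function(raw, fold, normalize) {
  out <- if (fold) fold_sfs(raw) else {
    mask <- matrix(FALSE, nrow(raw), ncol(raw))
    mask[1, 1] <- TRUE
    mask[nrow(raw), ncol(raw)] <- TRUE
    raw[mask] <- 0
    attr(raw, "mask") <- mask
    raw
  }
  if (normalize) {
    tot <- sum(out[!attr(out, "mask")])
    if (tot > 0) out[!attr(out, "mask")] <- out[!attr(out, "mask")] / tot
  }
  out
}

#' Fold a (joint) site-frequency spectrum
#'
#' Folding maps each cell to its minor-allele image: cell `(i, j)` and its
#' complement `(n1-i, n2-j)` are combined, the combined mass stored in the
#' cell whose total allele count is smaller (ties broken toward the first
#' population's smaller count). Fixed cells `(0,0)` and `(n1,n2)` and the
#' redundant half of the matrix are masked and zeroed.
#'
#' @param sfs numeric matrix `(n1+1) x (n2+1)` (use a 1-column matrix for one
#'   population).
#' @return folded matrix with attribute `mask`.
#' @export
fold_sfs <- function(sfs) {
  sfs <- as.matrix(sfs)
  n1 <- nrow(sfs) - 1
  n2 <- ncol(sfs) - 1
  out <- matrix(0, n1 + 1, n2 + 1)
  mask <- matrix(TRUE, n1 + 1, n2 + 1)
  tot <- n1 + n2
  for (i in 0:n1) {
    for (j in 0:n2) {
      d <- i + j
      ii <- n1 - i
      jj <- n2 - j
      keep <- (2 * d < tot) || (2 * d == tot && (i < ii || (i == ii && j <= jj)))
      if (keep) {
        self <- (i == ii && j == jj)
        out[i + 1, j + 1] <- sfs[i + 1, j + 1] +
          if (self) 0 else sfs[ii + 1, jj + 1]
        mask[i + 1, j + 1] <- FALSE
      }
    }
  }
  mask[1, 1] <- TRUE
  out[mask] <- 0
  attr(out, "mask") <- mask
  out
}

#' The three-population model printed by the study
#'
#' Convenience constructor for the stitched Mt. Evans / Lincoln / Merced
#' model used for the neutral PBS null: diploid sizes 368k / 220k / 371k,
#' Lincoln splitting from the Mt. Evans lineage 217k generations ago and
#' Merced 190k generations ago, symmetric migration of 1.75 (Evans-Lincoln)
#' and 2.07 (Evans-Merced) migrants/generation in the high class and 0.08 in
#' the low class, no direct Lincoln-Merced gene flow, and 85% of loci in the
#' high class. The ancestral lineage keeps the Mt. Evans size.
#'
#' @param p_high proportion of loci in the high-migration class.
#' @return a [demographic_model()].
#' @export
deer_mouse_model <- function(p_high = 0.85) {
  sizes <- c(evans = 368000, lincoln = 220000, merced = 371000)
  mig_h <- matrix(0, 3, 3)
  mig_h[1, 2] <- mig_h[2, 1] <- 1.75
  mig_h[1, 3] <- mig_h[3, 1] <- 2.07
  mig_l <- matrix(0, 3, 3)
  mig_l[1, 2] <- mig_l[2, 1] <- 0.08
  mig_l[1, 3] <- mig_l[3, 1] <- 0.08
  demographic_model(
    deme_sizes = sizes,
    split_times = c(190000, 217000),
    split_from = c("merced", "lincoln"),
    split_to = c("evans", "evans"),
    split_parent_sizes = c(NA, 368000),
    mig_high = mig_h, mig_low = mig_l, p_high = p_high)
}
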