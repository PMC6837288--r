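test_that("expression filtering uses library-size normalized means", {
  counts <- rbind(keep = c(10, 10), zero = c(0, 0), low = c(3, 3))
  expect_equal(rownames(filter_low_expression(counts, 10)), "keep")

  # libraries (100, 300) with gene counts (5, 15): normalized (10, 10)
  m <- rbind(g1 = c(5, 15), g2 = c(95, 285))
  kept <- filter_low_expression(m, 10)
  expect_true("g1" %in% rownames(kept))
  expect_error(filter_low_expression(rbind(c(0, 0)), 10), "no genes")
})

test_that("TMM factors reproduce the trimmed-mean closed forms", {
  set.seed(61)
  base <- matrix(rpois(400 * 2, 50), 400, 2)
  base[, 2] <- base[, 1]
  expect_equal(tmm_factors(base), c(1, 1), tolerance = 1e-9)

  # one library exactly double the other: factors (1/g, g) with g^2 = 2
  doubled <- cbind(base[, 1], 2 * base[, 1])
  f <- tmm_factors(doubled)
  expect_equal(f[2] / f[1], 2, tolerance = 1e-6)
  expect_equal(prod(f), 1, tolerance = 1e-6)
  expect_equal(f, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  # geometric mean is always one
  set.seed(62)
  m <- matrix(rnbinom(500 * 6, mu = 60, size = 5), 500, 6)
  expect_equal(exp(mean(log(tmm_factors(m)))), 1, tolerance = 1e-9)
})

test_that("log fold-changes follow the prior-count group-mean formula", {
  groups <- c("HH", "HH", "LL", "LL")
  equal_m <- matrix(c(30, 30, 30, 30), 1, 4,
                    dimnames = list("g1", NULL))
  lfc0 <- log_fold_change(equal_m, groups, c("HH", "LL"),
                          norm_factors = rep(1, 4))
  expect_equal(unname(lfc0["g1"]), 0)

  # group means 40 vs 10 with equal effective libraries
  m <- rbind(g1 = c(40, 40, 10, 10), g2 = c(60, 60, 90, 90))
  lfc <- log_fold_change(m, groups, c("HH", "LL"),
                         norm_factors = rep(1, 4))
  expect_equal(unname(lfc["g1"]), log2(40.5 / 10.5), tolerance = 1e-12)
  expect_equal(unname(lfc["g1"]), 1.94753, tolerance = 1e-5)

  # both group means zero: the prior cancels
  mz <- rbind(g1 = c(0, 0, 0, 0), g2 = c(50, 50, 50, 50))
  lfcz <- log_fold_change(mz, groups, c("HH", "LL"),
                          norm_factors = rep(1, 4))
  expect_equal(unname(lfcz["g1"]), 0)

  expect_error(log_fold_change(m, groups, c("HH", "XX")), "absent")
})

test_that("scaling every library by a common constant leaves LFC unchanged", {
  set.seed(63)
  g <- gen_expression_counts(n_genes = 300, group_sizes = c(LL = 4, HH = 4),
                             candidate_size = 20, shift = 0.5)
  # exact without the pseudocount (pure normalized ratio)
  l1 <- log_fold_change(g$counts, g$groups, c("HH", "LL"), prior_count = 0)
  l2 <- log_fold_change(g$counts * 3L, g$groups, c("HH", "LL"),
                        prior_count = 0)
  expect_equal(unclass(l1), unclass(l2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # with the default pseudocount the effect of depth is bounded by the
  # prior's weight, which is negligible for genes passing the standard
  # expression filter
  p1 <- log_fold_change(g$counts, g$groups, c("HH", "LL"))
  p2 <- log_fold_change(g$counts * 3L, g$groups, c("HH", "LL"))
  expressed <- rowMeans(g$counts) >= 10
  expect_lt(max(abs(p1 - p2)[expressed]), 0.1)
  expect_gt(cor(p1, p2), 0.999)
})

test_that("K-S shift statistic matches enumeration and ks.test", {
  expect_equal(ks_shift(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_shift(c(1, 3), c(2, 4))$D, 0.5)
  same <- ks_shift(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$sign, 0)

  set.seed(64)
  for (i in 1:100) {
    # small vectors with deliberate ties
    x <- sample(1:6, sample(2:9, 1), replace = TRUE) + 0.5 * rbinom(1, 1, 0.5)
    y <- sample(1:6, sample(2:9, 1), replace = TRUE)
    expect_equal(ks_shift(x, y)$D, ks_d_brute(x, y), tolerance = 1e-12)
  }

  # continuous data: D and asymptotic p agree with stats::ks.test
  set.seed(65)
  x <- rnorm(60)
  y <- rnorm(80, 0.4)
  got <- ks_shift(x, y)
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_asymptotic, ref$p.value, tolerance = 1e-6)

  named_x <- setNames(x[1:5], paste0("g", 1:5))
  named_y <- setNames(y[1:5], paste0("g", 3:7))
  expect_error(ks_shift(named_x, named_y), "exclude")
})

test_that("permutation null is reproducible and its q99 shrinks with set size", {
  set.seed(66)
  lfc <- setNames(rnorm(2000), paste0("g", 1:2000))
  set.seed(5)
  n1 <- permutation_null(lfc, 50, 200)
  set.seed(5)
  n2 <- permutation_null(lfc, 50, 200)
  expect_identical(n1$null_d, n2$null_d)
  expect_equal(n1$q99, quantile_threshold(n1$null_d, 0.99))

  set.seed(6)
  q10 <- permutation_null(lfc, 10, 300)$q99
  q100 <- permutation_null(lfc, 100, 300)$q99
  q1000 <- permutation_null(lfc, 1000, 300)$q99
  expect_gt(q10, q100)
  expect_gt(q100, q1000)

  expect_error(permutation_null(lfc, 2000, 200), "smaller")
  expect_error(permutation_null(lfc, 50, 10), "at least 100")
})

test_that("the composed gene-set test detects a concerted shift", {
  set.seed(67)
  g <- gen_expression_counts(n_genes = 2000,
                             group_sizes = c(LL = 3, HL = 8, HH = 8),
                             candidate_size = 60, shift = 0.6,
                             dispersion = 0.1)
  res <- geneset_shift_test(g$counts, g$groups, g$candidate_ids,
                            contrast = c("HH", "LL"), n_perm = 200)
  expect_s3_class(res, "geneset_shift")
  expect_true(res$decision)
  expect_equal(res$sign, 1)
  expect_true(res$D > res$q99)
  expect_lt(res$p_asymptotic, 0.01)
  expect_output(print(res), "concerted shift detected")
  expect_error(geneset_shift_test(g$counts, g$groups, c("absent1", "absent2"),
                                  n_perm = 200), "fewer than 2")
})

test_that("the gene-set test is invariant to gene and sample reordering", {
  set.seed(68)
  g <- gen_expression_counts(n_genes = 800, group_sizes = c(LL = 4, HH = 4),
                             candidate_size = 40, shift = 0.5)
  run <- function(counts, groups) {
    set.seed(99)
    geneset_shift_test(counts, groups, g$candidate_ids,
                       contrast = c("HH", "LL"), n_perm = 150)
  }
  base <- run(g$counts, g$groups)
  perm_genes <- sample(nrow(g$counts))
  r_genes <- run(g$counts[perm_genes, ], g$groups)
  expect_equal(r_genes$D, base$D, tolerance = 1e-12)
  expect_equal(r_genes$q99, base$q99, tolerance = 1e-12)
  # swap samples within the HH group
  ord <- seq_along(g$groups)
  hh <- which(g$groups == "HH")
  ord[hh] <- rev(hh)
  r_samp <- run(g$counts[, ord], g$groups[ord])
  expect_equal(r_samp$D, base$D, tolerance = 1e-12)
})

test_that("directional contrast compares regulator sets by permutation", {
  lfc <- setNames(c(1, 1, 1, -1, -1, -1), paste0("g", 1:6))
  same <- directional_contrast(lfc, c("g1", "g2", "g3"),
                               c("g4", "g5", "g6"))
  # identical magnitude, opposite sign sets: difference 2, exact p = 2/20
  expect_equal(same$difference, 2)
  expect_true(same$exact)
  expect_equal(same$p_permutation, 2 / 20)

  flat <- setNames(rep(0.3, 6), paste0("g", 1:6))
  r <- directional_contrast(flat, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(r$difference, 0)
  expect_equal(r$p_permutation, 1)
  expect_equal(r$se_pos, 0)

  expect_error(directional_contrast(lfc, c("g1", "g2"), c("g2", "g3")),
               "overlap")
})

test_that("naive per-gene DE screen controls format and FDR monotonicity", {
  set.seed(69)
  g <- gen_expression_counts(n_genes = 150, group_sizes = c(LL = 4, HH = 4),
                             candidate_size = 10, shift = 2)
  de <- de_test_naive(g$counts, g$groups, c("HH", "LL"))
  expect_equal(nrow(de), 150)
  expect_true(all(de$fdr >= de$p - 1e-12))
  expect_equal(de$fdr, p.adjust(de$p, "BH"))
})
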