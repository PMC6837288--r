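im_model <- function(mig = 1)
  demographic_model(c(a = 1000, b = 1000), split_times = 2000,
                    split_from = "b", split_to = "a",
                    split_parent_sizes = 1000, mig_high = mig)

test_that("pairwise coalescence times follow the standard coalescent", {
  m <- demographic_model(c(a = 1000))
  set.seed(1)
  r <- simulate_snps(m, c(a = 1), 5000, genotypes = FALSE,
                     mutation_model = "one_per_tree")
  # E[TMRCA] = 2N generations for two lineages; TMRCA ~ Exp so SE = 2N/sqrt(n)
  se <- 2000 / sqrt(5000)
  expect_lt(abs(mean(r$tmrca) - 2000), 3 * se)
  # a mutation on a 2-leaf genealogy always subtends exactly one leaf
  expect_true(all(r$derived[, 1] == 1))
})

test_that("no between-deme coalescence occurs more recently than the split", {
  m <- demographic_model(c(a = 1000, b = 1000), split_times = 5000,
                         split_from = "b", split_to = "a", mig_high = 0)
  set.seed(2)
  r <- simulate_snps(m, c(a = 1, b = 1), 300, genotypes = FALSE,
                     mutation_model = "one_per_tree")
  # the root joins lineages from both demes, which cannot happen pre-split
  expect_true(all(r$tmrca >= 5000))
})

test_that("neutral site-frequency spectra match closed forms", {
  m <- demographic_model(c(a = 1000))
  set.seed(3)
  # expected SFS by branch lengths, n = 4 haploids: xi_i proportional to 1/i
  sf <- expected_sfs_mc(m, c(a = 4), 50000, fold = FALSE)
  expect_lt(max(abs(sf[2:4, 1] - c(6, 3, 2) / 11)), 0.01)
  sff <- expected_sfs_mc(m, c(a = 4), 50000, fold = TRUE)
  expect_lt(max(abs(sff[2:3, 1] - c(8, 3) / 11)), 0.01)
  # sampled SNPs reproduce the same law under infinite-sites placement
  set.seed(4)
  r <- simulate_snps(m, c(a = 2), 50000, genotypes = FALSE)
  props <- tabulate(r$derived[, 1], 3) / 50000
  expect_lt(max(abs(props - c(6, 3, 2) / 11)), 0.012)
})

test_that("two-deme island model FST matches the coalescent closed form", {
  # eternal two-deme island model, N = 1000 diploids, M = 1 migrant/gen:
  # E[T_within] = 4N and E[T_between] = 4N + N/M generations, giving
  # Hudson FST = 1/(1 + 8M) (equivalently 1/(1+16Nm) with m = M/(2N))
  m <- demographic_model(c(a = 1000, b = 1000), split_times = 1e9,
                         split_from = "b", split_to = "a", mig_high = 1)
  set.seed(5)
  r <- simulate_snps(m, c(a = 10, b = 10), 20000, genotypes = FALSE)
  p1 <- r$derived[, 1] / 20
  p2 <- r$derived[, 2] / 20
  num <- (p1 - p2)^2 - p1 * (1 - p1) / 19 - p2 * (1 - p2) / 19
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_lt(abs(sum(num) / sum(den) - 1 / 9), 0.02)
})

test_that("folded 2D-SFS agrees with the independent simulator oracle", {
  oracle <- fold_sfs(msp_im_sfs)
  oracle <- oracle / sum(oracle)
  set.seed(6)
  ours <- expected_sfs_mc(im_model(1), c(a = 6, b = 6), 50000)
  tv <- sum(abs(ours - oracle)) / 2
  expect_lt(tv, 0.02)
})

test_that("the joint SFS is symmetric under deme exchange for a symmetric model", {
  # the unfolded spectrum is used: folding's tie-break on the minor-allele
  # anti-diagonal places mass asymmetrically by construction
  set.seed(7)
  s1 <- expected_sfs_mc(im_model(1), c(a = 4, b = 4), 40000, fold = FALSE)
  expect_lt(sum(abs(s1 - t(s1))), 0.06)
})

test_that("a near-panmictic model yields a PBS null concentrated at zero", {
  # scaled migration 2*N*m = 100 per lineage: demes are effectively one
  # population, so PBS reflects only sampling noise around zero
  m <- demographic_model(c(a = 1e4, b = 1e4, c = 1e4),
                         split_times = c(1e6, 2e6),
                         split_from = c("b", "c"), split_to = c("a", "a"),
                         mig_high = 50)
  null <- simulate_null_pbs(m, 3000, c(a = 48, b = 37, c = 15), seed = 8)
  expect_lt(abs(mean(null$pbs)), 0.01)
  expect_lt(quantile_threshold(null$pbs, 0.999), 0.12)
})

test_that("a degenerate migration mixture is independent of the mixing proportion", {
  base <- c(a = 1000, b = 1000, c = 1000)
  mk <- function(p) demographic_model(
    base, split_times = c(2000, 4000), split_from = c("b", "c"),
    split_to = c("a", "a"), mig_high = 0.5, mig_low = 0.5, p_high = p)
  n1 <- simulate_null_pbs(mk(1), 3000, c(a = 10, b = 10, c = 10), seed = 9)
  n0 <- simulate_null_pbs(mk(0), 3000, c(a = 10, b = 10, c = 10), seed = 10)
  expect_gt(suppressWarnings(ks.test(n1$pbs, n0$pbs)$p.value), 0.01)
})

test_that("the PBS null is invariant to exchanging symmetric outgroups", {
  mk <- function(perm) {
    sizes <- c(a = 2000, b = 1000, c = 1000)
    demographic_model(sizes, split_times = c(3000, 6000),
                      split_from = perm, split_to = c("a", "a"),
                      mig_high = 0.5)
  }
  nb <- simulate_null_pbs(mk(c("b", "c")), 3000,
                          c(a = 12, b = 10, c = 10), seed = 11)
  nc <- simulate_null_pbs(mk(c("c", "b")), 3000,
                          c(a = 12, b = 10, c = 10), seed = 12)
  expect_gt(suppressWarnings(ks.test(nb$pbs, nc$pbs)$p.value), 0.01)
})

test_that("null simulation is bit-reproducible under a fixed seed", {
  m <- im_model(0.5)
  m3 <- demographic_model(c(a = 1000, b = 1000, c = 1000),
                          split_times = c(2000, 4000),
                          split_from = c("b", "c"), split_to = c("a", "a"),
                          mig_high = 1, mig_low = 0.05, p_high = 0.8)
  n1 <- simulate_null_pbs(m3, 500, c(a = 5, b = 5, c = 5), seed = 99)
  n2 <- simulate_null_pbs(m3, 500, c(a = 5, b = 5, c = 5), seed = 99)
  expect_identical(n1$pbs, n2$pbs)
  expect_identical(n1$rate_class, n2$rate_class)
})

test_that("model construction validates its invariants", {
  expect_error(demographic_model(c(a = -1)), "positive")
  expect_error(demographic_model(c(a = 1, b = 1), split_times = c(2, 1),
                                 split_from = c("b", "b"),
                                 split_to = c("a", "a")), "increasing")
  expect_error(demographic_model(c(a = 1, b = 1)), "splits")
  expect_error(demographic_model(c(a = 1, b = 1), split_times = 10,
                                 split_from = "b", split_to = "a",
                                 mig_high = matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  expect_error(demographic_model(c(a = 1, b = 1), split_times = 10,
                                 split_from = "b", split_to = "a",
                                 p_high = 1.2), "p_high")
})
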