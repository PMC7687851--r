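test_that("allele counts summarize genotype matrices", {
  cs <- allele_count_summary(rbind(c(0, 1), c(2, 1)))
  expect_equal(cs$minor_counts, c(2, 2))
  expect_equal(cs$allele_total, 4L)
  expect_equal(allele_count_summary(matrix(0, 3, 2))$minor_counts, c(0, 0))
  expect_equal(allele_count_summary(matrix(c(1, 0, 2), 1))$minor_counts,
               c(1, 0, 2))
  expect_equal(allele_count_summary(matrix(c(1, 0, 2), 1))$allele_total, 2L)
  expect_error(allele_count_summary(matrix(c(0, 3), 1)), "invalid genotype")
})

test_that("proportion vectors normalize regularized counts", {
  expect_equal(proportion_vector(c(3, 1), pseudocount = 0), c(0.75, 0.25))
  expect_equal(proportion_vector(c(0, 4), pseudocount = 0.5), c(0.1, 0.9))
  expect_equal(proportion_vector(c(2, 2, 2), pseudocount = 7), rep(1 / 3, 3))
  expect_error(proportion_vector(c(0, 4), pseudocount = 0), "zero count")
  expect_error(proportion_vector(c(1, 2), pseudocount = -1), "non-negative")
})

test_that("T_KL matches hand-computed values and its invariants", {
  expect_equal(t_kl(c(0.75, 0.25), c(0.25, 0.75)), 0.5 * log(3))
  expect_equal(t_kl(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_error(t_kl(c(0.5, 0.5), c(1)), "equal length")
  expect_error(t_kl(c(0, 1), c(0.5, 0.5)), "strictly positive")

  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:30, 1)
    a <- proportion_vector(stats::rgamma(k, 1), pseudocount = 0.1)
    b <- proportion_vector(stats::rgamma(k, 1), pseudocount = 0.1)
    expect_identical(t_kl(a, b), t_kl(b, a))
    expect_gte(t_kl(a, b), 0)
  }
  # zero iff equal: perturbing any vector makes the statistic positive
  a <- rep(0.25, 4)
  b <- c(0.25 + 1e-6, 0.25 - 1e-6, 0.25, 0.25)
  expect_gt(t_kl(a, b), 0)
})

test_that("frequency-domain T_KL agrees with the proportion-domain form", {
  cnt <- function(x, total) {
    structure(list(minor_counts = x, allele_total = total),
              class = "allele_count_summary")
  }
  expect_equal(t_kl_from_frequencies(cnt(c(3, 1), 4), cnt(c(1, 3), 4),
                                     pseudocount = 0),
               0.5 * log(3), tolerance = 1e-12)
  expect_equal(t_kl_from_frequencies(cnt(c(2, 5), 20), cnt(c(2, 5), 20),
                                     pseudocount = 0), 0)
  set.seed(32)
  for (i in 1:25) {
    k <- sample(3:40, 1)
    total <- 2L * sample(20:200, 1)
    cu <- cnt(stats::rbinom(k, total, 0.05), total)
    cl <- cnt(stats::rbinom(k, total, 0.05), total)
    expect_equal(t_kl_from_frequencies(cu, cl, 0.5),
                 t_kl(proportion_vector(cu, 0.5), proportion_vector(cl, 0.5)),
                 tolerance = 1e-10)
  }
})

test_that("permutation test behaves at its boundaries", {
  g <- matrix(c(0, 1, 2, 0, 1, 0, 2, 1), 4, 2)
  xs <- extreme_sample(upper = g, lower = g)
  set.seed(33)
  res <- permutation_test(xs, n_permutations = 200)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)  # every permuted statistic is >= 0

  # disjoint carriers: observed statistic beats every permutation
  up <- matrix(c(rep(2L, 6), rep(0L, 6)), 6, 2)
  lo <- matrix(c(rep(0L, 6), rep(2L, 6)), 6, 2)
  xs2 <- extreme_sample(upper = up, lower = lo)
  set.seed(34)
  res2 <- permutation_test(xs2, n_permutations = 300)
  expect_equal(res2$p_value, 0)
  res3 <- permutation_test(xs2, n_permutations = 300, add_one = TRUE)
  expect_equal(res3$p_value, 1 / 301)

  expect_error(permutation_test(xs, n_permutations = 0), "n_permutations")
  expect_equal(res$p_value, res$perm_exceed_count / res$n_permutations)
})

test_that("permutation p-values are uniform under exchangeability", {
  set.seed(35)
  sc <- scenario_config(s = 0, two_n = 100, fraction = 0.2, k = 20)
  b <- 200
  pv <- klrare:::assoc_pvalues(sc, n_sims = 500, n_permutations = b)
  # p = count/B lives on a discrete grid; the randomized PIT of the
  # exceedance count is exactly Uniform(0,1) under exchangeability
  u <- (round(pv * b) + stats::runif(length(pv))) / (b + 1)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("type-I error tracks the nominal level at scaled-down settings", {
  sc <- scenario_config(s = 0, two_n = 100, fraction = 0.2, k = 20)
  res <- assoc_experiment(sc, n_sims = 150, n_permutations = 200, seed = 36)
  for (a in c(0.05, 0.01)) {
    r <- mean(res$p_values <= a)
    expect_lt(abs(r - a), 3 * sqrt(a * (1 - a) / 150))
  }
  # alpha = 1 rejects always; alpha = 0 rejects at most as often as any alpha
  expect_equal(mean(res$p_values <= 1), 1)
  expect_lte(mean(res$p_values <= 0), mean(res$p_values <= 0.05))
})

test_that("power rises with selection stringency", {
  # operating point chosen inside (0, 1) so the ordering is informative
  powers <- vapply(c(0.20, 0.10, 0.05), function(f) {
    sc <- scenario_config(s = 4, c = 0.12, n_positive = 4, two_n = 140,
                          fraction = f, k = 30)
    res <- assoc_experiment(sc, n_sims = 80, n_permutations = 150, seed = 37)
    res$rejection_rate
  }, numeric(1))
  se2 <- 2 * sqrt(pmax(powers * (1 - powers), 0.25 / 80) / 80)
  expect_gte(powers[2], powers[1] - (se2[1] + se2[2]))
  expect_gte(powers[3], powers[2] - (se2[2] + se2[3]))
})

test_that("experiments reproduce bit-for-bit under a fixed seed", {
  sc <- scenario_config(s = 2, c = 0.3, n_positive = 2, two_n = 40,
                        fraction = 0.2, k = 10)
  r1 <- assoc_experiment(sc, n_sims = 10, n_permutations = 50, seed = 38)
  r2 <- assoc_experiment(sc, n_sims = 10, n_permutations = 50, seed = 38)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$rejection_rate, r2$rejection_rate)
})
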