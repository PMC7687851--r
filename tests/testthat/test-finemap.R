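test_that("tail frequencies count alleles and regularize boundaries", {
  xs <- sample_with_counts(c(3, 0), c(1, 4), n = 2)
  tf <- tail_frequencies(xs)
  expect_equal(tf$p_upper, c(3 / 4, 0.5 / 4))
  expect_equal(tf$p_lower, c(1 / 4, 3.5 / 4))  # full count 4 -> 2N - 0.5

  # monomorphic column in a large tail
  big <- extreme_sample(upper = matrix(0L, 750, 1),
                        lower = matrix(0L, 750, 1))
  expect_equal(tail_frequencies(big)$p_upper, 0.5 / 1500)

  same <- sample_with_counts(c(2, 3), c(2, 3), n = 3)
  tf2 <- tail_frequencies(same)
  expect_equal(tf2$p_upper, tf2$p_lower)
})

test_that("kl_h matches hand values and is a symmetric divergence", {
  expect_equal(kl_h(0.3, 0.3), 0)
  expect_equal(kl_h(0.6, 0.4), 0.2 * log(1.5))
  set.seed(51)
  u <- stats::runif(50, 0.01, 0.99)
  l <- stats::runif(50, 0.01, 0.99)
  expect_equal(kl_h(u, l), kl_h(l, u), tolerance = 1e-12)
  expect_true(all(kl_h(u, l) >= 0))
  expect_true(all(kl_h(u, l)[abs(u - l) > 1e-6] > 0))
  expect_error(kl_h(0, 0.5), "strictly inside")
  expect_error(kl_h(0.5, 1), "strictly inside")
})

test_that("l_KL profiles compose frequency and divergence correctly", {
  # p_U = 0.6, p_L = 0.4 at both variants: pooled p = 0.5, ratio 1
  xs <- sample_with_counts(c(6, 6), c(4, 4), n = 5)
  pr <- l_kl_profile(xs, window = 1)
  expect_equal(pr$l_kl, rep(0.2 * log(1.5), 2))
  expect_equal(pr$p_pooled, c(0.5, 0.5))

  # equal tails give a zero profile
  same <- sample_with_counts(c(2, 5, 1), c(2, 5, 1), n = 4)
  expect_equal(l_kl_profile(same, window = 1)$l_kl, rep(0, 3))

  # external population frequency overrides the tail mean
  pr2 <- l_kl_profile(xs, window = 1, pop_freq = c(0.2, 0.2))
  expect_equal(pr2$l_kl, (0.2 / 0.8) * kl_h(0.6, 0.4) * c(1, 1))
})

test_that("l_KL is invariant to marker frequency under identical LD", {
  # the invariance is a small-signal property: use a weak-effect trait so the
  # tail-frequency differences stay in the regime where it holds
  set.seed(52)
  p_a <- 0.2
  mafs <- c(0.25, 0.45)
  n <- 1200
  nt <- 300
  stats_mat <- replicate(500, {
    g <- direct_ld_genotypes(n, p_a, mafs)
    y <- g$qtl + stats::rnorm(n, 0, 2)
    ord <- order(y)
    xs <- extreme_sample(upper = g$markers[ord[seq.int(n - nt + 1, n)], ,
                                           drop = FALSE],
                         lower = g$markers[ord[seq_len(nt)], , drop = FALSE])
    tf <- tail_frequencies(xs)
    pr <- l_kl_profile(xs, window = 1)
    c(pr$l_kl, kl_h(tf$p_upper, tf$p_lower))
  })
  l_means <- rowMeans(stats_mat)[1:2]
  h_means <- rowMeans(stats_mat)[3:4]
  # the scaled measure agrees across MAFs; the raw divergence does not
  expect_lt(abs(l_means[1] - l_means[2]) / max(l_means), 0.10)
  expect_gt(h_means[1] / h_means[2], 1.5)
})

test_that("moving average matches a brute-force oracle", {
  brute <- function(x, w) {
    h <- (w - 1) / 2
    vapply(seq_along(x), function(i) {
      mean(x[max(1, i - h):min(length(x), i + h)])
    }, numeric(1))
  }
  expect_equal(moving_average(c(0, 0, 0, 0, 5, 0, 0, 0, 0), 5),
               c(0, 0, 1, 1, 1, 1, 1, 0, 0))
  expect_equal(moving_average(rep(2.5, 8), 5), rep(2.5, 8))
  set.seed(53)
  for (w in c(1, 3, 5, 7)) {
    x <- stats::rnorm(25)
    expect_equal(moving_average(x, w), brute(x, w))
  }
  x <- stats::rnorm(10)
  expect_identical(moving_average(x, 1), x)
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 11), "odd|length")
})

test_that("localization declares hits on targets and ties", {
  mk <- function(smoothed) {
    structure(list(smoothed = smoothed,
                   peak_indices = klrare:::which_peaks(smoothed)),
              class = "finemap_profile")
  }
  x <- rep(0, 21); x[10] <- 1
  expect_true(localize(mk(x), c(10, 11)))
  x2 <- rep(0, 21); x2[1] <- 1
  expect_false(localize(mk(x2), c(10, 11)))
  expect_true(localize(mk(rep(0.3, 21)), c(10, 11)))  # 21-way tie
})

test_that("mean l_KL decays with recombination distance from the QTL", {
  set.seed(54)
  pop <- init_population(p_a = 0.05, marker_mafs = rep(0.05, 9),
                         pop_size = 3000,
                         rec_fractions = default_rec_fractions(
                           0.02, n_markers = 9, qtl_after = 4),
                         qtl_after = 4)
  pop <- evolve(pop, 30)
  model <- qtl_model(p_a = 0.05, d_over_v = 0, h2 = 0.3)
  prof <- rowMeans(replicate(60, {
    l_kl_profile(draw_finemap_sample(pop, model, 0.2, 300), window = 1)$l_kl
  }))
  dist <- abs(seq_len(9) - 4.5)
  expect_lt(stats::cor(prof, dist), -0.5)
  expect_gt(mean(prof[4:5]), mean(prof[c(1, 9)]))
})

test_that("localization power behaves at its limits", {
  set.seed(55)
  # no genetic signal: peak lands near-uniformly among smoothed positions
  null_model <- qtl_model(p_a = 0.05, d_over_v = 0, h2 = 0.001)
  res <- finemap_power(null_model, fraction = 0.2, n_populations = 8,
                       n_samples_per_pop = 5, n_per_tail = 100,
                       pop_size = 1000, n_generations = 5, n_markers = 21)
  expect_gte(res$power, 0)
  expect_lte(res$power, 1)
  # 2/21 under uniformity; allow generous Monte-Carlo + edge-effect slack
  expect_lt(res$power, 2 / 21 + 4 * sqrt((2 / 21) * (19 / 21) / 40) + 0.1)
  expect_equal(res$n_samples, 40)
  expect_equal(res$power, res$hits / res$n_samples)

  # single Bernoulli trial
  res1 <- finemap_power(qtl_model(h2 = 0.1), fraction = 0.2,
                        n_populations = 1, n_samples_per_pop = 1,
                        n_per_tail = 50, pop_size = 500, n_generations = 2)
  expect_true(res1$power %in% c(0, 1))
})
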