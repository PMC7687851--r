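#' Summarize minor-allele counts of a genotype matrix
#'
#' @param genotypes matrix (individuals x variants) of minor-allele counts in
#'   {0, 1, 2}.
#' @return An object of class `"allele_count_summary"`: list with
#'   `minor_counts` (per-variant column sums) and `allele_total` (2 x number
#'   of individuals).
#' @export
#' @examples
#' allele_count_summary(rbind(c(0, 1), c(2, 1)))  # counts 2, 2 of total 4
allele_count_summary <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 1 || ncol(genotypes) < 1) {
    stop("genotype matrix must be non-empty", call. = FALSE)
  }
  if (!all(genotypes %in% 0:2)) {
    stop("invalid genotype: entries must be 0, 1 or 2", call. = FALSE)
  }
  structure(list(minor_counts = unname(colSums(genotypes)),
                 allele_total = 2L * nrow(genotypes)),
            class = "allele_count_summary")
}

#' Across-variant minor-allele proportion vector
#'
#' Normalizes per-variant minor-allele counts of one tail into the
#' across-variant proportion distribution that the T_KL statistic compares: a
#' pseudocount is added to every count (to keep the vector strictly positive
#' when rare variants carry no minor alleles in a tail) and the regularized
#' counts are divided by their sum.
#'
#' @param counts an [allele_count_summary()] or a plain non-negative numeric
#'   vector of counts.
#' @param pseudocount non-negative regularization added to every count
#'   (default 0.5). With `pseudocount = 0` every count must be positive.
#' @return Numeric vector summing to 1 with all entries > 0.
#' @export
#' @examples
#' proportion_vector(c(3, 1), pseudocount = 0)    # 0.75 0.25
#' proportion_vector(c(0, 4), pseudocount = 0.5)  # 0.1 0.9
proportion_vector <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "allele_count_summary")) counts <- counts$minor_counts
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("zero count with zero pseudocount: proportion vector would leave ",
         "the KL statistic undefined", call. = FALSE)
  }
  reg <- counts + pseudocount
  reg / sum(reg)
}

#' Symmetrized Kullback-Leibler distance between two proportion vectors
#'
#' The stage-1 association statistic: the mean of the two directed KL
#' divergences between the across-variant minor-allele proportion vectors of
#' the upper and lower extreme samples,
#' \deqn{T_{KL} = \frac12\left(\sum_i p^U_i \log\frac{p^U_i}{p^L_i}
#'   + \sum_i p^L_i \log\frac{p^L_i}{p^U_i}\right),}
#' using the natural logarithm. It is non-negative, symmetric in its
#' arguments, and zero iff the two vectors are identical.
#'
#' @param p_upper,p_lower strictly positive numeric vectors of equal length
#'   summing to 1 (see [proportion_vector()]).
#' @return The statistic, a non-negative scalar.
#' @export
#' @examples
#' t_kl(c(0.75, 0.25), c(0.25, 0.75))  # 0.5 * log(3)
t_kl <- function(p_upper, p_lower) {
  if (length(p_upper) != length(p_lower)) {
    stop("proportion vectors must have equal length", call. = FALSE)
  }
  if (any(p_upper <= 0) || any(p_lower <= 0)) {
    stop("proportion vectors must be strictly positive", call. = FALSE)
  }
  0.5 * (sum(p_upper * log(p_upper / p_lower)) +
           sum(p_lower * log(p_lower / p_upper)))
}

#' T_KL from per-tail allele frequencies
#'
#' Frequency-domain formulation of the statistic: per-tail allele frequencies
#' `p_mi = X_i / 2N` are renormalized within tail and compared, which is
#' algebraically identical to [t_kl()] on the [proportion_vector()]s (the
#' tail totals cancel inside the weights and the log ratio). Kept as an
#' independent cross-check path for the statistic.
#'
#' @param counts_upper,counts_lower [allele_count_summary()] objects for the
#'   two tails.
#' @param pseudocount regularization added to each count before forming
#'   frequencies (default 0.5).
#' @return The statistic, equal to the [t_kl()] value within floating-point
#'   tolerance.
#' @export
t_kl_from_frequencies <- function(counts_upper, counts_lower,
                                  pseudocount = 0.5) {
  stopifnot(inherits(counts_upper, "allele_count_summary"),
            inherits(counts_lower, "allele_count_summary"))
  if (length(counts_upper$minor_counts) != length(counts_lower$minor_counts)) {
    stop("tails must cover the same variants", call. = FALSE)
  }
  if (pseudocount == 0 && (any(counts_upper$minor_counts == 0) ||
                           any(counts_lower$minor_counts == 0))) {
    stop("zero count with zero pseudocount", call. = FALSE)
  }
  p_u <- (counts_upper$minor_counts + pseudocount) / counts_upper$allele_total
  p_l <- (counts_lower$minor_counts + pseudocount) / counts_lower$allele_total
  su <- sum(p_u)
  sl <- sum(p_l)
  # symmetrized divergence with within-tail renormalized weights; the second
  # sum is weighted by the lower-tail frequencies, mirroring the first
  0.5 * (sum((p_u / su) * log((p_u / p_l) * (sl / su))) +
           sum((p_l / sl) * log((p_l / p_u) * (su / sl))))
}

# T_KL for many count configurations at once: `counts_u`, `counts_l` are
# k x B matrices of regularized (strictly positive) counts; returns length-B
# vector of statistics. Shared by permutation_test.
t_kl_columns <- function(counts_u, counts_l) {
  p_u <- counts_u / rep(colSums(counts_u), each = nrow(counts_u))
  p_l <- counts_l / rep(colSums(counts_l), each = nrow(counts_l))
  0.5 * colSums((p_u - p_l) * log(p_u / p_l))
}

#' Permutation test of association for an extreme sample
#'
#' Computes the observed T_KL between the upper- and lower-tail samples, then
#' repeatedly repartitions the pooled individuals at random into groups of
#' the original tail sizes and recomputes the statistic under the same
#' pseudocount rule. The p-value is the proportion of permuted statistics at
#' least as large as the observed one (ties count as exceedances); with
#' `add_one = TRUE` the (1 + count) / (1 + B) estimator is used instead.
#'
#' @param sample an [extreme_sample()].
#' @param n_permutations number of balanced relabelings B (default 1000).
#' @param pseudocount per-variant count regularization (default 0.5), applied
#'   identically to observed and permuted statistics so the permutation null
#'   is preserved by construction.
#' @param add_one use the (1 + count) / (1 + B) p-value estimator.
#' @return An object of class `"assoc_result"`: list with `statistic`,
#'   `p_value`, `n_permutations`, `perm_exceed_count` and `perm_stats` (the
#'   permuted statistics).
#' @export
permutation_test <- function(sample, n_permutations = 1000, pseudocount = 0.5,
                             add_one = FALSE) {
  if (n_permutations < 1) {
    stop("invalid configuration: n_permutations must be at least 1",
         call. = FALSE)
  }
  cu <- allele_count_summary(sample$upper)
  cl <- allele_count_summary(sample$lower)
  observed <- t_kl(proportion_vector(cu, pseudocount),
                   proportion_vector(cl, pseudocount))

  x <- rbind(sample$upper, sample$lower)
  n_u <- nrow(sample$upper)
  n2 <- nrow(x)
  total <- cu$minor_counts + cl$minor_counts
  b <- n_permutations
  # balanced relabelings: each column of `memb` marks one random upper group
  memb <- matrix(0, n2, b)
  sel <- vapply(seq_len(b), function(i) sample.int(n2, n_u), integer(n_u))
  memb[cbind(as.vector(sel), rep(seq_len(b), each = n_u))] <- 1
  counts_u <- crossprod(x, memb)           # k x B minor-allele counts
  counts_l <- total - counts_u
  perm_stats <- t_kl_columns(counts_u + pseudocount, counts_l + pseudocount)

  exceed <- sum(perm_stats >= observed)
  p_value <- if (add_one) (1 + exceed) / (1 + b) else exceed / b
  structure(list(statistic = observed, p_value = p_value,
                 n_permutations = b, perm_exceed_count = exceed,
                 perm_stats = perm_stats),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("T_KL association test\n")
  cat("  statistic:", format(x$statistic, digits = 6), "\n")
  cat("  p-value:", format(x$p_value, digits = 4),
      sprintf("(%d of %d permutations >= observed)\n",
              x$perm_exceed_count, x$n_permutations))
  invisible(x)
}

# Shared replicate engine: simulate `n_sims` cohorts under `scenario`, select
# extremes, and return the vector of permutation p-values. `sub_seeds` fixes
# one RNG sub-stream per replicate so runs are reproducible replicate-wise.
assoc_pvalues <- function(scenario, n_sims, n_permutations, pseudocount = 0.5,
                          sub_seeds = NULL) {
  n_tail <- scenario$two_n / 2L
  n_base <- ceiling(n_tail / scenario$fraction)
  vapply(seq_len(n_sims), function(i) {
    if (!is.null(sub_seeds)) set.seed(sub_seeds[i])
    panel <- build_variant_panel(scenario$k, scenario)
    cohort <- simulate_cohort(panel, n_base, scenario$sigma_eps)
    xs <- select_extremes(cohort, scenario$fraction, n_per_tail = n_tail)
    permutation_test(xs, n_permutations, pseudocount)$p_value
  }, numeric(1))
}

#' Monte-Carlo rejection rate of the T_KL test under a scenario
#'
#' Runs `n_sims` independent replicates of the full pipeline — draw a fresh
#' variant panel, simulate a base cohort of `ceiling(N / fraction)`
#' individuals, select the two extreme tails of N individuals, run the
#' permutation test — and reports the fraction of replicates with
#' `p <= alpha`. Under a null scenario (`s = 0`) this estimates the type-I
#' error rate; under an alternative it estimates power.
#'
#' @param scenario a [scenario_config()].
#' @param n_sims number of Monte-Carlo replicates.
#' @param n_permutations permutations per replicate.
#' @param alpha nominal significance level (default 0.05).
#' @param pseudocount count regularization (default 0.5).
#' @param seed optional integer seed; replicate sub-seeds are derived from it
#'   so results are reproducible and independent of evaluation order.
#' @return List with `rejection_rate`, `se` (binomial standard error),
#'   `n_sims`, `alpha` and the vector of replicate `p_values`.
#' @export
assoc_experiment <- function(scenario, n_sims, n_permutations, alpha = 0.05,
                             pseudocount = 0.5, seed = NULL) {
  if (n_sims < 1) stop("n_sims must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  pv <- assoc_pvalues(scenario, n_sims, n_permutations, pseudocount, sub_seeds)
  r <- mean(pv <= alpha)
  list(rejection_rate = r, se = sqrt(r * (1 - r) / n_sims), n_sims = n_sims,
       alpha = alpha, p_values = pv)
}
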