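#' Simulate haplotypes from the latent-Gaussian model
#'
#' Each haplotype is generated by drawing a latent vector Z from a
#' multivariate normal with mean 0, unit variances and AR(1) correlation
#' cor(Z_i, Z_j) = latent_rho^|i-j|, then setting the allele at variant i to
#' the minor allele iff Z_i exceeds the (1 - MAF_i) standard-normal quantile.
#' This preserves the per-variant marginal MAFs while inducing decaying
#' dependence between nearby variants.
#'
#' @param panel a [variant_panel()].
#' @param n_haplotypes number of haplotypes to draw.
#' @return Integer matrix (`n_haplotypes` x `k`) of 0/1 minor-allele
#'   indicators.
#' @export
simulate_haplotypes <- function(panel, n_haplotypes) {
  if (n_haplotypes < 1) stop("n_haplotypes must be at least 1", call. = FALSE)
  k <- panel$k
  rho <- panel$latent_rho
  z <- matrix(0, n_haplotypes, k)
  z[, 1] <- stats::rnorm(n_haplotypes)
  if (k > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (j in 2:k) {
      z[, j] <- rho * z[, j - 1] + innov_sd * stats::rnorm(n_haplotypes)
    }
  }
  thresholds <- stats::qnorm(1 - panel$maf)
  hap <- matrix(0L, n_haplotypes, k)
  hap[z > rep(thresholds, each = n_haplotypes)] <- 1L
  hap
}

#' Simulate a genotype/phenotype cohort
#'
#' Genotypes are the sum of two independent haplotypes from
#' [simulate_haplotypes()]; the quantitative trait is
#' `Y = sum_i beta_i * X_i + eps` with `eps ~ N(0, sigma_eps^2)` (baseline
#' mean fixed at zero).
#'
#' @param panel a [variant_panel()].
#' @param n_individuals cohort size; must be at least 1.
#' @param sigma_eps residual standard deviation (> 0).
#' @return An object of class `"cohort"`: list with `genotypes`
#'   (`n_individuals` x `k` matrix of minor-allele counts 0/1/2), `phenotype`
#'   (numeric vector) and `panel`.
#' @export
#' @examples
#' set.seed(1)
#' p <- variant_panel(maf = rep(0.05, 4))
#' ch <- simulate_cohort(p, 100, sigma_eps = 1)
#' dim(ch$genotypes)
simulate_cohort <- function(panel, n_individuals, sigma_eps = 1) {
  if (n_individuals < 1) stop("empty cohort: n_individuals must be >= 1",
                              call. = FALSE)
  if (sigma_eps <= 0) stop("sigma_eps must be positive", call. = FALSE)
  geno <- simulate_haplotypes(panel, n_individuals) +
    simulate_haplotypes(panel, n_individuals)
  y <- as.numeric(geno %*% panel$beta) +
    stats::rnorm(n_individuals, 0, sigma_eps)
  structure(list(genotypes = geno, phenotype = y, panel = panel),
            class = "cohort")
}

#' Construct an extreme sample from two genotype matrices
#'
#' Low-level constructor used by the samplers and by the file readers when an
#' extreme sample arrives as two pre-selected genotype matrices.
#'
#' @param upper,lower genotype matrices (individuals x variants) with entries
#'   in {0, 1, 2}; must have the same number of columns.
#' @param threshold_u,threshold_l the phenotype thresholds that defined the
#'   tails (`threshold_u >= threshold_l`); may be `NA` when unknown.
#' @return An object of class `"extreme_sample"`.
#' @export
extreme_sample <- function(upper, lower, threshold_u = NA_real_,
                           threshold_l = NA_real_) {
  upper <- as.matrix(upper)
  lower <- as.matrix(lower)
  if (ncol(upper) != ncol(lower)) {
    stop("upper and lower tails must cover the same variants", call. = FALSE)
  }
  if (nrow(upper) < 1 || nrow(lower) < 1) {
    stop("insufficient sample: both tails must be non-empty", call. = FALSE)
  }
  if (!all(upper %in% 0:2) || !all(lower %in% 0:2)) {
    stop("invalid genotype: entries must be 0, 1 or 2", call. = FALSE)
  }
  if (!is.na(threshold_u) && !is.na(threshold_l) && threshold_u < threshold_l) {
    stop("threshold_u must be >= threshold_l", call. = FALSE)
  }
  structure(list(upper = upper, lower = lower, threshold_u = threshold_u,
                 threshold_l = threshold_l),
            class = "extreme_sample")
}

#' @export
print.extreme_sample <- function(x, ...) {
  cat("Extreme-phenotype sample:", nrow(x$upper), "upper +", nrow(x$lower),
      "lower individuals,", ncol(x$upper), "variants\n")
  cat("  thresholds: U =", format(x$threshold_u, digits = 4),
      ", L =", format(x$threshold_l, digits = 4), "\n")
  invisible(x)
}

#' Select the phenotypic extremes of a cohort
#'
#' The tails are the `floor(fraction * n)` individuals with the largest
#' (upper) and smallest (lower) trait values; the reported thresholds U and L
#' are the boundary order statistics, i.e. the empirical (1 - fraction) and
#' fraction quantiles attained by the selected tails. Ties in the trait are
#' broken by stable ordering of individual index, so selection is
#' deterministic given the RNG state. If a tail holds more qualifiers than
#' `n_per_tail`, `n_per_tail` of them are drawn uniformly without replacement;
#' with fewer qualifiers the behaviour depends on `strict`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param fraction tail fraction in (0, 0.5].
#' @param n_per_tail individuals to keep per tail; default all qualifiers.
#' @param strict if `TRUE` (default), error when a tail holds fewer than
#'   `n_per_tail` qualifiers; if `FALSE`, take all qualifiers.
#' @return An [extreme_sample()]; phenotypes are discarded, only genotype rows
#'   are kept.
#' @export
select_extremes <- function(cohort, fraction, n_per_tail = NULL,
                            strict = TRUE) {
  if (fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  }
  y <- cohort$phenotype
  n <- length(y)
  n_q <- floor(fraction * n)
  if (n_q < 1) stop("insufficient sample: no individuals qualify",
                    call. = FALSE)
  if (is.null(n_per_tail)) n_per_tail <- n_q
  ord <- order(y)  # stable: ties broken by original index
  lower_qual <- ord[seq_len(n_q)]
  upper_qual <- ord[seq.int(n - n_q + 1L, n)]
  threshold_l <- y[ord[n_q]]
  threshold_u <- y[ord[n - n_q + 1L]]
  take <- function(qual) {
    if (length(qual) > n_per_tail) {
      qual[sample.int(length(qual), n_per_tail)]
    } else if (length(qual) < n_per_tail && strict) {
      stop("insufficient sample: fewer than n_per_tail qualifiers in a tail",
           call. = FALSE)
    } else {
      qual
    }
  }
  extreme_sample(upper = cohort$genotypes[take(upper_qual), , drop = FALSE],
                 lower = cohort$genotypes[take(lower_qual), , drop = FALSE],
                 threshold_u = max(threshold_u, threshold_l),
                 threshold_l = min(threshold_u, threshold_l))
}
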