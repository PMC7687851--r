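#' Per-tail minor-allele frequencies of an extreme sample
#'
#' Estimates `p_m = X_i / 2N` per variant in each tail. Boundary counts (0 or
#' 2N minor alleles) leave the two-allele KL distance undefined, so they are
#' regularized by `pseudocount` alleles: a zero count becomes `pseudocount`
#' and a full count becomes `2N - pseudocount`.
#'
#' @param sample an [extreme_sample()].
#' @param pseudocount allele regularization applied at the boundaries
#'   (default 0.5).
#' @return List with numeric vectors `p_upper` and `p_lower`, both strictly
#'   inside (0, 1).
#' @export
tail_frequencies <- function(sample, pseudocount = 0.5) {
  one_tail <- function(genotypes) {
    cs <- allele_count_summary(genotypes)
    cnt <- pmin(pmax(cs$minor_counts, pseudocount),
                cs$allele_total - pseudocount)
    cnt / cs$allele_total
  }
  list(p_upper = one_tail(sample$upper), p_lower = one_tail(sample$lower))
}

#' Symmetrized two-allele Kullback-Leibler distance
#'
#' The distance between the allele distributions {p_u, 1 - p_u} and
#' {p_l, 1 - p_l} of one variant in the two tails:
#' \deqn{H = \frac12\left(p_u\log\frac{p_u}{p_l}
#'   + (1-p_u)\log\frac{1-p_u}{1-p_l}
#'   + p_l\log\frac{p_l}{p_u} + (1-p_l)\log\frac{1-p_l}{1-p_u}\right).}
#' Natural logarithm; non-negative, symmetric, zero iff `p_u == p_l`.
#' Vectorized over its arguments.
#'
#' @param p_u,p_l minor-allele frequencies strictly inside (0, 1); callers
#'   must regularize boundary frequencies first (see [tail_frequencies()]).
#' @return Numeric vector of distances.
#' @export
#' @examples
#' kl_h(0.6, 0.4)  # 0.2 * log(1.5)
kl_h <- function(p_u, p_l) {
  if (any(p_u <= 0) || any(p_u >= 1) || any(p_l <= 0) || any(p_l >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  0.5 * (p_u * log(p_u / p_l) + (1 - p_u) * log((1 - p_u) / (1 - p_l)) +
           p_l * log(p_l / p_u) + (1 - p_l) * log((1 - p_l) / (1 - p_u)))
}

#' Per-variant l_KL linkage-disequilibrium profile
#'
#' The stage-2 fine-mapping measure: for each variant,
#' `l_KL = (p_m / p_M) * H(p_m^U, p_m^L)` where H is the symmetrized
#' two-allele KL distance between the tail frequencies and `p_m` is the
#' variant's minor-allele frequency. The `p_m / p_M` prefactor removes the
#' dependence of H on the variant's own frequency, leaving a quantity that
#' decays with recombination distance from the causal locus and depends only
#' on the causal-allele frequency — which is what makes the profile's peak a
#' QTL localizer. `p_m` refers to the population frequency, which an extreme
#' sample does not directly provide; by default it is estimated as the
#' unweighted mean of the two tail frequencies (the tails are equal-sized and
#' approximately symmetric in the supported designs), or an external
#' population frequency vector may be supplied.
#'
#' @param sample an [extreme_sample()].
#' @param window odd moving-average window for smoothing (default 5).
#' @param pop_freq optional numeric vector of external population
#'   minor-allele frequencies; default `NULL` uses the tail mean.
#' @param pseudocount boundary regularization for tail frequencies.
#' @return An object of class `"finemap_profile"`: list with `l_kl`,
#'   `smoothed`, `peak_indices` (all indices within relative tolerance 1e-12
#'   of the smoothed maximum), `window`, `p_upper`, `p_lower` and `p_pooled`.
#' @export
l_kl_profile <- function(sample, window = 5, pop_freq = NULL,
                         pseudocount = 0.5) {
  tf <- tail_frequencies(sample, pseudocount)
  p_m <- if (is.null(pop_freq)) (tf$p_upper + tf$p_lower) / 2 else pop_freq
  if (length(p_m) != length(tf$p_upper)) {
    stop("pop_freq must have one entry per variant", call. = FALSE)
  }
  l_kl <- (p_m / (1 - p_m)) * kl_h(tf$p_upper, tf$p_lower)
  smoothed <- moving_average(l_kl, window)
  structure(list(l_kl = l_kl, smoothed = smoothed,
                 peak_indices = which_peaks(smoothed), window = window,
                 p_upper = tf$p_upper, p_lower = tf$p_lower, p_pooled = p_m),
            class = "finemap_profile")
}

# indices within relative tolerance 1e-12 of the maximum
which_peaks <- function(x) {
  m <- max(x)
  which(x >= m - abs(m) * 1e-12)
}

#' @export
print.finemap_profile <- function(x, ...) {
  cat("l_KL fine-mapping profile over", length(x$l_kl), "variants\n")
  cat("  smoothed peak at index:", paste(x$peak_indices, collapse = ", "),
      sprintf("(window %d)\n", x$window))
  cat("  max l_KL:", format(max(x$l_kl), digits = 5), "\n")
  invisible(x)
}

#' Centred moving average with truncated edges
#'
#' Smooths a profile with a centred mean over `window` points. Positions
#' within `(window - 1) / 2` of either end average over the available points
#' only (the window is truncated, never padded), so the output has the same
#' length as the input.
#'
#' @param values numeric vector.
#' @param window odd window size, between 1 and `length(values)`.
#' @return Numeric vector of smoothed values, same length as `values`.
#' @export
#' @examples
#' moving_average(c(0, 0, 0, 0, 5, 0, 0, 0, 0), 5)
moving_average <- function(values, window = 5) {
  n <- length(values)
  if (window %% 2 == 0 || window < 1 || window > n) {
    stop("invalid configuration: window must be odd, >= 1 and <= length",
         call. = FALSE)
  }
  if (window == 1) return(values)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Does the smoothed profile peak at a target variant?
#'
#' Declares a localization hit when the set of indices attaining the smoothed
#' maximum (within relative tolerance 1e-12, so exact ties all count)
#' intersects the target set. With the default fine-mapping map the targets
#' are markers 10 and 11, which flank the unobserved causal locus.
#'
#' @param profile a [l_kl_profile()] result.
#' @param target_indices integer indices counted as successful localizations
#'   (default `c(10, 11)`).
#' @return `TRUE` if any maximizing index is a target.
#' @export
localize <- function(profile, target_indices = c(10, 11)) {
  length(intersect(profile$peak_indices, target_indices)) > 0
}

#' Monte-Carlo localization power of the l_KL profile
#'
#' Simulates `n_populations` Wright-Fisher populations (complete initial LD,
#' `n_generations` of random mating and drift), draws `n_samples_per_pop`
#' extreme samples from each (fresh environmental noise per sample), computes
#' the smoothed l_KL profile of each sample, and reports the fraction of
#' samples whose peak hits a target marker — the estimator B / (number of
#' samples).
#'
#' @param model a [qtl_model()].
#' @param fraction tail fraction for sample selection.
#' @param n_populations number of independent populations.
#' @param n_samples_per_pop extreme samples drawn per population.
#' @param n_per_tail individuals per tail (default 750, i.e. 2N = 1500).
#' @param pop_size diploid population size (default 15000).
#' @param n_generations generations of evolution (default 50).
#' @param theta_int per-marker-interval recombination fraction (default
#'   0.005).
#' @param n_markers markers in the region (default 21).
#' @param targets target marker indices (default `c(10, 11)`).
#' @param window smoothing window (default 5).
#' @param seed optional seed; per-population sub-seeds are derived from it.
#' @param populations optional list of pre-evolved
#'   [haplotype_population][init_population()] objects to reuse instead of
#'   simulating (then `n_populations` is taken from its length).
#' @return List with `power`, `se`, `hits`, `n_samples` and the logical
#'   per-sample `hit` vector.
#' @export
finemap_power <- function(model, fraction, n_populations = 20,
                          n_samples_per_pop = 10, n_per_tail = 750,
                          pop_size = 15000, n_generations = 50,
                          theta_int = 0.005, n_markers = 21,
                          targets = c(10, 11), window = 5, seed = NULL,
                          populations = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(populations)) {
    pop_seeds <- sample.int(.Machine$integer.max - 1L, n_populations)
    populations <- lapply(pop_seeds, function(s) {
      set.seed(s)
      pop <- init_population(
        p_a = model$p_a,
        marker_mafs = suppressMessages(
          default_marker_mafs(n_markers = n_markers, p_a = model$p_a)),
        pop_size = pop_size,
        rec_fractions = default_rec_fractions(theta_int,
                                              n_markers = n_markers))
      evolve(pop, n_generations)
    })
  } else {
    n_populations <- length(populations)
  }
  hit <- unlist(lapply(populations, function(pop) {
    vapply(seq_len(n_samples_per_pop), function(i) {
      xs <- draw_finemap_sample(pop, model, fraction, n_per_tail)
      localize(l_kl_profile(xs, window), targets)
    }, logical(1))
  }))
  p <- mean(hit)
  list(power = p, se = sqrt(p * (1 - p) / length(hit)), hits = sum(hit),
       n_samples = length(hit), hit = hit)
}
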