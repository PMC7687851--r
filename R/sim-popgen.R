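#' Dominance-coded QTL model
#'
#' Describes the causal locus of the fine-mapping stage. Genotypic values are
#' coded (AA, Aa, aa) = (-v, d, v) with `d = d_over_v * v`, so
#' `d_over_v = -1, 0, 1` give recessive, additive and dominant action of the
#' minor allele `a`. The residual variance is calibrated so that the locus
#' explains a target heritability h2 of the trait under Hardy-Weinberg
#' proportions.
#'
#' @param p_a QTL minor-allele frequency in (0, 0.5); default 0.01.
#' @param d_over_v dominance ratio d/v; -1, 0 or 1 in the standard designs,
#'   any real value is accepted.
#' @param v genotypic value of the `aa` genotype (default 1).
#' @param h2 heritability attributable to the QTL, in (0, 1).
#' @return An object of class `"qtl_model"` with fields `p_a`, `d_over_v`,
#'   `v`, `d`, `h2`, `var_g` (genotypic variance) and `sigma_eps` (residual
#'   SD).
#' @export
#' @examples
#' m <- qtl_model(p_a = 0.01, d_over_v = 0, h2 = 0.01)
#' m$var_g       # 0.0198
#' m$sigma_eps^2 # 1.9602
qtl_model <- function(p_a = 0.01, d_over_v = 0, v = 1, h2) {
  if (p_a <= 0 || p_a >= 0.5) stop("p_a must lie in (0, 0.5)", call. = FALSE)
  m <- list(p_a = p_a, d_over_v = d_over_v, v = v, d = d_over_v * v, h2 = h2)
  var_e <- env_variance_for_h2(m)  # validates h2
  m$var_g <- qtl_genetic_variance(m)
  m$sigma_eps <- sqrt(var_e)
  structure(m, class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  lbl <- if (x$d_over_v == -1) "recessive" else if (x$d_over_v == 0)
    "additive" else if (x$d_over_v == 1) "dominant" else
      paste0("d/v = ", x$d_over_v)
  cat("QTL model (", lbl, "): p_a = ", x$p_a, ", h2 = ", x$h2, "\n", sep = "")
  cat("  genotypic values (AA, Aa, aa): ", -x$v, ", ", x$d, ", ", x$v, "\n",
      sep = "")
  cat("  V_G = ", format(x$var_g, digits = 5), ", sigma_eps = ",
      format(x$sigma_eps, digits = 5), "\n", sep = "")
  invisible(x)
}

# Genotypic variance of the QTL under HWE with values (-v, d, v).
qtl_genetic_variance <- function(model) {
  p <- model$p_a
  q <- 1 - p
  mu <- -model$v * q^2 + 2 * p * q * model$d + p^2 * model$v
  q^2 * model$v^2 + 2 * p * q * model$d^2 + p^2 * model$v^2 - mu^2
}

#' Residual variance calibrated to a target heritability
#'
#' Returns the environmental variance `sigma_eps^2 = V_G * (1 - h2) / h2`,
#' where `V_G` is the QTL genotypic variance under Hardy-Weinberg proportions
#' with genotype values (AA, Aa, aa) = (-v, d, v).
#'
#' @param model a [qtl_model()] or a list with fields `p_a`, `d`, `v`, `h2`.
#' @return The residual variance (scalar).
#' @export
env_variance_for_h2 <- function(model) {
  h2 <- model$h2
  if (is.null(h2) || h2 <= 0 || h2 >= 1) {
    stop("invalid configuration: h2 must lie in (0, 1)", call. = FALSE)
  }
  qtl_genetic_variance(model) * (1 - h2) / h2
}

#' Evenly spaced marker MAF grid for the fine-mapping region
#'
#' Marker MAFs span \[`maf_min`, `maf_max`\] on an evenly spaced grid,
#' assigned to marker positions in random order (when `shuffle = TRUE`).
#' Complete initial LD (P(m|a) = 1) is impossible for a marker rarer than the
#' QTL allele, so grid values below `p_a` are raised to `p_a`; a message
#' reports how many.
#'
#' @param n_markers number of markers (default 21).
#' @param maf_min,maf_max grid range (defaults 0.001 and 0.05).
#' @param p_a QTL minor-allele frequency used as the floor (default 0.01).
#' @param shuffle assign grid values to positions in random order.
#' @return Numeric vector of length `n_markers`.
#' @export
default_marker_mafs <- function(n_markers = 21, maf_min = 0.001,
                                maf_max = 0.05, p_a = 0.01, shuffle = TRUE) {
  grid <- seq(maf_min, maf_max, length.out = n_markers)
  n_raised <- sum(grid < p_a)
  if (n_raised > 0) {
    message(n_raised, " marker MAF(s) below p_a = ", p_a,
            " raised to p_a to keep complete initial LD feasible")
    grid[grid < p_a] <- p_a
  }
  if (shuffle) grid <- grid[sample.int(n_markers)]
  grid
}

#' Recombination fractions of the fine-mapping map
#'
#' Markers are equally spaced with a uniform per-interval recombination
#' fraction `theta_int`; the QTL sits midway in the interval between markers
#' `n_markers/2` (rounded down... marker 10 for the default 21) and the next,
#' taking `theta_int / 2` on each side. With 21 markers and the QTL between
#' markers 10 and 11 this gives 22 loci and 21 adjacent intervals.
#'
#' @param theta_int per-adjacent-marker recombination fraction (default
#'   0.005).
#' @param n_markers number of markers (default 21).
#' @param qtl_after marker index the QTL follows (default 10).
#' @return Numeric vector of length `n_markers` (one fraction per adjacent
#'   locus pair, QTL included as a locus).
#' @export
default_rec_fractions <- function(theta_int = 0.005, n_markers = 21,
                                  qtl_after = 10) {
  if (qtl_after < 1 || qtl_after >= n_markers) {
    stop("qtl_after must name an interior marker interval", call. = FALSE)
  }
  # n_markers - 1 marker intervals; the one after `qtl_after` is split in two
  c(rep(theta_int, qtl_after - 1), theta_int / 2, theta_int / 2,
    rep(theta_int, n_markers - 1 - qtl_after))
}

#' Initialize a haplotype population in complete QTL-marker LD
#'
#' Builds the generation-0 haplotype pool: each haplotype carries the QTL
#' minor allele `a` with probability `p_a`; every `a`-haplotype carries the
#' marker minor allele `m` at every marker (P(m|a) = 1, complete initial LD),
#' while `A`-haplotypes carry `m` at marker i independently with probability
#' `(maf_i - p_a) / (1 - p_a)`, so the marginal marker MAF equals `maf_i`
#' exactly in expectation.
#'
#' @param p_a QTL minor-allele frequency.
#' @param marker_mafs marker MAFs (length = number of markers, default from
#'   [default_marker_mafs()]); every value must be at least `p_a`.
#' @param pop_size number of diploid individuals (default 15000).
#' @param rec_fractions per-interval recombination fractions (length = number
#'   of markers; default from [default_rec_fractions()]).
#' @param qtl_after marker index the QTL follows on the map (default 10).
#' @return An object of class `"haplotype_population"`: list with
#'   `haplotypes` (2 * pop_size x loci 0/1 matrix, QTL column included),
#'   `pop_size`, `generation`, `qtl_index` (column of the QTL),
#'   `marker_cols`, `rec_fractions`, `marker_mafs` and `p_a`.
#' @export
init_population <- function(p_a = 0.01, marker_mafs = NULL, pop_size = 15000,
                            rec_fractions = NULL, qtl_after = 10) {
  if (p_a <= 0 || p_a >= 0.5) stop("p_a must lie in (0, 0.5)", call. = FALSE)
  if (is.null(marker_mafs)) marker_mafs <- default_marker_mafs(p_a = p_a)
  n_markers <- length(marker_mafs)
  if (any(marker_mafs < p_a)) {
    stop("invalid configuration: marker MAF below p_a is incompatible with ",
         "complete initial LD (P(m|a) = 1)", call. = FALSE)
  }
  if (is.null(rec_fractions)) {
    rec_fractions <- default_rec_fractions(n_markers = n_markers,
                                           qtl_after = qtl_after)
  }
  if (length(rec_fractions) != n_markers) {
    stop("rec_fractions must have length = number of markers (loci - 1)",
         call. = FALSE)
  }
  n_hap <- 2L * pop_size
  a <- stats::rbinom(n_hap, 1L, p_a)
  hap <- matrix(0L, n_hap, n_markers + 1L)
  qtl_index <- qtl_after + 1L
  marker_cols <- setdiff(seq_len(n_markers + 1L), qtl_index)
  hap[, qtl_index] <- a
  for (i in seq_len(n_markers)) {
    p_m_given_A <- (marker_mafs[i] - p_a) / (1 - p_a)
    hap[, marker_cols[i]] <- ifelse(a == 1L, 1L,
                                    stats::rbinom(n_hap, 1L, p_m_given_A))
  }
  structure(list(haplotypes = hap, pop_size = pop_size, generation = 0L,
                 qtl_index = qtl_index, marker_cols = marker_cols,
                 rec_fractions = rec_fractions, marker_mafs = marker_mafs,
                 p_a = p_a),
            class = "haplotype_population")
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat("Haplotype population: ", x$pop_size, " diploids, ",
      length(x$marker_cols), " markers + 1 QTL, generation ", x$generation,
      "\n", sep = "")
  cat("  QTL allele frequency: ",
      format(mean(x$haplotypes[, x$qtl_index]), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Evolve a population under random mating, recombination and drift
#'
#' Discrete Wright-Fisher generations at constant census size: each offspring
#' draws two parents uniformly with replacement; each transmitted gamete
#' starts on a random parental haplotype and switches haplotype between
#' adjacent loci i, i+1 with probability `rec_fractions[i]` (no
#' interference). No mutation and no selection act during evolution.
#'
#' @param pop a [init_population()] result.
#' @param n_generations number of generations to advance (>= 0).
#' @return The evolved `"haplotype_population"` with `generation` advanced.
#' @export
evolve <- function(pop, n_generations) {
  if (n_generations < 0) stop("n_generations must be >= 0", call. = FALSE)
  if (n_generations == 0) return(pop)
  hap <- pop$haplotypes
  n_loci <- ncol(hap)
  p <- pop$pop_size
  n_gam <- 2L * p
  rec <- pop$rec_fractions
  col_idx <- rep(seq_len(n_loci), each = n_gam)
  for (g in seq_len(n_generations)) {
    # gametes 2o-1, 2o of offspring o come from its two independent parents
    pid <- sample.int(p, n_gam, replace = TRUE)
    row_a <- 2L * pid - 1L
    row_b <- 2L * pid
    # cumulative switch state along the chromosome (0 = first haplotype)
    state <- matrix(0L, n_gam, n_loci)
    state[, 1] <- stats::rbinom(n_gam, 1L, 0.5)
    for (j in 2:n_loci) {
      sw <- stats::rbinom(n_gam, 1L, rec[j - 1L])
      state[, j] <- (state[, j - 1L] + sw) %% 2L
    }
    rowsel <- row_a * (1L - state) + row_b * state
    hap <- matrix(hap[cbind(as.vector(rowsel), col_idx)], n_gam, n_loci)
  }
  pop$haplotypes <- hap
  pop$generation <- pop$generation + n_generations
  pop
}

#' Draw an extreme-phenotype sample for fine mapping
#'
#' Haplotypes are paired into diploids (rows 2j-1, 2j form individual j); each
#' individual's trait is `Y = G_Q + eps` where `G_Q` is the dominance-coded
#' genotypic value at the QTL and `eps ~ N(0, sigma_eps^2)` is drawn fresh on
#' every call (so repeated samples from one population differ through the
#' environmental noise). The upper and lower `fraction` tails are selected as
#' in [select_extremes()] and `n_per_tail` individuals are drawn uniformly
#' among the qualifiers of each tail. The returned genotype matrices cover
#' the markers only — the unobserved QTL column is dropped, so with the
#' default map the profile has 21 entries and the causal locus sits midway
#' between markers 10 and 11.
#'
#' @param pop a [haplotype_population][init_population()].
#' @param model a [qtl_model()].
#' @param fraction tail fraction in (0, 0.5].
#' @param n_per_tail individuals per tail (default all qualifiers).
#' @param strict error when a tail has too few qualifiers (default `TRUE`).
#' @return An [extreme_sample()] over the markers.
#' @export
draw_finemap_sample <- function(pop, model, fraction, n_per_tail = NULL,
                                strict = TRUE) {
  if (fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  }
  p <- pop$pop_size
  n_q <- floor(fraction * p)
  if (is.null(n_per_tail)) n_per_tail <- n_q
  if (n_per_tail > n_q && strict) {
    stop("insufficient sample: fraction * pop_size < n_per_tail",
         call. = FALSE)
  }
  hap <- pop$haplotypes
  odd <- seq.int(1L, 2L * p, by = 2L)
  qtl_geno <- hap[odd, pop$qtl_index] + hap[odd + 1L, pop$qtl_index]
  g_values <- c(-model$v, model$d, model$v)
  y <- g_values[qtl_geno + 1L] + stats::rnorm(p, 0, model$sigma_eps)

  ord <- order(y)
  lower_qual <- ord[seq_len(n_q)]
  upper_qual <- ord[seq.int(p - n_q + 1L, p)]
  take <- function(qual) {
    if (length(qual) > n_per_tail) qual[sample.int(length(qual), n_per_tail)]
    else qual
  }
  geno_rows <- function(ind) {
    hap[2L * ind - 1L, pop$marker_cols, drop = FALSE] +
      hap[2L * ind, pop$marker_cols, drop = FALSE]
  }
  extreme_sample(upper = geno_rows(take(upper_qual)),
                 lower = geno_rows(take(lower_qual)),
                 threshold_u = y[ord[p - n_q + 1L]],
                 threshold_l = y[ord[n_q]])
}
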