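#' Construct a variant panel
#'
#' A variant panel describes the rare-variant region used by the
#' association-stage simulator: per-variant minor-allele frequencies (MAFs),
#' causal flags, per-allele effect sizes, and the base of the autoregressive
#' correlation of the latent Gaussian used to generate haplotypes
#' (cor(Z_i, Z_j) = latent_rho^|i-j|).
#'
#' Causal variants must have MAF in \[0.001, 0.01\] and non-causal variants
#' MAF in \[0.001, 0.05\]; non-causal variants must have zero effect size.
#'
#' @param maf numeric vector of per-variant MAFs, each in (0, 0.5).
#' @param is_causal logical vector; defaults to all `FALSE`.
#' @param beta numeric vector of per-minor-allele effect sizes; must be zero
#'   wherever `is_causal` is `FALSE`. Defaults to all zero.
#' @param latent_rho base of the AR(1) latent correlation, in \[0, 1).
#' @return An object of class `"variant_panel"`: a list with elements `k`,
#'   `maf`, `is_causal`, `beta` and `latent_rho`.
#' @seealso [build_variant_panel()] for the scenario-driven generator,
#'   [simulate_cohort()] for drawing genotypes and phenotypes.
#' @export
#' @examples
#' variant_panel(maf = c(0.005, 0.02), is_causal = c(TRUE, FALSE),
#'               beta = c(0.6, 0))
variant_panel <- function(maf, is_causal = rep(FALSE, length(maf)),
                          beta = rep(0, length(maf)), latent_rho = 0.4) {
  k <- length(maf)
  if (length(is_causal) != k || length(beta) != k) {
    stop("`maf`, `is_causal` and `beta` must have equal length", call. = FALSE)
  }
  if (!is.numeric(maf) || any(maf <= 0) || any(maf >= 0.5)) {
    stop("all MAFs must lie in (0, 0.5)", call. = FALSE)
  }
  is_causal <- as.logical(is_causal)
  if (any(is.na(is_causal))) stop("`is_causal` must be TRUE/FALSE", call. = FALSE)
  if (any(beta[!is_causal] != 0)) {
    stop("non-causal variants must have beta = 0", call. = FALSE)
  }
  if (any(maf[is_causal] < 0.001 - 1e-12) || any(maf[is_causal] > 0.01 + 1e-12)) {
    stop("causal MAFs must lie in [0.001, 0.01]", call. = FALSE)
  }
  if (any(maf[!is_causal] < 0.001 - 1e-12) || any(maf[!is_causal] > 0.05 + 1e-12)) {
    stop("non-causal MAFs must lie in [0.001, 0.05]", call. = FALSE)
  }
  if (latent_rho < 0 || latent_rho >= 1) {
    stop("`latent_rho` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(k = k, maf = as.numeric(maf), is_causal = is_causal,
                 beta = as.numeric(beta), latent_rho = latent_rho),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("Variant panel:", x$k, "variants,", sum(x$is_causal), "causal\n")
  cat("  MAF range:", format(range(x$maf), digits = 3), "\n")
  if (any(x$is_causal)) {
    cat("  effect sizes:", sum(x$beta > 0), "positive,",
        sum(x$beta < 0), "negative\n")
  }
  cat("  latent AR base:", x$latent_rho, "\n")
  invisible(x)
}

#' Define an association-study scenario
#'
#' Bundles the parameters of one simulated extreme-sampling design: the number
#' of causal variants `s`, the effect-size constant `c` (effect sizes are
#' `c * |log10(MAF)|`), the split of causal variants into positive and negative
#' effect directions, the total extreme-sample size `2N`, the tail fraction
#' used for selection, and the residual standard deviation of the trait.
#'
#' The nine power-study scenarios of the method's evaluation are available
#' through [table3_scenarios()].
#'
#' @param s number of causal variants (0 gives a null scenario).
#' @param c effect-size constant; must be positive when `s > 0`.
#' @param n_positive,n_negative number of causal variants assigned positive and
#'   negative effect direction; must sum to `s`.
#' @param two_n total extreme-sample size 2N (N per tail); must be even.
#' @param fraction tail fraction q in (0, 0.5]; each tail holds the most
#'   extreme `fraction` of the base cohort.
#' @param sigma_eps residual standard deviation of the trait (default 1).
#' @param k number of variants in the region (default 100).
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(s, c = 0, n_positive = s, n_negative = 0,
                            two_n = 1000, fraction = 0.2, sigma_eps = 1,
                            k = 100) {
  if (s < 0 || k < 1) stop("invalid configuration: s >= 0 and k >= 1 required",
                           call. = FALSE)
  if (n_positive + n_negative != s) {
    stop("invalid configuration: n_positive + n_negative must equal s",
         call. = FALSE)
  }
  if (s > k) stop("invalid configuration: s cannot exceed k", call. = FALSE)
  if (s > 0 && c <= 0) {
    stop("invalid configuration: effect-size constant c must be positive",
         call. = FALSE)
  }
  if (two_n %% 2 != 0) stop("invalid configuration: two_n must be even",
                            call. = FALSE)
  if (fraction <= 0 || fraction > 0.5) {
    stop("invalid configuration: fraction must lie in (0, 0.5]", call. = FALSE)
  }
  if (sigma_eps <= 0) stop("invalid configuration: sigma_eps must be positive",
                           call. = FALSE)
  structure(list(s = s, c = c, n_positive = n_positive,
                 n_negative = n_negative, two_n = two_n, fraction = fraction,
                 sigma_eps = sigma_eps, k = k),
            class = "scenario_config")
}

#' Generate a variant panel for a scenario
#'
#' Draws the random panel a scenario prescribes: `s` causal indices are chosen
#' uniformly without replacement among the `k` variants; causal MAFs are
#' Uniform(0.001, 0.01) and non-causal MAFs Uniform(0.001, 0.05); causal
#' variant `j` receives effect size `c * |log10(maf_j)|`, negated for the
#' `n_negative` causal variants chosen uniformly at random for the negative
#' direction.
#'
#' @param k number of variants; must be at least `scenario$s`.
#' @param scenario a [scenario_config()].
#' @param latent_rho AR(1) base of the latent haplotype correlation.
#' @return A [variant_panel()].
#' @export
#' @examples
#' set.seed(1)
#' sc <- scenario_config(s = 50, c = 0.2, n_positive = 25, n_negative = 25)
#' p <- build_variant_panel(100, sc)
#' sum(p$beta > 0)  # 25
build_variant_panel <- function(k = scenario$k, scenario,
                                latent_rho = 0.4) {
  s <- scenario$s
  if (k < s) stop("invalid configuration: k must be at least s", call. = FALSE)
  if (s > 0 && scenario$c <= 0) {
    stop("invalid configuration: c must be positive", call. = FALSE)
  }
  maf <- stats::runif(k, 0.001, 0.05)
  is_causal <- rep(FALSE, k)
  beta <- rep(0, k)
  if (s > 0) {
    causal_idx <- sample.int(k, s)
    is_causal[causal_idx] <- TRUE
    maf[causal_idx] <- stats::runif(s, 0.001, 0.01)
    sign_vec <- rep(1, s)
    if (scenario$n_negative > 0) {
      neg <- sample.int(s, scenario$n_negative)
      sign_vec[neg] <- -1
    }
    beta[causal_idx] <- sign_vec * scenario$c * abs(log10(maf[causal_idx]))
  }
  variant_panel(maf = maf, is_causal = is_causal, beta = beta,
                latent_rho = latent_rho)
}
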