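#' The nine power-study scenarios
#'
#' Returns the standard grid of association-stage scenarios: 10, 20 or 50
#' causal variants with effect-size constants 0.6, 0.3 and 0.2 respectively,
#' crossed with three positive:negative direction splits (all positive, 80:20,
#' 50:50).
#'
#' @param two_n total extreme-sample size 2N (default 1500).
#' @param fraction tail fraction (default 0.10).
#' @param sigma_eps residual SD (default 1).
#' @param k region size (default 100).
#' @return Named list of nine [scenario_config()] objects, `"1"` through
#'   `"9"`.
#' @export
table3_scenarios <- function(two_n = 1500, fraction = 0.10, sigma_eps = 1,
                             k = 100) {
  grid <- list(
    list(s = 10, c = 0.6, pos = 10, neg = 0),
    list(s = 20, c = 0.3, pos = 20, neg = 0),
    list(s = 50, c = 0.2, pos = 50, neg = 0),
    list(s = 10, c = 0.6, pos = 8,  neg = 2),
    list(s = 20, c = 0.3, pos = 16, neg = 4),
    list(s = 50, c = 0.2, pos = 40, neg = 10),
    list(s = 10, c = 0.6, pos = 5,  neg = 5),
    list(s = 20, c = 0.3, pos = 10, neg = 10),
    list(s = 50, c = 0.2, pos = 25, neg = 25))
  out <- lapply(grid, function(g) {
    scenario_config(s = g$s, c = g$c, n_positive = g$pos, n_negative = g$neg,
                    two_n = two_n, fraction = fraction, sigma_eps = sigma_eps,
                    k = k)
  })
  names(out) <- as.character(seq_along(out))
  out
}

# experiment_report constructor shared by the run_* drivers
experiment_report <- function(design, cells) {
  stopifnot(is.data.frame(cells),
            all(c("estimate", "se", "n_replicates") %in% names(cells)))
  if (any(cells$estimate < 0 | cells$estimate > 1)) {
    stop("estimates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(design = design, cells = cells,
                 created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report (", x$design$experiment, "), ",
      nrow(x$cells), " cells\n", sep = "")
  print(x$cells, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Type-I-error experiment for the T_KL test
#'
#' For every combination of sample size and tail fraction, simulates null
#' cohorts (no causal variants), selects the extremes, runs the permutation
#' test, and estimates the rejection rate at each nominal level from the same
#' replicate p-values.
#'
#' @param two_n extreme-sample sizes to cover (default `c(1000, 1500)`).
#' @param fractions tail fractions (default `c(0.20, 0.10, 0.05)`).
#' @param alphas nominal levels (default `c(0.05, 0.01)`).
#' @param n_sims Monte-Carlo replicates per (two_n, fraction) cell (default
#'   200; a warning is issued below 50).
#' @param n_perms permutations per replicate (default 500).
#' @param k,sigma_eps region size and residual SD of the null model.
#' @param seed optional integer seed.
#' @return An `"experiment_report"` whose `cells` data frame has columns
#'   `two_n`, `fraction`, `alpha`, `estimate`, `se`, `n_replicates`.
#' @export
run_table1 <- function(two_n = c(1000, 1500), fractions = c(0.20, 0.10, 0.05),
                       alphas = c(0.05, 0.01), n_sims = 200, n_perms = 500,
                       k = 100, sigma_eps = 1, seed = NULL) {
  if (n_sims < 50) warning("fewer than 50 replicates: estimates will be noisy")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (tn in two_n) {
    for (f in fractions) {
      sc <- scenario_config(s = 0, two_n = tn, fraction = f,
                            sigma_eps = sigma_eps, k = k)
      sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
      pv <- assoc_pvalues(sc, n_sims, n_perms, sub_seeds = sub_seeds)
      for (a in alphas) {
        r <- mean(pv <= a)
        rows[[length(rows) + 1L]] <- data.frame(
          two_n = tn, fraction = f, alpha = a, estimate = r,
          se = sqrt(r * (1 - r) / n_sims), n_replicates = n_sims)
      }
    }
  }
  experiment_report(
    design = list(experiment = "type-I error", two_n = two_n,
                  fractions = fractions, alphas = alphas, n_sims = n_sims,
                  n_perms = n_perms, k = k, sigma_eps = sigma_eps,
                  seed = seed),
    cells = do.call(rbind, rows))
}

#' Power experiment across association scenarios
#'
#' Estimates the power of the T_KL permutation test for each requested
#' scenario at each sample size and tail fraction. Each tail holds
#' `two_n / 2` individuals drawn from a base cohort of
#' `ceiling(N / fraction)` individuals, so the base-population size differs
#' across tail fractions.
#'
#' @param scenarios integer ids into [table3_scenarios()] (default `1:9`) or
#'   a list of [scenario_config()] objects.
#' @param two_n extreme-sample sizes (default `c(1000, 1500)`).
#' @param fractions tail fractions (default `c(0.20, 0.10, 0.05)`).
#' @param n_sims replicates per cell.
#' @param n_perms permutations per replicate.
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed.
#' @return An `"experiment_report"` with cell columns `scenario`, `two_n`,
#'   `fraction`, `estimate`, `se`, `n_replicates`.
#' @export
run_power_scenarios <- function(scenarios = 1:9, two_n = c(1000, 1500),
                                fractions = c(0.20, 0.10, 0.05), n_sims = 200,
                                n_perms = 500, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(scenarios)) {
    if (!all(scenarios %in% 1:9)) {
      stop("scenario ids must lie in 1..9", call. = FALSE)
    }
    ids <- scenarios
  } else {
    ids <- seq_along(scenarios)
  }
  rows <- list()
  for (si in seq_along(ids)) {
    for (tn in two_n) {
      for (f in fractions) {
        sc <- if (is.numeric(scenarios)) {
          table3_scenarios(two_n = tn, fraction = f)[[ids[si]]]
        } else {
          s0 <- scenarios[[si]]
          scenario_config(s = s0$s, c = s0$c, n_positive = s0$n_positive,
                          n_negative = s0$n_negative, two_n = tn,
                          fraction = f, sigma_eps = s0$sigma_eps, k = s0$k)
        }
        sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
        pv <- assoc_pvalues(sc, n_sims, n_perms, sub_seeds = sub_seeds)
        r <- mean(pv <= alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = ids[si], two_n = tn, fraction = f, estimate = r,
          se = sqrt(r * (1 - r) / n_sims), n_replicates = n_sims)
      }
    }
  }
  experiment_report(
    design = list(experiment = "association power", scenarios = ids,
                  two_n = two_n, fractions = fractions, n_sims = n_sims,
                  n_perms = n_perms, alpha = alpha, seed = seed),
    cells = do.call(rbind, rows))
}

#' Fine-mapping localization-power experiment
#'
#' Estimates the l_KL localization power over a grid of dominance models,
#' heritabilities and tail fractions. The Wright-Fisher populations are
#' simulated once and shared across all cells — population genotypes do not
#' depend on the phenotype model, only the trait values drawn from them do —
#' which makes the model/heritability/stringency comparisons paired and
#' reduces their Monte-Carlo variance.
#'
#' @param d_over_v dominance ratios to cover (default `c(-1, 0, 1)`).
#' @param h2 heritabilities (default `c(0.01, 0.05, 0.10)`).
#' @param fractions tail fractions (default `c(0.20, 0.10, 0.05)`).
#' @param n_populations populations simulated (default 20).
#' @param n_samples_per_pop samples per population per cell (default 10).
#' @param two_n extreme-sample size (default 1500, i.e. 750 per tail).
#' @param p_a QTL minor-allele frequency (default 0.01).
#' @param pop_size,n_generations,theta_int,n_markers population settings; see
#'   [init_population()] and [default_rec_fractions()].
#' @param targets,window localization settings; see [localize()] and
#'   [moving_average()].
#' @param seed optional integer seed.
#' @return An `"experiment_report"` with cell columns `d_over_v`, `h2`,
#'   `fraction`, `estimate`, `se`, `n_replicates`.
#' @export
run_table2 <- function(d_over_v = c(-1, 0, 1), h2 = c(0.01, 0.05, 0.10),
                       fractions = c(0.20, 0.10, 0.05), n_populations = 20,
                       n_samples_per_pop = 10, two_n = 1500, p_a = 0.01,
                       pop_size = 15000, n_generations = 50,
                       theta_int = 0.005, n_markers = 21,
                       targets = c(10, 11), window = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (two_n %% 2 != 0) stop("two_n must be even", call. = FALSE)
  n_per_tail <- two_n / 2
  pop_seeds <- sample.int(.Machine$integer.max - 1L, n_populations)
  cell_seed_base <- sample.int(.Machine$integer.max - 1L, 1)
  populations <- lapply(pop_seeds, function(s) {
    set.seed(s)
    pop <- init_population(
      p_a = p_a,
      marker_mafs = suppressMessages(
        default_marker_mafs(n_markers = n_markers, p_a = p_a)),
      pop_size = pop_size,
      rec_fractions = default_rec_fractions(theta_int, n_markers = n_markers))
    evolve(pop, n_generations)
  })
  rows <- list()
  cell <- 0L
  for (dv in d_over_v) {
    for (h in h2) {
      model <- qtl_model(p_a = p_a, d_over_v = dv, h2 = h)
      for (f in fractions) {
        cell <- cell + 1L
        set.seed((cell_seed_base + cell) %% (.Machine$integer.max - 1L) + 1L)
        res <- finemap_power(model, f, n_samples_per_pop = n_samples_per_pop,
                             n_per_tail = n_per_tail, targets = targets,
                             window = window, populations = populations)
        rows[[length(rows) + 1L]] <- data.frame(
          d_over_v = dv, h2 = h, fraction = f, estimate = res$power,
          se = res$se, n_replicates = res$n_samples)
      }
    }
  }
  experiment_report(
    design = list(experiment = "fine-mapping power", d_over_v = d_over_v,
                  h2 = h2, fractions = fractions,
                  n_populations = n_populations,
                  n_samples_per_pop = n_samples_per_pop, two_n = two_n,
                  p_a = p_a, pop_size = pop_size,
                  n_generations = n_generations, theta_int = theta_int,
                  n_markers = n_markers, seed = seed),
    cells = do.call(rbind, rows))
}
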