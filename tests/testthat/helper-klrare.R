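# Small fixtures shared across test files; everything is built in code.

# a tiny deterministic panel of common-ish rare variants
tiny_panel <- function(k = 10, maf = 0.02, rho = 0.4) {
  variant_panel(maf = rep(maf, k), latent_rho = rho)
}

# an extreme sample whose tail minor-allele frequencies are set exactly:
# each tail has `n` individuals; column i of a tail carries `counts[i]`
# minor alleles laid out greedily over genotypes 2/1.
sample_with_counts <- function(counts_upper, counts_lower, n) {
  fill <- function(counts) {
    vapply(counts, function(cnt) {
      g <- integer(n)
      full <- cnt %/% 2
      g[seq_len(full)] <- 2L
      if (cnt %% 2 == 1) g[full + 1L] <- 1L
      g
    }, integer(n))
  }
  extreme_sample(upper = fill(counts_upper), lower = fill(counts_lower))
}

# haplotype pairs with one QTL and markers in complete initial LD
# (P(m|a) = 1), drawn directly rather than through the population simulator
direct_ld_genotypes <- function(n, p_a, marker_mafs) {
  draw_hap <- function() {
    a <- stats::rbinom(n, 1, p_a)
    m <- vapply(marker_mafs, function(q) {
      ifelse(a == 1, 1L, stats::rbinom(n, 1, (q - p_a) / (1 - p_a)))
    }, integer(n))
    list(a = a, m = m)
  }
  h1 <- draw_hap()
  h2 <- draw_hap()
  list(qtl = h1$a + h2$a, markers = h1$m + h2$m)
}
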