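---
title: "Two-stage rare-variant mapping from extreme phenotypes with Kullback-Leibler distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage rare-variant mapping from extreme phenotypes with Kullback-Leibler distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klrare)
```

## The problem

Rare variants (minor-allele frequency below 5%, often below 1%) are hard to
connect to quantitative traits: single-marker tests are underpowered at such
frequencies, and genotyping whole cohorts is expensive. Extreme-phenotype
sampling addresses both issues — only individuals in the upper tail
(trait value $Y > U$) and the lower tail ($Y < L$) of the trait distribution
are genotyped, where rare causal alleles are enriched or depleted.

klrare implements a two-stage strategy on such samples:

1. **Association** — a region of $k$ rare variants is tested as a unit by
   comparing, between the two tails, the distribution of minor alleles
   *across variants* with a symmetrized Kullback-Leibler (KL) distance,
   $T_{KL}$. Significance comes from a label-permutation test.
2. **Fine mapping** — once a region is established, each variant receives a
   per-variant LD measure $l_{KL}$ built from the same distance; the peak of
   the smoothed $l_{KL}$ profile localizes the quantitative trait locus
   (QTL).

## Stage 1: the $T_{KL}$ statistic

Let $X^U_{ij}$, $X^L_{ij}$ be minor-allele counts (0/1/2) for individual $j$
at variant $i$ in the upper and lower samples of sizes $N^U$, $N^L$. Within
each tail the counts are normalized across variants into a proportion vector
$\tilde p^U$, $\tilde p^L$ (each summing to 1 over the $k$ variants), and

$$T_{KL} = \tfrac12\Big(\sum_i \tilde p^U_i \log
\frac{\tilde p^U_i}{\tilde p^L_i} + \sum_i \tilde p^L_i \log
\frac{\tilde p^L_i}{\tilde p^U_i}\Big).$$

$T_{KL}$ is non-negative, symmetric in the two tails, and zero exactly when
the two proportion vectors coincide. Variants whose minor alleles push the
trait up concentrate in the upper tail, variants pushing it down concentrate
in the lower tail, and both kinds displace the two proportion vectors apart,
which is why the statistic is only mildly affected by mixed effect
directions — the property the scenario-3-versus-9 experiment quantifies.

Numerical choices:

* **Logarithm base.** Natural log. The permutation test is invariant to the
  base, and natural log is the KL convention.
* **Zero counts.** With MAFs down to 0.001 and roughly 1000–1500 alleles per
  tail, some variants carry no minor allele in a tail and the statistic
  would be undefined. A pseudocount of 0.5 is added to every per-variant
  count in each tail before normalizing — the smallest standard continuity
  correction — applied identically to observed and permuted statistics, so
  the permutation null is preserved by construction. It is configurable
  (`pseudocount` argument). Variants with zero minor alleles in both tails
  are retained rather than dropped, so $k$ never changes between
  permutations.
* **Permutations.** The pooled $N^U + N^L$ individuals are repartitioned
  uniformly at random into groups of the original sizes (a fixed-margin
  split, matching the observed design). The p-value is the proportion of
  permuted statistics $\ge$ the observed one — ties count against the
  observed statistic, the conservative direction. An add-one estimator
  $(1 + \text{count})/(1 + B)$ is available behind a flag.
* **Cross-check path.** `t_kl_from_frequencies()` computes the statistic
  from per-tail allele frequencies $p_{mi} = X_i / 2N$ instead of the
  normalized proportions; the two routes are algebraically identical (the
  tail totals cancel) and the test suite holds them to $10^{-10}$. In the
  frequency form, the second summand is weighted by the lower-tail
  frequencies, mirroring the first — the only form symmetric in the tails.

## Stage 2: the $l_{KL}$ profile

For a single variant with tail minor-allele frequencies $p^U_m$, $p^L_m$,
the two-allele symmetrized KL distance is

$$H = \tfrac12\Big(p^U_m\log\frac{p^U_m}{p^L_m}
 + p^U_M\log\frac{p^U_M}{p^L_M}
 + p^L_m\log\frac{p^L_m}{p^U_m}
 + p^L_M\log\frac{p^L_M}{p^U_M}\Big), \qquad p_M = 1 - p_m,$$

and the LD measure is $l_{KL} = (p_m / p_M)\, H$. Asymptotically
$l_{KL} \approx \tfrac12 (1-\theta)^{2n} p_a^2 b^2$, where $\theta$ is the
recombination fraction between the variant and the QTL, $n$ the age of the
QTL allele in generations, $p_a$ its frequency and $b$ the contrast in
selection gradients between the tails. Two things follow, and both are
tested: $l_{KL}$ decreases with $\theta$ (so its maximum localizes the
QTL), and — unlike the raw $H$ — it does not depend on the frequency of the
variant itself, only on that of the QTL. The invariance is a small-signal
approximation; the test suite probes it with a weak-effect trait where it
holds to within Monte-Carlo error and shows that the unscaled $H$ visibly
violates it.

Choices:

* **The $p_m/p_M$ prefactor** refers to the population frequency, which an
  extreme sample does not provide. Default: the unweighted mean of the two
  tail frequencies (tails are equal-sized and approximately symmetric in the
  supported designs); an external population frequency vector can be
  supplied instead (`pop_freq`).
* **Boundary frequencies.** A tail count of 0 (or $2N$) is moved in by 0.5
  alleles, the same correction as stage 1.
* **Smoothing.** A centred 5-point moving average guards against noisy
  profiles. Edges use truncated (shrinking) windows rather than padding —
  padding would fabricate data at the profile ends, where targets never lie.
* **Peak ties.** All indices within relative tolerance $10^{-12}$ of the
  smoothed maximum count as peaks; localization succeeds if any of them is a
  target index.

## The association-stage simulator

Haplotypes for $k = 100$ variants are generated from a latent Gaussian
vector $Z$ with unit variances and AR(1) correlation
$\mathrm{cov}(Z_i, Z_j) = 0.4^{|i-j|}$; the allele at variant $i$ is minor
iff $Z_i$ exceeds the $(1 - \text{MAF}_i)$ normal quantile, and a genotype
is the sum of two independent haplotypes. This preserves the marginal MAFs
exactly and induces decaying dependence along the region. Causal MAFs are
drawn from $U(0.001, 0.01)$, non-causal from $U(0.001, 0.05)$. The trait is
$Y = \sum_i \beta_i X_i + \varepsilon$, $\varepsilon \sim N(0, 1)$, with
$\beta_i = \pm c\,|\log_{10}(\text{MAF}_i)|$ — rarer variants get larger
effects. The nine standard scenarios cross $s \in \{10, 20, 50\}$ causal
variants (with $c = 0.6, 0.3, 0.2$ respectively) with three
positive:negative direction splits; `table3_scenarios()` returns them.

Open points resolved here:

* The effect-size formula is stated with $\log_{10}$ of a frequency below 1,
  which is negative for every rare variant; the direction splits would then
  be meaningless. Positive-direction variants get $+c\,|\log_{10} p|$ and
  negative-direction variants the negated value, and the $n_{neg}$
  negative variants are chosen uniformly at random within the causal set
  (the assignment order is not specified anywhere; random is the neutral
  choice).
* For a target of $N$ individuals per tail at tail fraction $q$, the base
  cohort has $\lceil N/q \rceil$ individuals, which makes $N$ and $q$
  jointly consistent (e.g. 7,500 for $N = 750$ at $q = 0.10$). The tails
  are the $\lfloor qn \rfloor$ most extreme individuals by trait value,
  with ties broken by stable index order for determinism; if a tail holds
  more qualifiers than $N$, the sample is drawn uniformly among them.

What this generator does **not** emulate: covariates, population structure,
missing genotypes, common-variant background, genotyping error. Passing
tests therefore demonstrate the statistical behaviour of the method under a
clean additive rare-variant architecture, not robustness to those
real-data complications. It is also worth stating plainly that with the
stated effect sizes ($\beta$ between 0.4 and 1.8 residual SDs per allele)
extreme-tail samples of 500–750 per tail carry a very strong aggregate
signal; the power experiments in this package routinely saturate near 1 at
the standard scenario grid, so the interesting regimes for method
comparison are the smaller sample sizes and looser thresholds.

## The fine-mapping simulator

A forward-time Wright-Fisher population: 15,000 diploids (census size,
taken as the stated effective size — the simplest model matching the
number), 21 markers plus one unobserved QTL midway between markers 10
and 11, evolving 50 non-overlapping generations under random mating,
recombination and drift, with no mutation or selection. Generation 0 has
complete association between the QTL minor allele $a$ and every marker's
minor allele $m$: $P(m \mid a) = 1$, achieved by giving $a$-haplotypes the
$m$ allele everywhere and $A$-haplotypes the $m$ allele at marker $i$ with
probability $(\text{MAF}_i - p_a)/(1 - p_a)$, so marginal marker MAFs are
exact.

Resolved design points, all configurable:

* **Marker count and targets.** The region is described as 21 variants with
  the causal locus between variants 10 and 11, and localization success is
  counted at variant 10 *or* 11. That counting only makes sense if the QTL
  itself is not an observed variant: the profile covers 21 markers, and the
  two targets flank the unobserved causal locus symmetrically.
* **Recombination map.** Not stated. Markers are equally spaced with a
  uniform per-interval fraction $\theta_{int} = 0.005$ by default, the QTL
  taking $\theta_{int}/2$ to each flanking marker. Over 50 generations the
  flanking-marker LD then decays by $(1 - 0.0025)^{50} \approx 0.88$ in
  $\delta$, enough to preserve a usable peak. Localization power is
  sensitive to this choice; it is exposed as `theta_int`.
* **Marker MAFs.** "Uniformly determined over [0.001, 0.05]" is read as an
  evenly spaced grid assigned to positions in random order. Complete
  initial LD is impossible for a marker rarer than the QTL, so grid values
  below $p_a = 0.01$ are raised to $p_a$ (reported via a message). Such
  markers are perfect QTL proxies at generation 0 wherever they sit.
* **Phenotypes.** $Y = G_Q + \varepsilon$ with genotypic values
  $(AA, Aa, aa) = (-v, d, v)$ and $d/v \in \{-1, 0, 1\}$ for recessive,
  additive, dominant action — the standard coding under which those ratios
  produce those models. $\varepsilon$ has variance
  $V_G (1 - h^2)/h^2$ with $V_G$ the Hardy-Weinberg genotypic variance, so
  the QTL explains heritability $h^2$ exactly. Repeated samples from one
  population redraw $\varepsilon$ only (genotypes are fixed once evolved):
  at the 5% threshold all qualifiers are taken, so fresh noise is the only
  source of between-sample variation consistent with fixed genotypes.

A caution on the recessive design: with $p_a = 0.01$ the population of
15,000 contains on average only $p_a^2 \times 15{,}000 = 1.5$ homozygous
carriers, and under a strictly recessive trait heterozygotes are
phenotypically invisible. The information available for localization is
then limited to a handful of chromosomes regardless of heritability, and
the localization power computed by `run_table2()` under that model stays
close to the no-signal baseline of roughly $2/21$. Published localization
powers for recessive loci at this allele frequency are substantially
higher, which is not reproducible under this phenotype coding; the additive
and dominant cells, by contrast, are reproduced closely.

## Experiment drivers, problem sizes and reproducibility

`run_table1()`, `run_power_scenarios()` and `run_table2()` orchestrate the
three standard experiments and return tidy cell tables with binomial
standard errors. Default replication is desk-scale — 200 simulations of 500
permutations for the association experiments, and 20 populations sampled 10
times each for fine mapping — with every count exposed as an argument for
full-scale runs (1000 × 1000 and 100 × 10). `run_table2()` simulates its
populations once and reuses them across all (model, $h^2$, threshold)
cells; genotypes do not depend on the phenotype model, so this is exact and
makes the cross-cell comparisons paired.

All drivers take a single `seed`; per-replicate sub-seeds are drawn up
front, so results are bit-for-bit reproducible and independent of
evaluation order. Replicates are executed serially — the sub-seed contract
means a parallel backend could be added without changing any result.

## Limitations

* Inference for $T_{KL}$ is permutation-only; no asymptotic null
  distribution is provided.
* One causal locus per region is assumed in stage 2. For multiple causal
  variants, the natural recipe is iterative peel-off — localize the peak,
  remove that variant, retest the remainder with $T_{KL}$, repeat while the
  test stays significant — which is documented here but not implemented.
* Burden, SKAT and SKAT-O comparisons, and the entropy-based and
  excess-frequency LD measures, are out of scope; the profile output
  leaves room to add columns for external measures.
* No common-variant effect model.
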