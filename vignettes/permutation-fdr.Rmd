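---
title: "Permutation-based tail-area FDR with confidence intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based tail-area FDR with confidence intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permfdr)
```

## The model

The tail-area (positive) FDR at a fixed rejection region is
$\mathrm{FDR} = E[F/S \mid S > 0]$, where $S$ is the number of tests called
significant and $F$ the number of those that are true nulls. `permfdr`
estimates it from the sufficient counts $(m, S, S^*_1, \dots, S^*_B)$: the
total number of tests, the observed positive count, and the positive count
in each of $B$ datasets in which sample labels were permuted.

Two assumptions carry the construction:

1. **Exchangeability of observations under the null.** Permuted data then
   contain no false null hypotheses, so the expected proportion of positive
   tests among true nulls is the same in observed and permuted results.
2. **Marginal-FDR approximation.** $E[F/S] \approx E[F]/E[S]$ for large
   $m$, and the number of false nulls called *not* significant,
   $m_1 - E[T]$, is approximated by zero. The second approximation makes
   the estimator conservative (it can only inflate the numerator), with
   bias vanishing as $\pi_0 \to 1$.

These yield the odds-ratio point estimate and the $\pi_0$ factorization

$$\widehat{\mathrm{FDR}}
  = \frac{\bar S^*}{S}\cdot\frac{1 - S/m}{1 - \bar S^*/m}
  = \hat\pi_0\,\frac{\bar S^*}{S},
  \qquad
  \hat\pi_0 = \frac{1 - S/m}{1 - \bar S^*/m}.$$

$\hat\pi_0$ is equivalent to the familiar fixed-$\lambda$ tail estimator
$\#\{p_i > \lambda\}/((1-\lambda)m)$ with $\lambda$ fixed at the
empirically adjusted significance threshold — but, unlike that estimator,
it does not require uniform p-values under the null, because both its
ingredients come from the same permutation distribution.
`st_pi0_fixed_lambda()` implements the baseline for the documented
equivalence; it is not used in the count-based pipeline.

## The variance and confidence interval

Treating positive-test counts as binomial and applying the delta method on
the log scale gives

$$\sigma^2_{\mathrm{FDR}}
  = \frac{1}{\sum_i S^*_i} + \frac{1}{mB - \sum_i S^*_i}
  + \frac{1}{S} + \frac{1}{m - S},$$

the analogue of the Woolf variance of a log odds ratio. An algebraically
identical "ratio" form exists; both are implemented
(`var_log_fdr(, form =)`) and property-tested for identity. In the common
regime $S \ll m$ the variance collapses to $1/\sum_i S^*_i + 1/S$
(`var_log_fdr_limit()`): precision is governed by the *positive-test
counts*, not by $m$, and extra permutations help only while
$1/\sum_i S^*_i$ is non-negligible next to $1/S$. That is the quantitative
answer to "how many permutations do I need?", and it is why the validation
scenarios below change very little between $B = 10$ and $B = 100$.

The interval is the exponential back-transform
$\exp\{\log\widehat{\mathrm{FDR}} \pm z_{\alpha/2}\,\sigma\}$. The normal
quantile is computed by `qnorm()` (so $z_{0.025} = 1.959964\ldots$, not a
rounded 1.96) for exact reproducibility.

### Over-dispersion

The binomial variance assumes independent tests. Dependence between
features induces positive correlation between tests and inflates the
variance of positive-test counts; the replicate permuted counts measure
that inflation directly:

$$\hat\phi = \frac{\sum_i (S^*_i - \bar S^*)^2/(B-1)}{m\hat p(1 - \hat p)},
  \qquad \hat p = \bar S^*/m,$$

used as a scalar multiplier on $\sigma^2_{\mathrm{FDR}}$. No return to the
raw data is needed. Departures from the *identically distributed* half of
the binomial assumption can only bias the variance upward (a conservative
direction), so the adjustment targets the dependence half.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `ci_level` | 0.95 | two-sided confidence level; determines $z_{\alpha/2}$ |
| `phi_floor` | `TRUE` | report $\max(\hat\phi, 1)$ so the dependence adjustment never *tightens* the interval; raw $\hat\phi$ always reported alongside |
| `zero_substitute` | `TRUE` | if $\sum_i S^*_i = 0$ the variance is undefined; substitute 1 for CI estimation only |
| `clip_fdr` | `FALSE` | estimates above 1 (possible when $\bar S^* > S$) are reported as-is with a warning; clipping is presentational |
| `lambda` | 0.5 | only for the fixed-$\lambda$ baseline $\hat\pi_0$ |
| `B` | user-set | guidance: stop increasing once $\sum_i S^*_i \gg S$ |

Design points that were genuinely open, and the choices made:

- **Flooring $\hat\phi$ at 1.** Whether a sub-unit dispersion estimate
  should shrink the variance is not settled; the default floors at 1
  (conservative) and the raw value is kept in the result, so both
  behaviors are available (`fdr_config(phi_floor = FALSE)`).
- **Zero-substitution display.** When $\sum_i S^*_i = 0$ the reported
  point estimate stays at the raw 0 while the CI is centred on the
  substituted estimate (`fdr_for_ci`); both values and a flag are in the
  result, so neither interpretation is hidden.
- **Boundary convention.** "Positive at threshold $t$" means the strict
  $p < t$, matching the usual reading of "significant at $p < 10^{-4}$";
  `count_positives(strict = FALSE)` switches to $\le$. Statistics with a
  larger-is-more-significant orientation are supported via
  `orientation = "statistic"`.
- **$B = 1$.** Over-dispersion cannot be estimated from one replicate;
  $\hat\phi$ falls back to 1 with a warning rather than erroring.
- **Permutation sampling.** Permutations are drawn uniformly *with
  replacement* from the permutation group (standard practice; a
  coincidental identity permutation is legal). Each replicate uses its own
  sub-seed derived from the master seed, so results are invariant to
  execution order and to how many replicates are drawn.
- **Which side is permuted.** By default the *outcome* table's sample
  labels are permuted, leaving each table's internal correlation intact —
  this is what makes the replicate counts informative about
  dependence-induced over-dispersion. Permuting the predictor side is
  available (`permutation_plan(unit = "predictors")`).
- **Threshold ties.** `select_threshold()` breaks ties toward the larger
  threshold: more discoveries at the same estimated FDR.

## Degenerate inputs

- $S = 0$: the tail-area FDR conditions on $S > 0$; `estimate_fdr()`
  errors with advice to loosen the threshold, and `build_fdr_table()`
  retains the row with an `NA` estimate so the grid is complete.
- $S = m$: a degenerate threshold; the estimate is 0 with a warning.
- $\bar S^* = m$: undefined denominator, an error naming the count.
- $\hat\pi_0 > 1$ or $\widehat{\mathrm{FDR}} > 1$: returned unclipped with
  a warning (clipping available via `clip_fdr`).

All count arithmetic is carried in doubles representing exact integers;
ratios are formed only at the end, with no intermediate rounding.

## What the simulators emulate

### Correlated case-control expression (`simulate_case_control()`)

Subjects $\times$ genes matrices of standard normal "z-scores" organized
in `n_blocks` equicorrelated blocks. The within-block correlation $\rho$
is solved in closed form so that the *population* root-mean-squared
correlation over all $\binom{m}{2}$ gene pairs equals the single
dependence parameter `alpha_rms`:
$\rho = \alpha\sqrt{\binom{m}{2} / (n_{blocks}\binom{b}{2})}$ for block
size $b$. An infeasible $\alpha$ (implied $\rho \ge 1$) errors with the
maximal feasible value. False nulls add a constant `shift` to case rows
and are spread evenly across blocks (deterministically given the seed), so
that dependence among false nulls mirrors the block structure; random
placement is a config away. Defaults are the weak-effect study design:
2000 genes, 40 blocks, 100+100 subjects, $\alpha = 0.05$, shift 0.15,
$\pi_0 = 0.75$.

This generator reproduces block-equicorrelated Gaussian dependence with a
specified RMS correlation — the one dependence summary the design is
parameterized by. It does *not* emulate heavy-tailed expression noise,
heteroscedastic genes, negative correlation, or realistic block-size
heterogeneity, so passing tests demonstrate calibration under Gaussian
block dependence, not under every real expression dataset.

### LD-block SNPs and trait modules (`simulate_snp_traits()`)

Haplotypes come from a latent-Gaussian (copula) threshold model: within an
LD block the latent normals are equicorrelated, and the latent correlation
is calibrated by root-finding on the bivariate normal orthant probability
so that the genotype-dosage correlation (the composite-LD surrogate under
Hardy–Weinberg sampling) at the block's mean allele frequency matches a
target drawn uniformly from `ld_range`. Genotypes are sums of two
independent haplotypes; allele frequencies are uniform on `maf_range`
(default (0.2, 0.5)). Traits are module-equicorrelated Gaussians with
within-module correlation uniform on `corr_range`. Each false-null
SNP–trait pair adds `effect_size` per allele to its trait; every pair is
tested by a simple-linear-regression F-test.

Defaults: 20 LD blocks $\times$ 5 SNPs, 10 modules $\times$ 5 traits,
giving $100 \times 50 = 5000$ tests; 200 subjects; `m1 = 15`;
`effect_size = 0.35`, chosen once analytically so that per-pair power is
roughly 0.5 at a $10^{-3}$ threshold with 200 subjects
(non-centrality $\beta\,\mathrm{sd}(g)\sqrt{n} \approx z_{5\times10^{-4}}$
with $\mathrm{sd}(g) \approx 0.66$ for these allele frequencies). Because
calibration uses the block-mean allele frequency, pairs with unequal MAFs
realize somewhat lower dosage correlation than their block target — MAF
heterogeneity attenuates thresholded-Gaussian correlation — so realized LD
tracks the configured range approximately rather than exactly. Recombination
processes, ascertainment, and non-Gaussian traits are out of scope.

## The evaluation harness

`run_scenario()` repeats simulate → test → permute → count → estimate over
replicate datasets and aggregates per threshold: the realized true FDR
(mean $F/S$ over replicates with $S > 0$), the mean and variance of the
estimate, its bias, mean $\hat\pi_0$ and raw $\hat\phi$, and the coverage
and width of both the adjusted and unadjusted intervals against the
scenario's realized true FDR. Replicates with $S = 0$ are excluded from
the true-FDR and coverage denominators — the quantity conditions on
$S > 0$ — and their frequency is reported (`prop_s_zero`). Simulation
seeds are derived from the master seed *independently of* $B$, so a rerun
with more permutations reuses identical datasets and isolates the
permutation noise.

The packaged validation studies use 200 replicate datasets per scenario —
enough for a binomial standard error of about 1.5 percentage points on a
95%-coverage estimate — with 2000-gene (weak-effect, $B$ up to 100) and
4000-gene (dependent coverage, $B = 10$) designs; the unit tests exercise
the same code paths at a few hundred genes and a handful of replicates.

## Known limitations

- The point estimator is conservatively biased by construction (the
  $m_1 - E[T] = 0$ approximation); the bias grows with the fraction of
  weak false nulls below the detection threshold.
- The CI is a normal approximation on the log scale; with very small
  counts ($S$ or $\sum_i S^*_i$ of a few units) it inherits the usual
  small-count inaccuracy of Woolf-type intervals, and under strong
  dependence coverage relies on the scalar $\hat\phi$ capturing the whole
  dependence effect.
- A single $\hat\phi$ multiplies the entire variance; dependence
  structures whose inflation differs sharply between the observed and
  permuted count terms are summarized by one number.
- When a post-hoc threshold rule is used (minimum estimated FDR or minimum
  upper confidence limit), the upper bound should be well below one before
  declaring the FDR significantly less than one; the selection step is not
  corrected for in the interval itself.
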