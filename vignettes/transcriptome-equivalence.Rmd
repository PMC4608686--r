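---
title: "Testing transcriptome equivalence between two products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing transcriptome equivalence between two products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txeq)
```

## The problem

When a follow-on (generic or biosimilar) product is claimed to act like a
reference product, one line of evidence is that the two induce statistically
indistinguishable genome-wide expression responses in a sensitive biological
test system. txeq implements that comparison for single-channel microarray
data: several treatment groups (a media-only control, a reference product, a
test product, and optionally a deliberately nonequivalent control that
calibrates the assay's sensitivity) are hybridized one sample per array, and
the question is whether the test product's response differs from the
reference product's.

Demonstrating equivalence is harder than demonstrating difference: a
negative univariate scan alone could just reflect low power. The package
therefore combines three complementary instruments, and reports a product
pair as "not distinguishable" only when all three agree:

1. **Per-probe t-tests with false-positive control.** Pooled-variance
   Student t-tests per probe, with three regimes computed independently:
   uncorrected ($P < \alpha$), Storey q-value FDR ($q < \alpha$), and
   Bonferroni familywise control ($P < \alpha/n$).
2. **A permutation test on the number of nominal positives.** The count of
   probes with $P < 0.05$ is compared with its null distribution under
   random reassignment of whole samples to groups. Because entire samples
   are permuted, gene–gene coexpression is preserved under the null — this
   is the guard against the independence assumption the per-probe
   corrections make.
3. **A multivariate dissimilarity statistic (mvt).** With Pearson
   dissimilarity $d_{ij} = 1 - r_{ij}$ between sample expression profiles,

   $$\mathrm{mvt} = \frac{d(G,H)}{s(G) + s(H)},$$

   where $d(G,H)$ is the mean dissimilarity over all between-group sample
   pairs and $s(G)$ the mean over within-group pairs — a ratio of
   between-group difference to within-group spread, in analogy to the
   univariate t statistic. Significance is assessed by a permutation null:
   $\Pr(\mathrm{MVT} > \mathrm{mvt})$ over random reassignments of the
   pooled samples into groups of the original sizes, estimated with
   add-one smoothing $(1 + \#\{\mathrm{MVT} > \mathrm{mvt}\})/(n_{perm}+1)$
   so a p-value is never exactly zero. For small groups the test
   enumerates all $\binom{|G|+|H|}{|G|}$ reassignments exactly.

Sample-level views — classical MDS on the Pearson dissimilarity,
standardized PCA, and Ward (`"ward.D"`) hierarchical clustering — provide
the corresponding visual evidence.

## Preprocessing model

Raw data are median foreground and background intensities per spot. The
pipeline applies, in order:

1. **normexp background correction** per array, with an **offset of 8**.
   The net intensity $X = \mathrm{fg} - \mathrm{bg}$ is modeled as
   $X = B + S$ with $B \sim N(\mu_b, \sigma_b)$ and
   $S \sim \mathrm{Exp}(\alpha)$; parameters are fitted per array by
   maximum likelihood (method-of-moments initialization; the optimizer is
   boxed by the moment constraints $\sigma_b^2, \alpha^2 \le
   \mathrm{var}(X)$, which also keeps it off a numerically degenerate
   large-$\sigma$ ridge). Each net intensity is then replaced by
   $E[S \mid X = x] = \mu_{sf} + \sigma_b\,\phi(z)/\Phi(z)$ with
   $\mu_{sf} = x - \mu_b - \sigma_b^2/\alpha$, $z = \mu_{sf}/\sigma_b$,
   evaluated in log space and, for $z < -20$, by the asymptotic tail
   expansion — the result is strictly positive and monotone for any finite
   input, so adding the offset and taking log2 is always defined.
2. **log2** transform.
3. **Quantile normalization** across arrays (rank-mean rule; ties receive
   the mean of the reference values over their rank span, making the
   operation deterministic and idempotent).
4. **Replicate-probe averaging**: spots sharing a probe id are averaged
   into one unique-probe row.

Correcting on the raw scale and logging afterwards is the standard
single-channel convention; the conditional-expectation correction is not
defined on the log scale. The fitted normexp parameters of every array are
recorded in the expression matrix's provenance.

## The analysis pipeline

```{r, eval = FALSE}
cfg <- list(
  data = synthetic_config(seed = 1),   # or list(raw = ..., sheet = ...)
  markers = c("GENE000001", "GENE000010"),
  seed = 1, out_dir = "results")
report <- run_pipeline(cfg)
```

`run_pipeline()` executes: preprocessing; the univariate battery of the
reference product against every other group; selection of the
**responsive probe set** (probes with $q < 0.05$ and fold change
$\ge 1.3$, two-sided, in the reference-vs-media comparison), which serves
as a sensitized feature space; the pairwise **comparison grid** (counts of
significant probes within that set, with q-values recomputed within the
set so the FDR denominator is the set size, plus mvt permutation p-values
on the set-restricted dissimilarity); MDS/PCA/Ward views; an optional
marker-gene panel; and the three-pronged equivalence verdict for each
product against the reference.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `offset` | 8 | intensity added after background correction, stabilizes log2 variance at low intensities |
| `alpha` | 0.05 | significance level for all three univariate regimes and the verdict prongs |
| `q_thresh` | 0.05 | q-value cut for the responsive set and grid counts |
| `fc_thresh` | 1.3 | linear fold-change cut (two-sided, $|\log_2 \mathrm{fc}| \ge \log_2 1.3$) |
| `n_perm_count` | 2000 | permutations for the significant-count test |
| `n_perm_mvt` | $10^5$ | permutations for the mvt test |

All thresholds are configuration, never constants, so the pipeline can be
reused outside this study design.

## The synthetic-data generator

`generate_dataset()` produces raw intensity sets with known ground truth so
that every downstream stage is testable without any external download. Per
probe $p$ and sample $s$ in group $g$ the true log2 level is

$$L_{ps} = b_p + e_{pg} + \textstyle\sum_k \lambda_{pk} f_{ks} + \varepsilon_{ps},$$

with per-probe baselines $b_p \sim N(10, 0.8)$ (log2), planted effects
$e_{pg}$ of magnitude `effect_log2` and random sign on `n_responsive`
probes, latent coexpression factors ($k = 1..5$, loadings of sd 0.1) and
residual noise of sd 0.25. The `reference` and `test` groups share the
identical effect vector; the `nonequivalent` group copies only
`share_fraction` (default 0.9) of it and draws independent effects of the
same magnitude for the remainder — so it agrees with the reference on most
of the response but not all of it, the situation an equivalence assay must
detect. `media` has zero effects.

On the raw scale, signals $S = c\,2^L$ are rescaled so the all-probe mean
signal is `signal_mean` (2000), and each physical spot carries a
multiplicative print-batch effect $E \sim \mathrm{Exp}(1)$ drawn **once per
spot and shared across arrays**. This gives the within-array signal the
exponential marginal that the normexp model assumes — so background
correction is exercised in-model — while cancelling from all group
contrasts, leaving per-probe testing power governed by the log2 noise
parameters. Foreground is $B + S E$ with spot background
$B \sim N(50, 10)$ truncated at zero; the recorded background is an
independent draw from the same law.

Design choices worth making explicit:

* **Bright-array regime.** The intensity scale (signal mean 2000 over a
  background of 50 ± 10) keeps almost all probes well above background.
  This is deliberate: it makes per-probe power a function of the log2
  noise alone, so closed-form noncentral-t oracles apply. At dimmer
  settings a sizable fraction of probes becomes background-dominated and
  fold changes are attenuated by the conditional-mean correction — a real
  phenomenon the generator can reproduce (lower `signal_mean`), but not
  the regime the calibration tests are about.
* **Spot effects shared across arrays.** Drawing $E$ per spot per array
  instead would add ≈1.85 log2 units of per-measurement noise and swamp
  every planted effect; sharing it across arrays models print-batch
  variation (all arrays from one print lot) and cancels in contrasts.
* **Latent factors, not an explicit correlation matrix**, keep generation
  $O(\text{probes})$ and scale to the full 39,429-probe design.
* What the generator does **not** emulate: spatial artifacts, dye or batch
  structure (the emulated study processed all arrays in one batch),
  intensity-dependent variance beyond the background mechanism, and
  heavy-tailed biological outliers. Passing calibration tests on this
  generator therefore demonstrates correctness of the statistical
  machinery under its stated model, not robustness to such artifacts.

## Numerical choices

* **q-values**: Storey's estimator with the smoother — $\hat\pi_0(\lambda)$
  on the grid $\lambda = 0, 0.05, \ldots, 0.90$, cubic smoothing spline
  (df = 3), evaluated at the largest $\lambda$ and clamped to
  $[1/m, 1]$; the floor corresponds to "at least one true null", the least
  committal admissible estimate when nearly all hypotheses are false. With
  $\pi_0 = 1$ the q-values reduce exactly to Benjamini–Hochberg.
* **Zero-variance probes** are dropped (with a warning) before PCA
  standardization; zero-variance t-tests return $t=0, p=1$ for equal means
  and $p=0$ with a warning otherwise.
* **Permutation p-values** use strict inequality with add-one smoothing;
  exact enumeration (used automatically in tests for small designs)
  includes the identity reassignment, so exact p-values are never zero
  either.
* **Ties** in quantile normalization get rank-span means; Ward clustering
  uses `hclust`'s deterministic `"ward.D"` update on unsquared
  dissimilarities; MDS is classical/Torgerson (deterministic,
  oracle-verifiable) rather than stress-majorization, which can differ
  visually from iterative MDS but not statistically.
* **PCA** standardizes with the sample (n−1) standard deviation and fixes
  component signs by making each component's largest-magnitude loading
  positive.

## Calibration evidence and problem sizes

The test suite regenerates all of its evidence at run time; the sizes were
chosen so the whole suite runs on a laptop in a few minutes:

* mvt and count permutation tests agree **exactly** with exhaustive
  enumeration on 4-vs-4 and 3-vs-3 designs.
* The mvt permutation test's type-I error at $\alpha = 0.05$, over 1000
  null datasets (6-vs-6, 100 probes, 500 permutations each), lies within
  [0.035, 0.065].
* normexp correction matches direct quadrature of $E[S\mid X=x]$ to
  $10^{-6}$ over a 189-point parameter grid; the per-array MLE, averaged
  over 15 datasets of 10,000 spots drawn from $N(50,10) +
  \mathrm{Exp}(200)$, recovers all three parameters within 5% (single-fit
  scatter for $\sigma_b$ is larger — the exponential dominates that
  condition — which is a property of the likelihood, not the optimizer:
  limma's MLE lands on the same optimum to four digits).
* A planted responsive set (200 probes, effect 1 log2, noise 0.25, 8-vs-8)
  is recovered with ≥90% sensitivity at ≤10% empirical FDR, and the
  three-pronged verdict passes equivalent pairs and fails
  `share_fraction = 0.9` nonequivalent pairs in ≥90% of 50 replicates
  (2000 probes, coexpression on).

## Known limitations

* The pipeline assumes a minimal 3-column raw format (probe id, foreground
  median, background median); full scanner-export parsing (e.g. complete
  GenePix headers) is out of scope — only the two median columns are used.
* Exact reproduction of a historical analysis depends on the precise
  normexp variant (MLE vs saddle-point), the order of log2 and
  normalization, and the q-value smoother settings of the original; counts
  can differ by small margins between variants even when every method-level
  check passes.
* Per-probe q-values inherit the independence assumption; that is exactly
  why the count-permutation and mvt prongs, which preserve coexpression,
  are required before an equivalence verdict is issued.
* The verdict is a calibrated screening judgment, not a regulatory
  equivalence proof; its operating characteristics are those measured on
  the generator's model.
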