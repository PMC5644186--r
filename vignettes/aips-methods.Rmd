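---
title: "Distance-based ancestry inference with portable SNP weights"
author: "aips package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based ancestry inference with portable SNP weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aips)
```

## The problem

Population stratification — systematic allele-frequency differences between
subpopulations — confounds genetic association studies and can produce
false-positive hits when cases and controls differ in ancestry composition.
Model-based admixture estimators (Bayesian or likelihood clustering) handle
this well for strongly diverged populations, but become slow on cohorts of
tens of thousands of samples and struggle to separate *closely related*
subpopulations, such as those within Europe, where allele-frequency
differences are modest.

This package implements a distance-based alternative. It combines two
standard tools: principal component analysis of a panel of ancestry
informative markers (AIMs), and inverse-distance-weighted (IDW) spatial
interpolation. Every individual is placed in a low-dimensional PCA score
space; reference populations are summarized by their centroids; and each
individual's ancestry membership is distributed over nearby centroids with
weights that decay with distance.

## The model

### P-mode PCA and portable SNP weights

Let $G$ be the $n \times p$ dosage matrix over the AIMs panel. Missing calls
are replaced by the per-SNP mean of observed dosages, then each column is
standardized to zero mean and unit sample standard deviation (divisor
$n-1$). Because an imputed value equals the column mean, it standardizes to
exactly zero and contributes nothing to any score.

PCA is performed in *P-mode*: the eigendecomposition of the $p' \times p'$
SNP correlation matrix $R = X^\top X/(n-1)$, where $X$ is the standardized
matrix over the $p'$ SNPs retained after dropping zero-variance
(monomorphic) columns. The top-$K$ eigenvectors are per-SNP loadings — "SNP
weights" — and the scores of any sample genotyped on the same AIMs are

$$ x_{ik} = \sum_{m=1}^{p'} \tilde g_{im}\, v_{mk}, $$

where $\tilde g$ standardizes with the *training* means and standard
deviations. This is what makes the weights portable: a consortium can fit
them once and each member cohort computes comparable scores without access
to the training genotypes, and without the $O(n^2)$ cost of sample-mode PCA
on very large cohorts. P-mode is practical because informative AIMs panels
are small (the approach is intended for panels of at most roughly 25,000
markers, for which a dense correlation matrix is comfortable).

Numerical conventions, fixed once:

* scores are $X V$, *not* rescaled by singular values — any common affine
  rescaling of scores cancels in the power-kernel proportions below;
* each loading column's sign is chosen so its largest-magnitude entry is
  positive (eigenvector signs are otherwise arbitrary, and determinism
  matters for byte-identical reruns);
* eigenvalues are clamped at zero against negative round-off;
* $K$ defaults to 5, the customary choice for intra-continental panels;
  `scree_table()`/`screeplot()` support choosing differently;
* when $n \le p'$ a warning notes that projected scores for new samples are
  subject to shrinkage; no correction is applied.

### Centroids and the admixture set

The centroid of reference population $j$ is the per-component mean score
$\bar x_{jk}$ of its labelled members (unweighted — no robustification is
attempted). For an individual with score vector $x_i$, the plain distance to
centroid $j$ is $d_{ij} = \sqrt{\sum_k (x_{ik} - \bar x_{jk})^2}$.

Not every population should receive ancestry mass. The selection rule keeps
the nearest population $c_1$ unconditionally, then examines the next $s - 1$
nearest candidates $j$ in order of $d_{ij}$: candidate $j$ is kept iff the
individual is *strictly* closer to centroid $j$ than centroid $c_1$ is,
i.e. $\mathrm{dist}(c_1, j) > d_{ij}$. Geometrically, the individual must
lie between the two centroids rather than on the far side of $c_1$. The
strict inequality means an individual sitting exactly on a centroid is
called unadmixed. `s` defaults to 3 and is an upper bound — the selected set
may be a singleton.

One implementation subtlety: the centroid–centroid distances used by the
rule are computed with the same arithmetic (same function) as the
individual–centroid distances, so the equality case is excluded bitwise
deterministically rather than at the mercy of floating-point rounding.

### Three weighting kernels

Over the selected set, proportions are normalized kernel weights:

* **PD** (power-distance): $\Delta_j \propto d_{ij}^{-\alpha}$;
* **ED** (exponential-distance): $\Delta_j \propto e^{-\alpha d_{ij}}$;
* **EVD** (eigenvalue-weighted): the power kernel applied to
  $d^{EV}_{ij} = \sqrt{\sum_k (x_{ik}-\bar x_{jk})^2\, EV_k / \sum_k EV_k}$,
  so components explaining more variance dominate the metric.

For the EVD scheme the eigenvalue-weighted metric is used for *both*
selection and weighting; mixing metrics could select a population that then
receives near-zero weight. When all $K$ eigenvalues are equal, the EVD
metric is the plain metric scaled by $1/\sqrt K$, and EVD proportions
coincide with PD exactly.

$\alpha$ is not prescribed by the method; defaults are $\alpha = 2$ for the
power kernels (the classical inverse-square IDW) and $\alpha = 1$ for ED.
They are recorded in every output header. PD and EVD proportions are
invariant to a global rescaling of score space (the $c^{-\alpha}$ factor
cancels); ED proportions are not, which is one reason PD is the default
scheme.

Degenerate geometry: any distance below `zero_distance_epsilon` (default
$10^{-12}$ score units) is an exact hit; all mass is split equally among
sub-epsilon populations, which is the kernel limit. Kernels are evaluated
relative to the smallest distance to avoid overflow.

### Centroid separation: Hotelling's T²

Whether two reference clusters are genuinely distinct is tested with the
two-sample Hotelling T² on their members' scores, with pooled covariance.
The statistic is reported on the F scale,
$F = T^2 (n - K - 1)/(K(n-2))$, with a parametric p-value from
$F(K,\, n-K-1)$ and a permutation p-value from label shuffling using the
add-one estimator $(1 + \#\{F^\ast \ge F\})/(1 + B)$, which cannot return
zero. $B$ defaults to 10,000, giving a resolution of $10^{-4}$. The
permutation loop uses the exact total-scatter identity
$T^2 = c(n-2)u/(1-cu)$ with $u = d^\top T^{-1} d$ (a rank-one
Sherman–Morrison reduction), so each draw costs one small quadratic form;
the tests verify this equals the direct pooled-covariance formula.

### Accuracy metric

Against known labels, accuracy is summarized by a confusion table of mean
inferred proportions (rows: true population; columns: inferred; an
`Unknown` row collects unlabelled samples) and by the macro average

$$ \mathrm{Avg\%Correct} \;=\; \frac1p \sum_{j=1}^{p}
   \frac{1}{n_j} \sum_{i \in j} Q_{i,j}, $$

the mean over populations of the mean correct proportion. The outer division
by $p$ weighs populations equally, so a rare population counts as much as a
large one — deliberately different from a pooled per-sample mean, and the
tests pin an example where the two differ (0.7 vs 0.83).

## The synthetic-data generator

Real reference panels (HGDP, HapMap and similar) are access-controlled, so
the package ships a Balding–Nichols simulator as first-class, tested code.
Per SNP, an ancestral frequency $q$ is uniform on `maf_range` (default
0.05–0.5); population $j$ draws its frequency from
$\mathrm{Beta}(q(1-F)/F,\ (1-q)(1-F)/F)$, with variance $q(1-q)F$;
genotypes are $\mathrm{Binomial}(2, p_j)$, and an admixed individual with
mixing vector $m$ draws from $\mathrm{Binomial}(2, \sum_j m_j p_j)$.
Missing calls are placed uniformly at random.

Default conditions emulate a modestly diverged intra-continental setting at
desk scale: 5 subpopulations at $F_{ST} = 0.05$ (typical of within-continent
divergence), 2,000 AIMs, 50 labelled reference and 20 held-out samples per
population. Randomness is split into per-population substreams
(`seed + 7919 j`), so enlarging the design does not reshuffle existing
populations.

What the generator does *not* emulate: linkage disequilibrium between
markers (AIMs panels are chosen to avoid strong LD, so independence is the
intended regime), clines and isolation-by-distance geography, genotyping
batch effects, and realistic AIMs selection — the marker panel is taken as
given. Passing tests therefore demonstrate correctness of the algorithmic
machinery and recoverability under the stated divergence model, not
field accuracy on any particular human panel.

## Problem sizes used in the tests

The simulation-based checks use: the default 5-population panel above (plus
50 two-way 50/50 admixed individuals) for parameter recovery; 2,000
replicates for the Hotelling size calibration and 50 replicates of
10,000-permutation tests for permutation/parametric agreement; 10,000
random geometries for the selection-rule oracle; and one 4,000-sample ×
2,000-SNP end-to-end run as a cohort-scale smoke test. These sizes keep the
full suite comfortably reproducible on a single CPU while leaving the
Monte-Carlo margins wide relative to the asserted bounds.

## Design choices made where the design was open

* **Input formats.** PLINK 1 binary (SNP-major v1.00) and additive-coded
  delimited text; dosages count the A1 allele; sample keys are `FID_IID`.
  Sample-major `.bed` files are rejected rather than silently transposed.
* **Monomorphic filtering** happens in one place (standardization), never in
  the readers, so there is a single point of truth for which SNPs survive.
* **Divisor** $n-1$ for the standard deviation; the covariance/eigenvalue
  identity with the SVD cross-check in the tests then holds exactly.
* **Q-mode PCA is not implemented**: the portable-weights route is the point
  of the package, and the SVD oracle in the test suite already covers the
  algebraic equivalence on small panels.
* **Statistic scale.** Hotelling results are reported as F (with $T^2$
  alongside in the returned object), since the F scale is the one with a
  finite-sample reference distribution.
* **Selection-rule reading.** The rule compares each candidate against the
  distance from the *single* nearest population's centroid to that
  candidate's centroid. An alternative reading — comparing against the
  distance between the two nearest centroids to each other — exists; the
  per-candidate comparison is implemented because it extends naturally
  beyond the second candidate and treats each candidate symmetrically.
* **CLI.** A thin `Rscript` dispatcher (`aips_main()`, wrapped by
  `inst/cli/aips.R`) with `fit` / `project` / `infer` / `simulate` /
  `hotelling` subcommands. Flags only; every output starts with `#` header
  lines recording version, subcommand, parameters and seed, so any file can
  be regenerated from its own header.

## Worked example

```{r example}
panel <- simulate_structured_panel(n_pops = 3, fst = 0.05, n_snps = 500,
                                   n_ref = 30, n_test = 10, seed = 42)
fit <- aips(panel$genotypes, panel$labels, K = 3)
fit
round(head(fitted(fit), 3), 3)
avg_percent_correct(fitted(fit), panel$labels)
```

New cohorts genotyped on the same AIMs are placed with `predict()`:

```{r predict}
newcomers <- simulate_structured_panel(n_pops = 3, fst = 0.05, n_snps = 500,
                                       n_ref = 2, n_test = 0, seed = 43)
round(predict(fit, newcomers$genotypes), 3)
```

## Known limitations

* Proportions are interpolation weights, not likelihood-based admixture
  fractions; they have no associated uncertainty intervals.
* An individual from a population absent from the reference set is still
  assigned to the nearest available centroids — the method cannot say
  "none of the above".
* ED proportions depend on the absolute scale of score space; comparing ED
  results across weight sets fitted on different panels is not meaningful.
* Projection shrinkage when $n \le p'$ is warned about, not corrected.
* No local (per-locus) ancestry; the estimate is global per individual.
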