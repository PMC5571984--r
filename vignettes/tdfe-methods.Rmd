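---
title: "Tensor products of multi-view matrices: model, decomposition, and feature extraction"
author: "tdfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor products of multi-view matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfe)
```

## The problem

Multi-view data gives several feature-by-sample matrices that describe the
same biological system through different modalities: mRNA and miRNA
expression measured on the same specimens (views sharing their samples,
Case I), or the same genes measured under different treatments or time
courses (views sharing their features, Case II). Any method that merges
or linearly combines views must decide how much weight each view gets,
and there is no natural criterion for that choice — a view with ten times
more features should not automatically dominate the result.

`tdfe` avoids weights entirely by *multiplying* views instead of adding
them. For views $X^{(k)}$, $k = 1, \dots, m$, sharing the sample index
$j$:

* the **Type I tensor** keeps every combination of one feature per view,
  $$x_{i_1,\dots,i_m,j} = \prod_k x^{(k)}_{i_k j},$$
  an $(m{+}1)$-mode array with the shared mode last;
* the **Type II tensor** contracts the shared mode away,
  $$\tilde x_{i_1,\dots,i_m} = \sum_j \prod_k x^{(k)}_{i_k j},$$
  an $m$-mode array. For two views it is simply the matrix product
  $X^{(1)} (X^{(2)})^T$ and costs a factor $1/M$ less memory than Type I.

Case II swaps the roles of features and samples; the package handles both
through one code path by orienting the shared axis to the columns.

Each product entry combines exactly one feature from each view, so no
cross-view weight ever enters. That is the entire trick — the rest is
standard multilinear algebra and order statistics.

## Decomposition

The product tensor is decomposed by the higher-order SVD (`hosvd()`):
each mode's factor matrix holds the leading left singular vectors of that
mode's unfolding, and the core is the tensor contracted with every
transposed factor,
$$G = T \times_1 U_1^T \cdots \times_m U_m^T.$$
No iterative (HOOI) refinement is applied; the plain HOSVD is the
algorithm whose factors have the interpretation used throughout the
package: columns of $U_k$ are that mode's *singular value vectors*, and
core entries $G(\ell_1,\dots,\ell_m)$ with large absolute value say which
combination of per-mode components act together (`rankCore()`).

A Type II tensor has no shared-mode factor. `projectMissingMode()`
recovers per-view shared-mode vectors by pushing each view's factor
through its own data, $\tilde x^{(k)}_{\ell j} = \sum_i U_k[i, \ell]\,
x^{(k)}_{ij}$. This gives $m$ sets of sample vectors (Case I) whose
cross-view correlations expose latent correspondence between views —
the central output of the method.

Numerical conventions, all fixed and covered by oracle tests:

* **Unfolding**: mode-$k$ fibers as rows, remaining modes in cyclic order
  $k{+}1, \dots, m, 1, \dots, k{-}1$; verified by the full-rank
  reconstruction identity (max error $< 10^{-8}$ on random
  $5\times6\times7$ tensors) and the energy identity
  $\|G\|_F = \|T\|_F$.
* **Sign**: each factor column's largest-magnitude entry is made positive
  (ties: first index), so runs are reproducible; all downstream outputs
  are invariant under column sign flips, which is also tested.
* **Truncation**: default rank $\min(10, \text{mode size})$ per mode.
  Ten components comfortably cover the informative range — core ranking
  in practice concentrates within the first handful of components — while
  keeping the per-mode SVD cheap. Wide unfoldings (more than
  $\max(4n, 512)$ columns) go through the $n \times n$ gram matrix
  instead of a full SVD; the two paths agree to the tested tolerances on
  small cases.
* **Storage**: Type I tensors are dense, with a configurable element cap
  (default $2\times10^8$) because their memory and time grow as $MN^2$
  for two views; past the cap the package errors and recommends Type II.

## Feature extraction

Standardized views (per sample column: zero mean, sum of squares $N$;
`standardizeView()`) feed either tensor. Features are extracted as
distributional outliers on chosen factor columns: with
$\sigma_\ell$ the standard deviation of column $\ell$ over all features,
$$P_i = P_{\chi^2}\!\left[> \sum_{\ell} \left(
  \frac{u_{\ell i}}{\sigma_\ell}\right)^2\right],$$
with degrees of freedom equal to the number of columns used, followed by
Benjamini–Hochberg adjustment (`bhAdjust()`, a validated wrapper over
`stats::p.adjust`) and selection at adjusted $P < \alpha$
(default $\alpha = 0.01$; the first five components by default, both
configurable per view, including single-component selection with one
degree of freedom). $\sigma_\ell$ is computed about the column mean with
denominator $n-1$; factor columns are near zero-mean unit-norm vectors,
so this choice is numerically indistinguishable from the uncentered
convention — except in one degenerate situation discussed under
*Limitations*. Exact zeros in $P$ are coded as the smallest positive
double so that BH and sorting stay well defined.

The gram-matrix PCA baseline (`pcaDecompose()`,
`pcaUnsupervisedFE()`) embeds features rather than samples: scores are
eigenvectors of $G = XX^T$, loadings their sample-space images
$v_k = X^T u_k$. It is implemented through the SVD of $X$ for stability
(the gram eigendecomposition is the test oracle, not the
implementation). An optional screen keeps only components whose loadings
show sample-class dependence at $P < 0.05$ under categorical regression
before the same $\chi^2$/BH selection runs on the scores.

## Association tools

* `categoricalRegressionTest()`: class-means regression of a sample
  vector on labels, F test against the intercept-only model. Invariant
  to label renaming and affine transforms of the vector.
* `templateCorrelations()`: Pearson correlation of each feature profile
  with a template over the concatenated condition/time axis; raw $P$
  from $t = r\sqrt{(n-2)/(1-r^2)}$, BH adjusted. (An empirical-null FDR
  would also be defensible here; BH is used because it is assumption-light
  and consistent with the selection step.)
* `scaleShiftFit()`: per-feature linear map of the profile onto the
  template (one slope and intercept shared across conditions), so that
  profiles with different baselines and amplitudes can be overdrawn;
  constant profiles get slope 0, intercept `mean(template)`, and a flag.
* `groupwiseTimepointTest()`: at each time point, pooled-variance
  two-sided t test between two groups of fitted values, or the
  class-means F test for three or more. The fitted values of the
  selected features are pooled as replicates at each time point —
  exactly the quantity plotted when profiles are overdrawn.
* `upgmaPair()`: average-linkage clustering of labelled sample vectors
  under $d(u,v) = -|r(u,v)|$. Distances are deliberately left negative
  ($-|r| \in [-1, 0]$): average linkage only needs an ordering, and
  shifting would change nothing but the printed heights. Sign-flipped
  vectors are identical at distance $-1$; singleton–singleton merges are
  reported as the pairing.

## The synthetic benchmark

`generateTwoView()` reproduces a two-view Case I benchmark with a known
latent link. With defaults $c = 0.8$, $N = 1000$, $N_0 = M = 50$:

* signal rows ($i \le N_0$):
  $x^{(1)}_{ij} = \tfrac{c}{2}(j/M + \sin \pi j/M) + (1-c)\varepsilon$ and
  $x^{(2)}_{ij} = \tfrac{c}{2}((M-j)/M + \sin \pi j/M) +
  (1-c)\varepsilon$, with $\varepsilon \sim U[0,1]$ independently per
  entry;
* noise rows ($i > N_0$): $x_{ij} = \varepsilon$ at full amplitude
  (weight 1, not $1-c$ — the benchmark's definition, deliberately kept).

The two base curves share the sinusoid but have opposite linear trends;
their mixture coefficients make the *direct* correlation between
corresponding signal rows essentially zero (the deterministic parts
correlate at about $0.06$ and the $n = 50$ sampling noise swamps that),
so no row-by-row correlation screen can find the link. The package's
acceptance checks compute exactly this: the raw signal-row correlation
stays inside the near-zero $n=50$ sampling band across 100 seeds, while
the Type II pipeline's projected sample vectors align across views with
mean minimum–maximum absolute correlation within $0.05$ of $0.97$ over
10 seeds. All randomness flows through one seeded stream (view 1 before
view 2, rows drawn in row-major order), so a seed pins the dataset
bit-identically across platforms.

What the generator does *not* emulate: heavy-tailed expression
distributions, feature–feature correlation inside the noise block,
batch structure, missing values, and count noise. Passing the benchmark
therefore demonstrates the multilinear machinery, not robustness to
real-data pathologies.

Standardization is **off** by default for the benchmark (its rows are
already on a common $[0,1]$ scale; centering is part of the omics
pipeline defaults instead, where columns are standardized before any
tensor is formed).

## Limitations

* **Selection power on the benchmark.** On this benchmark the
  $\chi^2$/BH extraction step is not well powered at $\alpha = 0.01$:
  the full-amplitude noise rows give the tensor's feature factors a
  dominant all-positive (Perron) first component when the data are not
  centered — which makes every feature's uncentered score huge — while
  after column standardization the centered signal singular value
  ($\approx 12.5$) barely clears the noise bulk edge ($\approx 10.9$),
  leaving only $\approx 40\%$ of the top factor's mass on the signal
  rows and raw signal $P$-values near $10^{-2}$ that cannot survive BH.
  The test suite computes these selection counts on a reduced
  ($N = 300$) benchmark and documents the shortfall rather than hiding
  it; the benchmark's demonstrated strength is the latent *cross-view
  correspondence*, not the outlier step, which is powered on data whose
  factors concentrate (as the planted-outlier unit tests show).
* Dense tensors only; no sparse storage or missing-value handling.
* Plain HOSVD only; no CP/PARAFAC, no HOOI refinement, no generalized
  SVD across views.
* BH is the only multiplicity control; no empirical-null or q-value
  estimators.

## Problem sizes used by the test suite

The suite exercises the full benchmark ($N = 1000$) for the projection
checks (10 seeds), a reduced $N = 300$ benchmark for the Type I
selection counts (10 seeds), 100-seed null calibrations at
$N = 1000 \times 2$, and 2000-replicate null simulations for the
regression and correlation kernels — sizes chosen to keep each check's
Monte-Carlo error well below its assertion margin.
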