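---
title: "Eigenmode structure-function coupling: models, synthetic worlds, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenmode structure-function coupling: models, synthetic worlds, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigencoupling)
```

## The model

A structural connectome is a weighted undirected graph: an adjacency matrix
$A$ of interregional connection strengths. Its graph Laplacian $L = D - A$
(with $D$ the diagonal matrix of weighted degrees) is normalized by its
largest eigenvalue, $L' = L / \lambda_{\max}$, so spectra are comparable
across network sizes and densities. The eigenvectors $u_k$ of $L'$ — the
*eigenmodes* — are the network's spatial harmonics, ordered by eigenvalue
$\lambda_k \in [0, 1]$. Under linear network diffusion
$\dot{x} = -\beta L' x$, a mode decays as $e^{-\beta \lambda_k t}$:
near-zero eigenvalues correspond to global, persistent spreading patterns
("low frequency"); large eigenvalues to spatially complex, fast-decaying
ones ("high frequency"). The heat-kernel prediction
$\hat F = U e^{-\beta \Lambda t_c} U^\top$ (available as
`heat_kernel_fc()`) is the special case of the general expansion
$\hat F = \sum_k c_k u_k u_k^\top$ fitted by `whole_brain_fit()`.

Regionally, a region $i$'s functional connectivity profile (column $i$ of
the FC matrix, self-connection excluded) is regressed on a band of
eigenmodes plus the constant mode $u_1$ as intercept:

$$\hat F_i = b_1^i u_1 + U^{B} b^i, \qquad
  U^{L} = (u_2, \ldots, u_{K_L}), \quad U^{H} = (u_{K_H}, \ldots, u_N).$$

Coefficients are ordinary least squares; coupling is the Pearson
correlation $R$ between predicted and empirical profiles (`fit_region()`,
`coupling_map()`). Defaults follow the reference analysis on a 1000-region
connectome: $K_L = 14$ and $K_H = 434$, i.e. a high band covering the upper
$56.6\%$ of the spectrum; both thresholds are explicit arguments
everywhere.

The *functional gradient* (`functional_gradient()`) is the first
non-trivial eigenvector of a diffusion-map embedding of FC: per-row
top-10% thresholding, cosine affinity with negatives clipped to zero,
anisotropic normalization with $\alpha = 0.5$, row normalization, and the
second eigenvector of the resulting transition matrix (diffusion time 0).
Regions with gradient $> 0$ form the "transmodal" group, the rest the
"unimodal" group (`split_by_gradient()`; the strict inequality is
deliberate). The embedding parameters follow the standard diffusion-map
recipe for cortical gradients and are all exposed.

## Hypothesis-testing machinery

Three null families are provided. (1) `label_permutation_test()` permutes
regions' network assignments and recomputes network mean couplings
(default 10,000 permutations). (2) `spin_permutation()` draws uniform 3-D
rotations of the regions' spherical coordinates and re-matches regions
greedily one-to-one, preserving spatial autocorrelation. (3)
`rewire_preserving_degree()` applies Maslov–Sneppen double-edge swaps that
carry weights with edges (default budget: 10x the edge count in attempted
swaps), and `degree_preserving_spatial_null()` resamples the topology from
the degree sequence outright while keeping coordinates and the weight
multiset. Empirical p-values use the proportion rule with a $+1$
correction, $p = (1 + \#\{\text{at least as extreme}\})/(1 + n)$, so $p$
is never zero while the raw proportion (attached as an attribute)
reproduces the "$P < 10^{-4}$ at $n = 10{,}000$" reporting convention.
Multiple comparisons use Benjamini–Hochberg (`fdr_bh()`).
`pseudo_eigenmode()` generates frequency-matched surrogate modes: a random
unit vector in the span of the `window` (default 21) eigenmodes nearest in
eigenvalue, which preserves band-limited spectral content and norm by
construction; the cited literature names no formula, so this construction
was chosen for those two provable properties.

Model comparison (`compare_models()`) contrasts the low-only model with a
combined low+high model under 80/20 subject splits (default 100
repetitions). The combined model is an L1-penalized (LASSO, via glmnet)
fit in which only high-frequency features are penalized by default — the
main-analysis convention that "preserves all low-frequency eigenmodes" —
with `penalize_low = TRUE` for the all-bands variant. The penalty is
chosen per region by nested 80/20 splits *within* the training set
(default 20 inner repetitions) on a 50-point log-spaced grid spanning
$[10^{-4}, 1] \times \lambda_{\max}$, where $\lambda_{\max}$ is computed
from the data as the smallest penalty zeroing all penalized coefficients.
Eigenmodes of every subject-subset group-average connectome are aligned to
the all-subject reference basis (`align_eigenmodes()`: greedy matching
maximizing $|\cos|$ within a $\pm 10$-index window, then sign fixing)
before any coefficients are transported; test-set evaluation uses the
test-group-average SC eigenmodes and FC, the reading we adopted of an
ambiguous protocol (the alternative — averaging per-subject predictions —
is a one-line change in user code). Growth curves (`growth_curve()`) add
random subsets of the high band to the in-sample OLS model, without
sparsity selection, because random addition is the point of that analysis.

## The synthetic world

Every downstream stage is testable because the generator plants known
structure.

**Geometry.** `generate_structural_connectome()` places regions on a
Fibonacci sphere lattice with a small angular jitter (default 0.02) and
connects the shortest `density` fraction of pairs with weights
$e^{-d/\text{decay\_length}}$ times log-normal noise. The quasi-uniform
lattice is a deliberate choice: with i.i.d. random placement, degree
heterogeneity localizes the high-frequency eigenmodes onto a few regions
(participation ratios of 2–10 on 200 regions), and any band-limited
symmetric signal built from them is spiky — it must either be clipped,
destroying the exact band membership the zero-noise tests rely on, or
rescaled down until the fixed observation noise dominates. On the lattice,
participation ratios stay near $N/3$ across the spectrum. What a green
test does *not* establish, therefore, is robustness to the strong mode
localization of empirical connectomes.

**Planted signals.** `synthetic_ground_truth()` builds a symmetric matrix
$M = M_L + M_H + \text{baseline}$ and derives per-region, per-mode
coefficients from it. Each band matrix has its columns *exactly* in the
band's span (so zero-noise band regressions give $R = 1$ to machine
precision) and is shaped by alternating projections with four structural
constraints:

* *hollow diagonal* — a planted column's implied self-value leaks into the
  complementary band's regression through the dropped-self-row design
  (fitting $p$ high-band predictors on $N - 1$ observations captures
  $\hat y_i^2 \cdot m_H(i) / (1 - m_H(i))$ of a smooth column with implied
  self-value $\hat y_i$, where $m_H(i)$ is the high-band mass at region
  $i$), so diagonals are pushed toward zero;
* *group support* — the high-band signal is confined to the null space of
  the unimodal rows of the band, which makes its unimodal columns exactly
  zero; this is possible only because the band dimension
  ($0.566N$ at the default $K_H$) exceeds the unimodal group size, which
  is why the default planted gradient (the Fiedler vector centered at its
  0.45 quantile) produces a 45/55 unimodal/transmodal split. The low band
  has only $K_L - 1$ dimensions, fewer than the transmodal count, so its
  localization is approximate and transmodal low-band coupling sits near
  0.15 rather than 0;
* *equalized column energies* within the signal's own group (defaults:
  mean squared column norm 8 for the low signal, 10 for the high);
* *bounded entries*, so the planted matrix stays inside the correlation
  range without clipping (a residual global rescale at 0.95 is applied and
  logged if needed).

Gaussian noise (default $\sigma = 0.05$) is added to the upper triangle
and mirrored; the diagonal is set to 1 and values clipped to $[-1, 1]$.
With these defaults the low-band coupling map averages $\approx 0.95$ on
unimodal and $\approx 0.13$ on transmodal regions, and the high-band map
reverses the pattern — the qualitative reversal the package's acceptance
tests require in 19 of 20 seeds.

**Recovery precision.** OLS recovery of planted coefficients has pooled
correlation $\approx \sqrt{E / (E + p\sigma^2)}$ for band size $p$ and
per-region signal energy $E$. The criterion of $r \ge 0.99$ is tested on
single-band worlds — the low band at default energy and the high band at
energy 18 — because in the mixed world the transmodal energy budget is
capped by the correlation range and the localization geometry, leaving the
pooled value at $\approx 0.990$, exactly at the threshold. This is a
property of the stated world, not of the estimator, and is documented
rather than hidden.

**Subjects and time series.** `generate_subject_set()` jitters template
weights multiplicatively (log-normal, mean one) and replants each
subject's FC from its own eigenmodes. The default jitter is 0.02: at
desk-scale $N$ the eigenvalue spacing is ~$N$-fold wider than on a
1000-region connectome, so high-frequency modes decorrelate across subject
subsets correspondingly faster, and 0.02 keeps group-average eigenmodes
transferable between train and test splits — the regime the reference
analysis operates in with 55+ subjects at $N = 1000$.
`generate_time_series()` draws Gaussian series with the planted FC as
target covariance; planted-and-clipped matrices need not be positive
semidefinite, so eigenvalues are clipped at $10^{-8}$ and the matrix
renormalized to unit diagonal (logged). `group_fc_bootstrap()` implements
the group-FC thresholding: 1000 resamples of 276 timepoints from the
concatenated series, keeping edges whose bootstrap percentile interval
excludes zero; the interval level is not fixed by the source protocol and
defaults to the conventional 95% (logged).

## Numerical conventions

Eigenvector signs are fixed by making each mode's largest-magnitude entry
positive (ties to the lowest region index); within numerically degenerate
eigenvalue groups, columns are ordered lexicographically. Disconnected
structural input is an error, not a largest-component extraction: the
normalization and the constant first mode assume one component, and the
generator guarantees connectivity. The regional fit excludes the trivial
unit self-connection from both fitting and $R$. $R$ is a Pearson
correlation, not $R^2$. Predictors are never standardized (eigenmodes are
unit norm). The gradient's sign is anchored so the highest-degree region
(structural if supplied, else functional) is non-positive. Coordinate
descent in glmnet runs at `thresh = 1e-14` (glmnet's internal deviance
scale) with up to $10^6$ passes, tight enough that the $\lambda = 0$ end
of a warm-started path matches OLS to $10^{-6}$.

## Known limitations

The generator does not model hemispheric symmetry, geodesic distances,
realistic hemodynamics, or tractography biases, and its delocalized
eigenmodes are cleaner than any empirical connectome's. Group sizes,
energies and noise were chosen once to make every planted property
measurable at desk scale; conclusions about empirical data require the
real pipelines this package's contracts mirror. The `pseudo_benchmark()`
comparison fits OLS on fixed designs rather than re-running the nested
LASSO per randomization; this keeps the benchmark apples-to-apples with
its empirical counterpart at 10 x 100 scale. Multi-gradient alignment
(Procrustes) and gradient dispersion metrics are out of scope.
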