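---
title: "Contrastive PCA for spatial and functional data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive PCA for spatial and functional data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastPCA)
```

## The model

Given a target dataset with empirical covariance $\hat\Sigma_T$ and a
background dataset with covariance $\hat\Sigma_B$ over the same $p$
features, contrastive PCA seeks directions maximizing the Rayleigh quotient

$$\mathcal{R}(v) \;=\; \frac{v^\top \hat\Sigma_T v}{v^\top \hat\Sigma_B v}.$$

Stationary points are generalized eigenvectors, $\hat\Sigma_T v = \lambda
\hat\Sigma_B v$, and the eigenvalue along each direction is exactly the
target-to-background variance ratio of the data projected onto it. This
identity (eigenvalue = projected variance ratio, verified to $10^{-8}$ in
the test suite) is what makes the spectrum directly interpretable: GE1 with
$\lambda_1 = 20$ means "twenty times more target variance than background
variance along this gene program".

The method assumes the background covariance is positive definite — the
quotient is meaningless along directions the background does not constrain.
In practice backgrounds can be rank-deficient (fewer observations than
features, or features with no variation), so a small ridge $\varepsilon I$
is added; see *Numerical choices*.

### Spatial extension (k-ρPCA)

When the $n$ target observations carry locations $s_i \in \mathbb{R}^m$
(spots or bins on a slide; any $m \ge 1$ is supported), the target
covariance is replaced by the kernel-weighted form

$$\hat\Sigma_T^K = \frac{1}{n-1} X^\top K X, \qquad
  K_{ij} = \exp\!\left(-\frac{\lVert s_i - s_j\rVert^2}{2h^2}\right),$$

with $X$ column-centered. The kernel up-weights covariance between nearby
observations, so variance that is *spatially coherent* dominates variance
that is merely large: a gene program fluctuating independently from spot to
spot contributes little to $X^\top K X$ because its positive and negative
fluctuations cancel under the smooth weighting, while a program following a
tissue domain contributes fully. The background (typically dissociated
scRNA-seq, which has no coordinates) keeps its plain covariance. Two
consequences of the construction worth knowing:

- With $K = I$ the method reduces exactly to plain contrastive PCA, and
  with an all-ones $K$ the weighted covariance of centered data vanishes;
  both limits are reached continuously as $h \to 0$ and $h \to \infty$ and
  are verified numerically in the tests.
- A truncated kernel (entries beyond a cutoff radius zeroed, diagonal kept)
  is generally indefinite, so the weighted covariance can have negative
  eigenvalues. These are retained, sorted normally, and flagged with a
  warning rather than clipped — they are informative (directions whose
  spatial autocovariance is negative) and clipping would silently change
  the objective.

### Functional extension (f-ρPCA)

For curves observed at (possibly irregular, per-sample) time points, each
sample is represented in a basis $B(t) = (b_1(t), \dots, b_D(t))^\top$ by
least squares, giving coefficient rows $a_i$ stacked into $A_X$ (target)
and $A_Y$ (background). With the Gram matrix
$G_{kl} = \int_\mathcal{T} b_k(t) b_l(t)\,dt$ the contrastive quotient over
functions $v(t) = c^\top B(t)$ becomes, after per-group centering,

$$\mathcal{R}(c) = \frac{c^\top G A_X^\top A_X G\, c \,/\, (n-1)}
                        {c^\top G A_Y^\top A_Y G\, c \,/\, (m-1)},$$

because the $L^2$ projection of sample $i$ onto $v$ is
$\int X_i(t) v(t)\,dt = a_i^\top G c$. Substituting $w = G^{1/2} c$ turns
this into the symmetric coefficient-space problem

$$\max_w \frac{w^\top G^{1/2} A_X^\top A_X G^{1/2} w}
              {w^\top G^{1/2} A_Y^\top A_Y G^{1/2} w},$$

solved by the core eigensolver; eigenfunction coefficients are recovered as
$c = G^{-1/2} w$. We derive and use this $G^{-1/2}$ back-map (the same
reduction used in classical basis-expansion functional PCA) because it is
the unique choice under which (a) the eigenvalues equal the
target-to-background variance ratios of the eigenfunction scores
$\theta_i = a_i^\top G c$ — checked to $10^{-6}$ in the tests against
scores computed independently by dense quadrature — and (b) with an
orthonormal basis ($G = I$) the method collapses to contrastive PCA of the
raw coefficients. Formulations that instead map solutions back with a
$G^{1/2}$ factor break both properties whenever the basis is
non-orthogonal, which B-splines are.

A discrete-domain variant (`f_rho_pca_discrete`) is provided for curves
measured on one shared grid: plain covariances of the gridded values, with
eigenvectors interpreted as functions by linear interpolation. On densely
sampled curves generated from a basis, the two routes agree (max absolute
difference of unit-normalized eigenfunctions below 0.05; tested).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | `min(10, p)` | Components returned. Applications typically inspect the first few GEs; 10 is a ceiling, not a recommendation. |
| `eps` | `1e-8 · tr(Σ_B)/p` | Background ridge, in variance units, scaled to the mean feature variance so it is dimensionless in effect. Large enough to make a PSD background numerically Cholesky-factorizable, small enough (8 orders below the data scale) not to perturb well-posed problems. |
| `h` | `sqrt(median pairwise distance)` | Kernel bandwidth, in coordinate units. The median heuristic adapts to the slide's scale without tuning; all unordered pairs enter, with the midpoint convention for even counts. |
| `radius` / `mean_neighbors` | none | Kernel truncation, for sparsity on large slides. `mean_neighbors = N` picks the smallest radius whose closed-ball neighbor count (self excluded) averages `N`; the count jumps only at observed pairwise distances, so the radius is located exactly on that grid. |
| `D`, `order` | 5, 4 | B-spline basis size and order (cubic). Five cubic splines resolve one interior feature per two-week trajectory without overfitting 11 time points. Interior knots are uniform on the domain with full end-knot multiplicity. |
| `r2_min`, `min_per_group` | 0.5, 7 | Trajectory QC: keep fits with $R^2 \ge 0.5$ (inclusive), analyze a gene only if both groups retain at least 7 trajectories. |
| `scale` (depth normalization) | $10^4$ | Counts-per-ten-thousand before `log1p`, the convention used throughout single-cell analysis. |

## Numerical choices

- **Solver.** $\hat\Sigma_B + \varepsilon I = LL^\top$ by Cholesky; the
  ordinary symmetric eigenproblem of $L^{-1} \hat\Sigma_T L^{-\top}$ is
  solved and back-transformed ($v = L^{-\top} u$). This guarantees real
  eigenvalues and $\Sigma_B$-orthonormal eigenvectors
  ($V^\top (\hat\Sigma_B + \varepsilon I) V = I$) by construction, unlike
  generic nonsymmetric generalized solvers. A Cholesky failure aborts with
  the offending smallest eigenvalue named.
- **Signs and ties.** Each eigenvector is flipped so its largest-magnitude
  entry is positive — signs are otherwise arbitrary. Within a degenerate
  eigenvalue the returned basis of the eigenspace is arbitrary too; tests
  of degenerate cases compare subspaces, not vectors.
- **Symmetrization.** Kernel-weighted covariances are exactly symmetrized
  as $(S + S^\top)/2$; inputs asymmetric beyond $10^{-8}$ relative are
  rejected rather than silently symmetrized.
- **Gram matrices.** Monomial and Fourier entries are closed-form; B-spline
  entries use Gauss–Legendre quadrature per knot span with the node count
  exact for the product degree, cross-checked by order doubling (and, in
  the tests, against dense trapezoid integration).
- **Matrix square roots.** $G^{1/2}$ via eigendecomposition with negative
  roundoff eigenvalues clipped at zero; substantially negative eigenvalues
  are an error, not a clip.
- **Degenerate fits.** A constant trajectory has $TSS = 0$; its $R^2$ is
  defined as 0 so any positive QC threshold drops it. Samples with fewer
  distinct in-domain time points than basis functions are excluded with a
  recorded reason, not an error.
- **Memory.** Truncated kernels are stored sparse and $X^\top K X$ is
  computed as $X^\top (KX)$, never materializing a dense $n \times n$
  product.

## What the synthetic generators emulate

`make_spatial_dataset` plants one gene program $u^*$ (a unit loading vector
supported on a third of the features) whose activity follows a smooth
one-period sinusoidal stripe across a 16×16 spot grid, on top of three
shared non-spatial modes and Gaussian noise; the background (1000
observations, the depth expected of a dissociated single-cell reference)
carries the shared modes and noise but no stripe. `make_functional_dataset`
plants one unit-$G$-norm temporal mode drawn at score SD 3 in the target
group only, over two shared modes (both groups, unit SD), isotropic
curve-level variation (unit projection SD in every direction of function
space, giving a strictly positive definite background covariance operator),
and measurement noise (SD 0.3) at the 11 design time points of a two-week
course (days 0–9 and 14), 50 curves per group. Truth records carry the
planted loadings, fields, and scores, so recovery is measured against known
ground truth.

What the generators do **not** emulate: count overdispersion and sparsity
(values are Gaussian, not negative binomial), hexagonal Visium geometry,
batch effects, or correlated measurement noise. Passing recovery tests
therefore demonstrates that the estimators find planted low-rank contrasts
under Gaussian noise at realistic sizes — not that they are robust to the
full error structure of real assays, where the preprocessing filters and
normalizations in this package do part of that work.

Problem sizes used throughout the test and acceptance suites — 256 spots ×
30 features with a 1000-observation background (spatial); 50–150 curves
per group, $D = 5$ (functional); 20 simulated datasets per recovery
experiment — were chosen so each experiment isolates one statistical
question at the smallest size where the answer is interpretable.

The ranking experiment (four genes with planted score-variance ratios 8,
4, 2, 1 between groups) uses 150 curves per group by a power argument: a
variance-ratio estimate from two groups of $n$ curves has coefficient of
variation $\approx \sqrt{4/n}$, and resolving adjacent factor-2 gaps (log
gap 0.69) at roughly three standard errors requires $n \approx 150$. At
$n = 50$ the orderings of neighboring ratios invert too often for the
experiment to measure the estimator rather than sampling noise.

## Known limitations

- **Mode recovery is background-limited at small group sizes.** The
  recovered direction is, in population terms, proportional to
  $\Sigma_B^{-1}$ applied to the planted contrast, so estimation noise in
  $\hat\Sigma_B$ rotates the answer by an angle of order $\sqrt{(D-1)/m}$
  — *independent of how strong the planted signal is*. At $m = 50$
  background curves with $D = 5$ this floor is roughly 0.3 radians, i.e.
  typical grid correlations around 0.95 with a heavy lower tail: the
  median recovery at the default functional scenario is high, but
  individual replicates below 0.9 are expected and observed. The spatial
  pipeline does not show this floor at defaults because its background has
  1000 observations. Users contrasting small groups should interpret
  single-dataset eigenfunctions with this sampling variability in mind (or
  increase the ridge deliberately, trading bias for stability).
- The solver is dense ($O(p^3)$); for feature counts beyond ~10⁴, subset
  to highly variable genes first (`select_hvg`), as the applications this
  package targets do.
- Sparse-design functional data (very few, irregular points per curve) is
  fit per sample by least squares; covariance-smoothing approaches for
  sparse designs are out of scope.
- `median_of_ratios_size_factors` implements only size factors, not
  dispersion estimation or differential tests; its reference set excludes
  features with any zero, so very sparse matrices need a pseudocount
  upstream.

## Design decisions that were genuinely open

- **Centering in coefficient space.** The quotient could be formed on raw
  or per-group-centered coefficients. Centering per group matches the
  operator formulation (covariances are about each process's own mean
  function) and makes the eigenvalue-as-variance-ratio identity exact; a
  flag (`center = FALSE`) restores the uncentered behavior.
- **Explicit $(n-1)$ divisors.** With unequal group sizes the divisors do
  not cancel in the quotient; making them explicit keeps eigenvalues
  interpretable as variance ratios regardless of group sizes.
- **Neighbor semantics.** Truncation zeroes kernel entries beyond the
  radius (keeping the unit diagonal) rather than switching to k-nearest
  neighbors, and neighbor counts exclude self; both choices follow the
  radius-based definition of spatial neighborhoods.
- **HVG selection** ranks features by variance of depth-normalized log
  values computed on the background only — the simplest defensible
  definition, and configurable, since dispersion-based alternatives exist.
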