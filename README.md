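# contrastPCA

Contrastive principal component analysis for spatial and functional
transcriptomics, built around a single primitive: Rayleigh-quotient
maximization solved as a generalized eigenproblem.

## The problem

Ordinary PCA finds directions of maximal variance in one dataset. Many
genomics questions are instead *contrastive*: which gene programs vary in a
tumor section but not in matched normal tissue, or which temporal expression
patterns appear after a booster vaccine dose but not after the primer dose?
Contrastive PCA answers this by maximizing the variance ratio between a
**target** and a **background** dataset,

```
v* = argmax_v  (vᵀ Σ̂_T v) / (vᵀ Σ̂_B v),
```

whose solutions are the generalized eigenvectors of the pair
`(Σ̂_T, Σ̂_B)`: the "GE" directions. Each eigenvalue λᵢ is the
target-to-background variance ratio along GEᵢ.

Two extensions broaden what "target variance" means:

- **k-ρPCA (spatial).** For a spatially registered target (Visium spots,
  Visium HD bins), the target covariance is replaced by its kernel-weighted
  form `Σ̂ᵀᴷ = XᵀKX/(n−1)`, with `K_ij = exp(−‖sᵢ−sⱼ‖²/2h²)` a Gaussian
  kernel over spot locations (bandwidth `h` defaulting to the square root of
  the median pairwise distance, optionally truncated at a radius chosen to
  hit a mean neighbor count). The leading GEs are gene programs with high
  *spatially coherent* variance in the tissue and low variance in a
  non-spatial background such as scRNA-seq of adjacent normal tissue — a
  direct route to spatially variable, condition-specific genes.
- **f-ρPCA (functional).** For two groups of curves (e.g. per-patient
  expression trajectories after two vaccine doses), each curve is fit to a
  basis `B(t)` (B-splines by default) and the same quotient is maximized in
  coefficient space, with the basis Gram matrix
  `G_kl = ∫ b_k(t) b_l(t) dt` correcting for non-orthogonality:

  ```
  w* = argmax_w  (wᵀ G^½ A_Xᵀ A_X G^½ w) / (wᵀ G^½ A_Yᵀ A_Y G^½ w).
  ```

  Solutions map back to eigenfunctions `v(t)` — contrastive temporal modes
  of variation. Projecting fitted curves onto `v₁` gives f-GE1 scores, and
  the target/background ratio of their variances ranks genes by how much
  extra temporal variation the target condition shows.

The package implements the solver (Cholesky whitening of the regularized
background, guaranteeing real eigenvalues and Σ_B-orthonormal directions),
both extensions, the surrounding preprocessing (count QC filters, depth
normalization, DESeq-style median-of-ratios size factors, day-0 trajectory
scaling, highly-variable-gene selection), synthetic data generators with
planted ground truth, format readers/writers (Matrix Market triplet,
delimited matrices, long-format curve tables), and a small CLI.

## Worked example

Synthetic data with known planted structure:

```r
library(contrastPCA)

## --- spatial: a gene program active along a smooth stripe, absent from a
##     non-spatial background
sp  <- make_spatial_dataset(spatial_scenario(seed = 42))
fit <- k_rho_pca(center_columns(sp$target), sp$coords,
                 center_columns(sp$background), k = 3)
fit$decomposition
#> <contrastive_decomposition> 3 components over 30 features
#>   eigenvalues: 236.486   4.975   4.131
round(fit$h, 3)
#> [1] 2.839
abs(cor(fit$decomposition$eigenvectors[, 1], sp$truth$u_star))
#> [1] 0.98

## --- functional: two groups of trajectories, one extra temporal mode in
##     the target group
fd <- make_functional_dataset(functional_scenario(seed = 42))
ft <- fit_samples(fd$target$times, fd$target$values, fd$basis, "target")
fb <- fit_samples(fd$background$times, fd$background$values, fd$basis,
                  "background")
qc  <- qc_filter(ft, fb, r2_min = 0.5, min_per_group = 7)
efs <- f_rho_pca(qc$target, qc$background, k = 2)
efs
#> <eigenfunction_set> 2 eigenfunctions, bspline basis D = 5
#>   eigenvalues: 9.077 1.329
score_variance_ratio(score_samples(qc$target, efs),
                     score_samples(qc$background, efs), 1)
#> [1] 9.08
```

The spatial eigenvalue of 236 says GE1 carries vastly more kernel-weighted
variance in the tissue than in the background, and its loadings recover the
planted gene program almost exactly (|r| = 0.98). The functional top
eigenvalue of 9.1 matches the planted target-only mode (score SD 3 against
unit background variation, so a variance ratio of 10 up to sampling error),
and equals the f-GE1 score variance ratio, as it must.

The same analyses run from a shell:

```sh
inst/cli/contrastpca synth --out fixtures --seed 42
inst/cli/contrastpca krho --target fixtures/target.tsv \
    --coords fixtures/coords.tsv --background fixtures/background.tsv \
    --k 3 --out results/krho
inst/cli/contrastpca frho --input fixtures/curves.tsv \
    --target-group target --k 2 --out results/frho
```

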