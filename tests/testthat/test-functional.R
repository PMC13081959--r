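test_that("make_basis builds the advertised systems", {
  mono <- make_basis("monomial", D = 2, domain = c(0, 1))
  expect_equal(mono$eval(c(0, 0.5, 1)),
               cbind(1, c(0, 0.5, 1)), ignore_attr = TRUE)
  expect_equal(mono$gram, matrix(c(1, 1/2, 1/2, 1/3), 2), tolerance = 1e-12)

  four <- make_basis("fourier", D = 3, domain = c(0, 2 * pi))
  expect_equal(four$gram, diag(3), tolerance = 1e-12)
  expect_equal(four$eval(1)[1, ],
               c(1 / sqrt(2 * pi), sin(1) / sqrt(pi), cos(1) / sqrt(pi)))

  bs <- make_basis("bspline", D = 5, domain = c(0, 14))
  expect_length(bs$knots, 5 + 4)             # D + order
  expect_equal(sum(bs$knots == 0), 4)        # full end multiplicity
  tt <- seq(0, 14, length.out = 23)
  expect_equal(rowSums(bs$eval(tt)), rep(1, 23))  # partition of unity

  expect_error(make_basis("bspline", D = 3, domain = c(0, 1)), "order")
})

test_that("gram matrices are symmetric and integrate basis products", {
  bs <- make_basis("bspline", D = 6, domain = c(-1, 3))
  expect_equal(bs$gram, t(bs$gram))
  # quadrature cross-check against dense trapezoid integration
  tt <- seq(-1, 3, length.out = 20001)
  B <- bs$eval(tt)
  w <- rep(diff(tt)[1], length(tt)); w[c(1, length(tt))] <- w[1] / 2
  G_trap <- crossprod(B * sqrt(w))
  expect_equal(bs$gram, G_trap, tolerance = 1e-6)
})

test_that("sqrt_psd computes the symmetric square root", {
  expect_equal(sqrt_psd(diag(2)), diag(2))
  expect_equal(sqrt_psd(diag(c(4, 9))), diag(c(2, 3)))
  set.seed(5)
  A <- random_spd(6)
  S <- sqrt_psd(A)
  expect_equal(S %*% S, A, tolerance = 1e-10)
  expect_error(sqrt_psd(diag(c(1, -1))), "positive semi-definite")
})

test_that("fit_samples recovers exact representations and flags bad samples", {
  bs <- make_basis("bspline", D = 5, domain = c(0, 10))
  tt <- seq(0, 10, length.out = 10)
  # a curve equal to the second basis function
  fs <- fit_samples(list(tt, tt), list(bs$eval(tt)[, 2], bs$eval(tt)[, 2]),
                    bs)
  expect_equal(fs$coefficients[1, ], c(0, 1, 0, 0, 0), tolerance = 1e-10)
  expect_equal(fs$r_squared[1], 1)

  # constants are exactly representable (partition of unity), R^2 := 0
  fc <- fit_samples(list(tt, tt), list(rep(3.5, 10), rep(-1, 10)), bs)
  expect_equal(fc$coefficients[1, ], rep(3.5, 5), tolerance = 1e-10)
  expect_equal(fc$r_squared, c(0, 0))

  # pure noise against a rich basis at many points fits poorly
  set.seed(15)
  tt2 <- seq(0, 10, length.out = 200)
  fn <- fit_samples(list(tt2), list(rnorm(200)), bs)
  expect_lt(fn$r_squared[1], 0.2)

  # too few distinct points: excluded with a reason, not an error
  ff <- fit_samples(list(c(0, 1, 2), tt), list(1:3, rnorm(10)), bs,
                    sample_ids = c("bad", "good"))
  expect_equal(nrow(ff$coefficients), 1L)
  expect_equal(ff$dropped$sample_id, "bad")
  expect_match(ff$dropped$reason, "distinct")
})

test_that("qc_filter applies the inclusive R^2 threshold and group minimum", {
  bs <- make_basis("monomial", D = 2, domain = c(0, 1))
  mk <- function(r2, group) {
    functional_sample_set(matrix(rnorm(2 * length(r2)), length(r2), 2), bs,
                          group = group, r_squared = r2)
  }
  all_good <- qc_filter(mk(rep(1, 10), "target"), mk(rep(1, 10), "background"),
                        r2_min = 0.5, min_per_group = 7)
  expect_true(all_good$pass)
  expect_equal(nrow(all_good$report), 0L)

  # boundary: exactly 0.5 is kept, 0.49 is dropped
  bd <- qc_filter(mk(c(0.5, 0.49), "target"), mk(rep(1, 3), "background"),
                  r2_min = 0.5, min_per_group = 1)
  expect_equal(nrow(bd$target$coefficients), 1L)
  expect_equal(bd$report$sample_id, "s2")

  # a group falling under the minimum fails the unit
  fail <- qc_filter(mk(c(rep(1, 6), rep(0, 4)), "target"),
                    mk(rep(1, 10), "background"),
                    r2_min = 0.5, min_per_group = 7)
  expect_false(fail$pass)
})

test_that("f_rho_pca with an orthonormal basis reduces to coefficient-space contrastive PCA", {
  set.seed(25)
  four <- make_basis("fourier", D = 4, domain = c(0, 1))
  AX <- matrix(rnorm(30 * 4), 30, 4) %*% diag(c(2, 1, 1, 0.5))
  AY <- matrix(rnorm(40 * 4), 40, 4)
  efs <- f_rho_pca(functional_sample_set(AX, four, "target"),
                   functional_sample_set(AY, four, "background"),
                   k = 4, eps = 0)
  dec <- generalized_eigensolve(sample_covariance(center_columns(AX)),
                                sample_covariance(center_columns(AY)),
                                k = 4, eps = 0)
  expect_equal(efs$eigenvalues, dec$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(diag(cor(efs$coefficient_vectors, dec$eigenvectors))),
               rep(1, 4), tolerance = 1e-6)
})

test_that("identical groups give unit eigenvalues; whitened orthonormality holds", {
  set.seed(35)
  bs <- make_basis("bspline", D = 5, domain = c(0, 14))
  A <- matrix(rnorm(25 * 5), 25, 5)
  same <- f_rho_pca(functional_sample_set(A, bs, "target"),
                    functional_sample_set(A, bs, "background"),
                    k = 5, eps = 0)
  expect_equal(same$eigenvalues, rep(1, 5), tolerance = 1e-9)

  B <- matrix(rnorm(25 * 5), 25, 5) + 0.5
  efs <- f_rho_pca(functional_sample_set(A, bs, "target"),
                   functional_sample_set(B, bs, "background"), k = 5)
  Gh <- sqrt_psd(bs$gram)
  Bc <- sweep(B, 2, colMeans(B), "-")
  CY <- Gh %*% crossprod(Bc) %*% Gh / (nrow(B) - 1) +
    diag(efs$regularization, 5)
  expect_equal(t(efs$w_vectors) %*% CY %*% efs$w_vectors, diag(5),
               tolerance = 1e-8)
  # eigenfunction coefficients live in the whitened relation c = G^{-1/2} w
  expect_equal(Gh %*% efs$coefficient_vectors, efs$w_vectors,
               tolerance = 1e-8)
})

test_that("eigenvalues are invariant to re-expressing curves in an equivalent basis", {
  # cubic polynomials: monomial D = 4 and a no-interior-knot cubic B-spline
  # basis span the same space
  set.seed(45)
  mono <- make_basis("monomial", D = 4, domain = c(0, 1))
  bsp <- make_basis("bspline", D = 4, domain = c(0, 1), order = 4)
  AXm <- matrix(rnorm(30 * 4), 30, 4) %*% diag(c(1.5, 1, 0.7, 0.4))
  AYm <- matrix(rnorm(30 * 4), 30, 4)
  tt <- seq(0, 1, length.out = 9)
  refit <- function(Am) {
    vals <- Am %*% t(mono$eval(tt))
    t(apply(vals, 1, function(y) lm.fit(bsp$eval(tt), y)$coefficients))
  }
  e_mono <- f_rho_pca(functional_sample_set(AXm, mono, "target"),
                      functional_sample_set(AYm, mono, "background"),
                      k = 4, eps = 0)
  e_bsp <- f_rho_pca(functional_sample_set(refit(AXm), bsp, "target"),
                     functional_sample_set(refit(AYm), bsp, "background"),
                     k = 4, eps = 0)
  expect_equal(e_bsp$eigenvalues, e_mono$eigenvalues, tolerance = 1e-6)
})

test_that("the discrete route matches the basis route on densely sampled curves", {
  fd <- make_functional_dataset(functional_scenario(seed = 2L,
                                                    measurement_noise_sd = 0))
  grid <- seq(0, 14, length.out = 60)
  B <- fd$basis$eval(grid)
  gd <- f_rho_pca_discrete(fd$target$coefficients %*% t(B),
                           fd$background$coefficients %*% t(B), grid, k = 1)
  efs <- f_rho_pca(
    functional_sample_set(fd$target$coefficients, fd$basis, "target"),
    functional_sample_set(fd$background$coefficients, fd$basis, "background"),
    k = 1)
  nrm <- function(v) v / sqrt(sum(v^2))
  vb <- nrm(efs$evaluate(grid)[, 1]); vd <- nrm(gd$vectors[, 1])
  expect_lt(min(max(abs(vb - vd)), max(abs(vb + vd))), 0.05)

  # interpolation contract between grid points
  mid <- (grid[3] + grid[4]) / 2
  expect_equal(gd$evaluate(mid)[1], (gd$vectors[3, 1] + gd$vectors[4, 1]) / 2)

  set.seed(55)
  X <- matrix(rnorm(20 * 6), 20, 6)
  same <- f_rho_pca_discrete(X, X, 1:6, k = 6, eps = 0)
  expect_equal(same$eigenvalues, rep(1, 6), tolerance = 1e-9)
  expect_error(f_rho_pca_discrete(X, X, 1:5), "grid length")
})

test_that("scores are exact L2 projections of fitted curves", {
  set.seed(65)
  bs <- make_basis("bspline", D = 5, domain = c(0, 14))
  G <- bs$gram
  fd <- make_functional_dataset(functional_scenario(seed = 9L))
  ft <- fit_samples(fd$target$times, fd$target$values, bs, "target")
  fb <- fit_samples(fd$background$times, fd$background$values, bs,
                    "background")
  efs <- f_rho_pca(ft, fb, k = 2)

  # a sample equal to v1 (scaled to unit G-norm) scores exactly 1
  c1 <- efs$coefficient_vectors[, 1]
  c1 <- c1 / sqrt(drop(crossprod(c1, G %*% c1)))
  efs_unit <- efs
  efs_unit$coefficient_vectors <- cbind(c1)
  self <- functional_sample_set(rbind(c1, -c1), bs, "target")
  th <- score_samples(self, efs_unit, center = FALSE)
  expect_equal(unname(th$scores[, 1]), c(1, -1), tolerance = 1e-10)

  # a G-orthogonal sample scores 0
  ortho <- qr.Q(qr(cbind(G %*% c1, diag(5))))[, 2]
  th0 <- score_samples(functional_sample_set(rbind(ortho, ortho), bs,
                                             "target"),
                       efs_unit, center = FALSE)
  expect_equal(unname(th0$scores[, 1]), c(0, 0), tolerance = 1e-10)

  # coefficient-space inner products match dense trapezoid quadrature
  st <- score_samples(ft, efs, center = TRUE)
  tg <- seq(0, 14, length.out = 1e4)
  Bg <- bs$eval(tg)
  Ac <- sweep(ft$coefficients, 2, colMeans(ft$coefficients), "-")
  v1g <- Bg %*% efs$coefficient_vectors[, 1]
  for (i in c(1, 7)) {
    xi <- Bg %*% Ac[i, ]
    quad <- pracma::trapz(tg, as.numeric(xi * v1g))
    expect_equal(unname(st$scores[i, 1]), quad, tolerance = 1e-4)
  }
})

test_that("score variance ratios behave as variance ratios", {
  bs <- make_basis("monomial", D = 1, domain = c(0, 1))
  mk <- function(v, g) {
    s <- functional_sample_set(cbind(v), bs, g)
    structure(list(scores = cbind(fGE1 = v), group = g,
                   sample_ids = s$sample_ids), class = "score_set")
  }
  expect_equal(score_variance_ratio(mk(c(-1, 0, 1), "target"),
                                    mk(c(-1, 0, 1), "background")), 1)
  expect_equal(score_variance_ratio(mk(c(-2, 0, 2), "target"),
                                    mk(c(-1, 0, 1), "background")), 4)
  expect_error(score_variance_ratio(mk(c(-1, 0, 1), "target"),
                                    mk(c(2, 2, 2), "background")),
               "degenerate")

  # in-sample ratio on component 1 equals the top eigenvalue at eps = 0
  fd <- make_functional_dataset(functional_scenario(seed = 3L))
  ft <- fit_samples(fd$target$times, fd$target$values, fd$basis, "target")
  fb <- fit_samples(fd$background$times, fd$background$values, fd$basis,
                    "background")
  efs <- f_rho_pca(ft, fb, k = 2, eps = 0)
  r <- score_variance_ratio(score_samples(ft, efs), score_samples(fb, efs), 1)
  expect_equal(r, efs$eigenvalues[1], tolerance = 1e-6)
})

test_that("an isotropic background reduces f-rhoPCA to ordinary functional PCA", {
  fd <- make_functional_dataset(functional_scenario(
    seed = 8L, n_target = 100L, n_background = 2000L, n_shared = 2L,
    target_extra_sd = 2, measurement_noise_sd = 0))
  # background drawn with only the isotropic component
  fdb <- make_functional_dataset(functional_scenario(
    seed = 9L, n_background = 2000L, n_shared = 0L, target_extra_sd = 0,
    measurement_noise_sd = 0))
  ft <- functional_sample_set(fd$target$coefficients, fd$basis, "target")
  fb <- functional_sample_set(fdb$background$coefficients, fd$basis,
                              "background")
  efs <- f_rho_pca(ft, fb, k = 1)
  cref <- fpca_oracle(fd$target$coefficients, fd$basis, k = 1)
  tg <- seq(0, 14, length.out = 200)
  expect_gt(abs(cor(efs$evaluate(tg)[, 1],
                    drop(fd$basis$eval(tg) %*% cref[, 1]))), 0.9)
})

test_that("a planted target-only mode is recovered across seeds", {
  corrs <- sapply(1:10, function(s) {
    fd <- make_functional_dataset(functional_scenario(seed = s))
    ft <- fit_samples(fd$target$times, fd$target$values, fd$basis, "target")
    fb <- fit_samples(fd$background$times, fd$background$values, fd$basis,
                      "background")
    efs <- f_rho_pca(ft, fb, k = 1)
    grid_cor(efs, fd$truth$v_star, fd$basis)
  })
  # background-whitening noise at 50 curves per group caps per-seed
  # alignment (see the methods vignette); recovery must still be strong
  # in aggregate and never near chance
  expect_gt(median(corrs), 0.9)
  expect_gt(min(corrs), 0.6)
})

test_that("planted variance ratios order genes by score variance ratio", {
  ratios <- c(8, 4, 2, 1)
  ok <- sapply(1:5, function(s) {
    est <- sapply(seq_along(ratios), function(j) {
      fd <- make_functional_dataset(functional_scenario(
        seed = s * 10 + j, n_target = 150L, n_background = 150L,
        target_extra_sd = sqrt(ratios[j] - 1)))
      ft <- fit_samples(fd$target$times, fd$target$values, fd$basis,
                        "target")
      fb <- fit_samples(fd$background$times, fd$background$values, fd$basis,
                        "background")
      efs <- f_rho_pca(ft, fb, k = 1)
      score_variance_ratio(score_samples(ft, efs), score_samples(fb, efs), 1)
    })
    all(diff(est) < 0)
  })
  expect_gte(sum(ok), 4)
})
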