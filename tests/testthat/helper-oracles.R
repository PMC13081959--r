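# Shared fixtures and independent oracles used across test files.

# random symmetric positive definite matrix with eigenvalues in [lo, hi]
random_spd <- function(p, lo = 0.5, hi = 2) {
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  Q %*% (runif(p, lo, hi) * t(Q))
}

# brute-force Rayleigh quotient maximization over direction grids.
# For p == 3 a Fibonacci sphere (near-uniform); otherwise random directions.
# With refine = TRUE the best global direction seeds a second, local
# Fibonacci patch (still pure enumeration, never the solver's answer).
rq_grid_max <- function(ST, SB, n_dir = 1e4, refine = FALSE) {
  p <- ncol(ST)
  rq <- function(V) rowSums((V %*% ST) * V) / rowSums((V %*% SB) * V)
  if (p == 3) {
    i <- seq_len(n_dir) - 0.5
    phi <- acos(1 - 2 * i / n_dir)
    theta <- pi * (1 + sqrt(5)) * i
    V <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  } else {
    V <- matrix(rnorm(n_dir * p), n_dir, p)
    V <- V / sqrt(rowSums(V^2))
  }
  vals <- rq(V)
  best <- max(vals)
  if (!refine) return(best)
  v0 <- V[which.max(vals), ]
  # enumerate a small cap of perturbed directions around the best point
  for (radius in c(4, 0.5, 0.06) * sqrt(4 * pi / n_dir)) {
    B <- qr.Q(qr(cbind(v0, diag(p))))[, 2:p, drop = FALSE]
    ang <- matrix(rnorm(n_dir * (p - 1)), n_dir, p - 1)
    ang <- ang / sqrt(rowSums(ang^2)) * runif(n_dir, 0, radius)
    Vc <- t(v0 %o% rep(1, n_dir)) + ang %*% t(B)
    Vc <- Vc / sqrt(rowSums(Vc^2))
    vals <- rq(Vc)
    if (max(vals) > best) {
      best <- max(vals)
      v0 <- Vc[which.max(vals), ]
    }
  }
  best
}

# ordinary functional PCA of one coefficient set (independent route used to
# check the contrastive reduction): eigenfunctions of the L2 covariance
# operator of the fitted curves.
fpca_oracle <- function(A, basis, k = 1) {
  A <- sweep(A, 2L, colMeans(A), "-")
  Gh <- sqrt_psd(basis$gram)
  Cw <- Gh %*% crossprod(A) %*% Gh / (nrow(A) - 1)
  es <- eigen((Cw + t(Cw)) / 2, symmetric = TRUE)
  solve(Gh, es$vectors[, seq_len(k), drop = FALSE])
}

# grid correlation between an eigenfunction column and a coefficient-space
# truth vector, on a dense grid
grid_cor <- function(efs, truth_coefs, basis, n_grid = 200) {
  tg <- seq(basis$domain[1], basis$domain[2], length.out = n_grid)
  abs(cor(efs$evaluate(tg)[, 1], drop(basis$eval(tg) %*% truth_coefs)))
}
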