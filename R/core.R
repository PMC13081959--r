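# ---- centered matrices -------------------------------------------------------

#' Center the columns of an observations-by-features matrix
#'
#' Subtracts the column (feature) means so that every feature has mean zero
#' across observations, the form in which all covariance computations in the
#' package expect their input.
#'
#' @param M Numeric matrix, observations in rows, features in columns. Row and
#'   column names, when present, are carried over as observation and feature
#'   identifiers.
#' @param feature_ids,obs_ids Optional character vectors overriding the
#'   dimnames of `M`.
#' @return A `centered_matrix` object: a list with elements `values` (the
#'   centered matrix), `centered = TRUE`, `feature_ids`, `obs_ids`, and
#'   `means` (the subtracted column means).
#' @examples
#' cm <- center_columns(matrix(c(1, 3, 2, 4), 2, 2))
#' colMeans(cm$values)  # all zero
#' @export
center_columns <- function(M, feature_ids = NULL, obs_ids = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) {
    stop("center_columns: need at least 2 observations, got ", nrow(M))
  }
  if (!all(is.finite(M))) {
    stop("center_columns: input contains non-finite entries")
  }
  mu <- colMeans(M)
  values <- sweep(M, 2L, mu, "-")
  new_centered_matrix(values,
                      feature_ids = feature_ids %||% colnames(M),
                      obs_ids = obs_ids %||% rownames(M),
                      means = mu)
}

new_centered_matrix <- function(values, feature_ids = NULL, obs_ids = NULL,
                                means = NULL, centered = TRUE) {
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  if (is.null(obs_ids)) obs_ids <- paste0("obs", seq_len(nrow(values)))
  stopifnot(length(feature_ids) == ncol(values),
            length(obs_ids) == nrow(values))
  structure(list(values = values, centered = centered,
                 feature_ids = as.character(feature_ids),
                 obs_ids = as.character(obs_ids),
                 means = means),
            class = "centered_matrix")
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat(sprintf("<centered_matrix> %d observations x %d features (centered: %s)\n",
              nrow(x$values), ncol(x$values), x$centered))
  invisible(x)
}

as_centered_matrix <- function(M) {
  if (inherits(M, "centered_matrix")) return(M)
  center_columns(M)
}

# ---- covariance matrices -----------------------------------------------------

new_covariance_matrix <- function(values, divisor, kind) {
  stopifnot(kind %in% c("plain", "kernel_weighted", "coefficient_space"))
  structure(list(values = values, divisor = divisor, kind = kind),
            class = "covariance_matrix")
}

#' @export
print.covariance_matrix <- function(x, ...) {
  cat(sprintf("<covariance_matrix> %d x %d, kind = %s, divisor = %d\n",
              nrow(x$values), ncol(x$values), x$kind, x$divisor))
  invisible(x)
}

#' Sample covariance of a centered matrix
#'
#' Computes `t(X) %*% X / (n - 1)` for a column-centered matrix `X`.
#'
#' @param M A `centered_matrix` (or a raw matrix if `center = TRUE`).
#' @param center If `TRUE`, a raw matrix is centered first; otherwise an
#'   uncentered input is an error.
#' @return A `covariance_matrix` of kind `"plain"`.
#' @export
sample_covariance <- function(M, center = FALSE) {
  if (!inherits(M, "centered_matrix")) {
    if (!center) {
      stop("sample_covariance: input is not a centered_matrix; ",
           "pass center = TRUE to center it first")
    }
    M <- center_columns(M)
  } else if (!isTRUE(M$centered)) {
    stop("sample_covariance: input matrix is marked uncentered")
  }
  n <- nrow(M$values)
  if (n < 2L) stop("sample_covariance: need at least 2 observations")
  S <- crossprod(M$values) / (n - 1)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(M$feature_ids, M$feature_ids)
  new_covariance_matrix(S, divisor = n - 1L, kind = "plain")
}

cov_values <- function(S) {
  if (inherits(S, "covariance_matrix")) S$values else as.matrix(S)
}

check_symmetric <- function(S, what = "matrix", tol = 1e-8) {
  a <- max(abs(S - t(S)))
  scale <- max(abs(S), 1e-300)
  if (a > tol * scale) {
    stop(what, " is asymmetric beyond tolerance (max |S - t(S)| = ",
         format(a), ")")
  }
  (S + t(S)) / 2
}

#' Default ridge regularization for a background covariance
#'
#' `1e-8 * trace(Sigma_B) / p`, a scale-aware ridge that makes a
#' rank-deficient background positive definite without measurably
#' perturbing well-conditioned problems.
#'
#' @param sigma_B Background covariance (`covariance_matrix` or matrix).
#' @return A nonnegative scalar.
#' @export
default_epsilon <- function(sigma_B) {
  S <- cov_values(sigma_B)
  1e-8 * sum(diag(S)) / ncol(S)
}

# ---- generalized eigenproblem ------------------------------------------------

#' Solve the contrastive generalized eigenproblem
#'
#' Finds directions `v` maximizing the Rayleigh quotient
#' `t(v) %*% Sigma_T %*% v / t(v) %*% Sigma_B %*% v`, the contrastive PCA
#' objective: generalized eigenvectors of the pair
#' `(Sigma_T, Sigma_B + eps * I)`. The solve whitens the background by a
#' Cholesky factorization `Sigma_B + eps*I = L %*% t(L)`, diagonalizes the
#' symmetric matrix `L^-1 Sigma_T L^-T`, and back-transforms, which
#' guarantees real eigenvalues and background-orthonormal eigenvectors
#' (`t(V) %*% (Sigma_B + eps*I) %*% V = I`).
#'
#' Eigenvalues are the target-to-background variance ratio along each
#' direction, sorted descending. Each eigenvector is sign-flipped so its
#' largest-magnitude entry is positive.
#'
#' @param sigma_T Target covariance (`covariance_matrix` or symmetric matrix).
#' @param sigma_B Background covariance, same dimension.
#' @param k Number of components to return (default `min(10, p)`).
#' @param eps Nonnegative ridge added to the background diagonal; default
#'   [default_epsilon()].
#' @return A `contrastive_decomposition`: list with `eigenvalues` (length
#'   `k`, descending), `eigenvectors` (`p x k`), `regularization`,
#'   `n_components`, `feature_ids`.
#' @examples
#' d <- generalized_eigensolve(diag(c(4, 1)), diag(2), k = 2, eps = 0)
#' d$eigenvalues  # 4 1
#' @export
generalized_eigensolve <- function(sigma_T, sigma_B, k = NULL, eps = NULL) {
  ST <- cov_values(sigma_T)
  SB <- cov_values(sigma_B)
  p <- ncol(ST)
  if (!all(dim(ST) == dim(SB))) {
    stop("generalized_eigensolve: covariance dimensions differ (",
         p, " vs ", ncol(SB), ")")
  }
  ST <- check_symmetric(ST, "target covariance")
  SB <- check_symmetric(SB, "background covariance")
  if (is.null(eps)) eps <- default_epsilon(SB)
  if (eps < 0) stop("generalized_eigensolve: eps must be nonnegative")
  if (is.null(k)) k <- min(10L, p)
  if (k > p) stop("generalized_eigensolve: k = ", k, " exceeds dimension p = ", p)

  SBr <- SB + diag(eps, p)
  R <- tryCatch(chol(SBr), error = function(e) NULL)
  if (is.null(R)) {
    emin <- min(eigen(SBr, symmetric = TRUE, only.values = TRUE)$values)
    stop("generalized_eigensolve: background covariance (+ eps*I) is not ",
         "positive definite; smallest eigenvalue = ", format(emin))
  }
  L <- t(R)  # lower triangular, SBr = L %*% t(L)

  # whitened target: L^-1 ST L^-T
  W <- forwardsolve(L, t(forwardsolve(L, ST)))
  W <- (W + t(W)) / 2
  es <- eigen(W, symmetric = TRUE)
  idx <- seq_len(k)
  lambda <- es$values[idx]
  U <- es$vectors[, idx, drop = FALSE]
  V <- backsolve(R, U)  # v = L^-T u

  # sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  if (any(lambda < 0)) {
    warning("generalized_eigensolve: ", sum(lambda < 0),
            " negative eigenvalue(s) retained (indefinite target covariance, ",
            "e.g. after kernel truncation)")
  }
  fid <- if (inherits(sigma_T, "covariance_matrix") &&
             !is.null(rownames(sigma_T$values))) rownames(sigma_T$values)
         else rownames(ST)
  structure(list(eigenvalues = lambda, eigenvectors = V,
                 regularization = eps, n_components = k,
                 feature_ids = fid),
            class = "contrastive_decomposition")
}

#' @export
print.contrastive_decomposition <- function(x, ...) {
  cat(sprintf("<contrastive_decomposition> %d components over %d features\n",
              x$n_components, nrow(x$eigenvectors)))
  cat("  eigenvalues:", format(utils::head(x$eigenvalues, 5), digits = 4),
      if (x$n_components > 5) "...\n" else "\n")
  invisible(x)
}

#' Rayleigh quotient of a direction for a covariance pair
#'
#' `t(v) %*% Sigma_T %*% v / t(v) %*% Sigma_B %*% v`; scale-invariant in
#' `v`, maximized by the top generalized eigenvector.
#'
#' @param v Nonzero numeric direction vector.
#' @param sigma_T,sigma_B Covariances (`covariance_matrix` or matrix).
#' @return Scalar quotient.
#' @export
rayleigh_quotient <- function(v, sigma_T, sigma_B) {
  v <- as.numeric(v)
  if (all(v == 0)) stop("rayleigh_quotient: v is the zero vector")
  ST <- cov_values(sigma_T)
  SB <- cov_values(sigma_B)
  den <- drop(crossprod(v, SB %*% v))
  if (den <= 0) {
    stop("rayleigh_quotient: degenerate direction, t(v) Sigma_B v = ",
         format(den), " <= 0")
  }
  drop(crossprod(v, ST %*% v)) / den
}

#' Project observations onto contrastive components
#'
#' @param M A `centered_matrix` (or raw matrix with matching feature count).
#' @param decomposition A `contrastive_decomposition`.
#' @return An `n x k` score matrix; column `i` holds per-observation scores
#'   on generalized eigenvector `i` (columns named `GE1`, `GE2`, ...).
#' @export
project_scores <- function(M, decomposition) {
  X <- if (inherits(M, "centered_matrix")) M$values else as.matrix(M)
  V <- decomposition$eigenvectors
  if (ncol(X) != nrow(V)) {
    stop("project_scores: feature dimension mismatch (", ncol(X),
         " vs ", nrow(V), ")")
  }
  S <- X %*% V
  colnames(S) <- paste0("GE", seq_len(ncol(S)))
  if (inherits(M, "centered_matrix")) rownames(S) <- M$obs_ids
  S
}

`%||%` <- function(a, b) if (is.null(a)) b else a
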