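# Spatial kernels and the kernel-weighted contrastive decomposition (k-rhoPCA).
# The target covariance is replaced by t(X) %*% K %*% X / (n-1), which
# up-weights covariance between spatially close observations so the leading
# contrastive directions reflect spatially coherent variance.

#' Construct spatial coordinates
#'
#' @param points Numeric `n x m` matrix of locations (m = 2 for slide
#'   coordinates; any m >= 1 is allowed).
#' @param obs_ids Optional identifiers aligned with the rows of an
#'   expression matrix; defaults to rownames or `obs1..obsn`.
#' @return A `spatial_coordinates` object.
#' @export
spatial_coordinates <- function(points, obs_ids = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L) stop("spatial_coordinates: need at least 2 points")
  if (!all(is.finite(points))) {
    stop("spatial_coordinates: non-finite coordinates")
  }
  obs_ids <- as.character(obs_ids %||% rownames(points) %||%
                            paste0("obs", seq_len(nrow(points))))
  if (anyDuplicated(obs_ids)) {
    stop("spatial_coordinates: duplicate obs_ids: ",
         paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", "))
  }
  structure(list(points = points, obs_ids = obs_ids),
            class = "spatial_coordinates")
}

#' @export
print.spatial_coordinates <- function(x, ...) {
  cat(sprintf("<spatial_coordinates> %d points in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

as_spatial_coordinates <- function(x) {
  if (inherits(x, "spatial_coordinates")) x else spatial_coordinates(x)
}

#' Median-heuristic kernel bandwidth
#'
#' The default bandwidth is the square root of the median pairwise Euclidean
#' distance among locations; the median of an even-length set of distances is
#' the midpoint of the two central values.
#'
#' @param coords A `spatial_coordinates` object or coordinate matrix.
#' @return Positive bandwidth `h`.
#' @export
median_bandwidth <- function(coords) {
  coords <- as_spatial_coordinates(coords)
  d <- stats::dist(coords$points)
  med <- stats::median(d)
  if (med <= 0) {
    stop("median_bandwidth: zero spread (median pairwise distance is 0)")
  }
  sqrt(med)
}

#' Gaussian spatial kernel
#'
#' `K[i, j] = exp(-d(i, j)^2 / (2 h^2))`. With a truncation `radius`, entries
#' beyond the radius are set to zero (the unit diagonal is always kept) and
#' the kernel is stored sparse. A truncated kernel may be indefinite; the
#' eigensolver tolerates (and warns about) the resulting negative
#' eigenvalues.
#'
#' @param coords A `spatial_coordinates` object or coordinate matrix.
#' @param h Positive bandwidth; default [median_bandwidth()].
#' @param radius Optional truncation radius (distance units).
#' @return A `spatial_kernel`: list with `weights` (`n x n`, dense matrix or
#'   sparse `Matrix`), `bandwidth`, `radius`, `kernel_kind = "gaussian"`,
#'   `obs_ids`.
#' @export
gaussian_kernel <- function(coords, h = NULL, radius = NULL) {
  coords <- as_spatial_coordinates(coords)
  if (is.null(h)) h <- median_bandwidth(coords)
  if (h <= 0) stop("gaussian_kernel: bandwidth h must be positive")
  D <- as.matrix(stats::dist(coords$points))
  K <- exp(-D^2 / (2 * h^2))
  dimnames(K) <- NULL
  if (!is.null(radius)) {
    if (radius <= 0) stop("gaussian_kernel: radius must be positive")
    K[D > radius] <- 0
    diag(K) <- 1
    K <- methods::as(methods::as(Matrix::Matrix(K), "generalMatrix"),
                     "CsparseMatrix")
    K <- Matrix::forceSymmetric(K)
  }
  structure(list(weights = K, bandwidth = h, radius = radius,
                 kernel_kind = "gaussian", obs_ids = coords$obs_ids),
            class = "spatial_kernel")
}

#' @export
print.spatial_kernel <- function(x, ...) {
  cat(sprintf("<spatial_kernel> %d x %d %s kernel, h = %.4g%s\n",
              nrow(x$weights), ncol(x$weights), x$kernel_kind, x$bandwidth,
              if (is.null(x$radius)) "" else sprintf(", radius = %.4g", x$radius)))
  invisible(x)
}

#' Truncation radius achieving a target mean neighbor count
#'
#' Returns the smallest radius `r` such that the mean over observations of
#' the number of other observations within distance `r` (closed boundary,
#' self excluded) reaches `target_mean`. Because the mean neighbor count is a
#' step function jumping only at observed pairwise distances, the smallest
#' feasible radius is one of those distances and is located exactly.
#'
#' @param coords A `spatial_coordinates` object or coordinate matrix.
#' @param target_mean Desired mean neighbor count, in `(0, n)`.
#' @return Positive radius.
#' @export
radius_for_mean_neighbors <- function(coords, target_mean) {
  coords <- as_spatial_coordinates(coords)
  n <- nrow(coords$points)
  if (target_mean >= n) {
    stop("radius_for_mean_neighbors: target_mean = ", target_mean,
         " is infeasible with n = ", n, " observations")
  }
  if (target_mean <= 0) stop("radius_for_mean_neighbors: target_mean must be > 0")
  d <- sort(as.numeric(stats::dist(coords$points)))
  # mean neighbor count at radius r is 2 * #{pairs with distance <= r} / n
  need <- ceiling(target_mean * n / 2 - 1e-12)
  if (need > length(d)) {
    stop("radius_for_mean_neighbors: target_mean = ", target_mean,
         " is infeasible (max attainable mean is ", 2 * length(d) / n, ")")
  }
  d[need]
}

#' Mean neighbor count at a given radius
#'
#' @param coords A `spatial_coordinates` object or coordinate matrix.
#' @param radius Radius (closed boundary; self excluded).
#' @return Mean over observations of the neighbor count.
#' @export
mean_neighbor_count <- function(coords, radius) {
  coords <- as_spatial_coordinates(coords)
  d <- as.numeric(stats::dist(coords$points))
  2 * sum(d <= radius) / nrow(coords$points)
}

#' Kernel-weighted sample covariance
#'
#' `t(X) %*% K %*% X / (n - 1)` for a centered matrix `X`, symmetrized as
#' `(S + t(S)) / 2` to absorb floating-point asymmetry. With `K = I` this
#' reduces to the plain sample covariance; with an all-ones `K` it vanishes
#' on centered data.
#'
#' @param M A `centered_matrix`.
#' @param K A `spatial_kernel` (or bare `n x n` weight matrix).
#' @return A `covariance_matrix` of kind `"kernel_weighted"`.
#' @export
kernel_weighted_covariance <- function(M, K) {
  if (!inherits(M, "centered_matrix")) {
    stop("kernel_weighted_covariance: M must be a centered_matrix")
  }
  W <- if (inherits(K, "spatial_kernel")) K$weights else K
  n <- nrow(M$values)
  if (nrow(W) != n || ncol(W) != n) {
    stop("kernel_weighted_covariance: kernel dimension (", nrow(W),
         ") does not match observation count (", n, ")")
  }
  if (inherits(K, "spatial_kernel") && !is.null(K$obs_ids)) {
    bad <- which(K$obs_ids != M$obs_ids)
    if (length(bad)) {
      stop("kernel_weighted_covariance: obs_ids misaligned at positions ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
  }
  # (K X) first: never materializes a dense K %*% t(X)
  KX <- as.matrix(W %*% M$values)
  S <- crossprod(M$values, KX) / (n - 1)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(M$feature_ids, M$feature_ids)
  new_covariance_matrix(S, divisor = n - 1L, kind = "kernel_weighted")
}

#' Kernel-weighted contrastive PCA (k-rhoPCA)
#'
#' Contrasts a spatially registered target expression matrix against a
#' non-spatial background: maximizes
#' `t(v) SigmaK_T v / t(v) Sigma_B v` where `SigmaK_T` is the
#' kernel-weighted target covariance. The leading generalized eigenvectors
#' are gene programs with high spatially coherent variance in the target and
#' low variance in the background; their eigenvalues are the corresponding
#' variance ratios.
#'
#' @param target Target expression, a `centered_matrix` or raw
#'   observations-by-features matrix (centered on entry).
#' @param coords `spatial_coordinates` (or coordinate matrix) for the target
#'   observations, aligned by `obs_ids`.
#' @param background Background expression over the identical ordered feature
#'   list, `centered_matrix` or raw matrix.
#' @param k Number of components (default `min(10, p)`).
#' @param h Kernel bandwidth; `NULL` (default) for the median heuristic.
#' @param radius Optional kernel truncation radius; `NULL` for no truncation.
#' @param mean_neighbors Alternative to `radius`: choose the radius so the
#'   mean spatial neighbor count equals this value
#'   (see [radius_for_mean_neighbors()]).
#' @param eps Background ridge; default [default_epsilon()].
#' @return List with `decomposition` (a `contrastive_decomposition`),
#'   `scores` (target observations projected on the components), `kernel`,
#'   `h`, and `radius` as resolved.
#' @export
k_rho_pca <- function(target, coords, background, k = NULL, h = NULL,
                      radius = NULL, mean_neighbors = NULL, eps = NULL) {
  target <- as_centered_matrix(target)
  background <- as_centered_matrix(background)
  coords <- as_spatial_coordinates(coords)
  if (ncol(target$values) != ncol(background$values) ||
      !identical(target$feature_ids, background$feature_ids)) {
    stop("k_rho_pca: target and background must share an identical ordered ",
         "feature list")
  }
  if (nrow(coords$points) != nrow(target$values)) {
    stop("k_rho_pca: coordinate count (", nrow(coords$points),
         ") does not match target observations (", nrow(target$values), ")")
  }
  if (!is.null(mean_neighbors)) {
    if (!is.null(radius)) stop("k_rho_pca: give radius or mean_neighbors, not both")
    radius <- radius_for_mean_neighbors(coords, mean_neighbors)
  }
  if (is.null(h)) h <- median_bandwidth(coords)
  # reuse the target's obs_ids so alignment is by construction
  kern <- gaussian_kernel(
    spatial_coordinates(coords$points, obs_ids = target$obs_ids),
    h = h, radius = radius)
  sigma_T <- kernel_weighted_covariance(target, kern)
  sigma_B <- sample_covariance(background)
  dec <- generalized_eigensolve(sigma_T, sigma_B, k = k, eps = eps)
  scores <- project_scores(target, dec)
  list(decomposition = dec, scores = scores, kernel = kern,
       h = h, radius = radius)
}
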