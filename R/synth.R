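# Synthetic datasets with planted contrastive structure. The spatial
# scenario emulates a spatially registered target carrying one smooth
# spatial expression mode (a gene program active along a low-frequency
# stripe) on top of shared non-spatial modes also present in the background;
# the functional scenario emulates two groups of noisy curves sharing
# background modes of variation with one extra mode present (or inflated)
# only in the target group. Truth records carry the planted loadings and
# scores so recovery can be measured exactly.

#' Spatial scenario parameters
#'
#' Defaults describe a modest slide contrasted against a deep non-spatial
#' reference: a 16 x 16 unit grid of spots, 30 features, a gene program `u*`
#' loading on a random third of the features, a one-period sinusoidal stripe
#' across the grid's long axis (mean zero, unit standard deviation over
#' spots) scaled by `field_amplitude`, three shared non-spatial modes at
#' unit score standard deviation, Gaussian residual noise, and 1000
#' background observations (dissociated single-cell references are
#' typically much deeper than the slide, and the background covariance must
#' be estimated well for the contrast to be stable).
#'
#' @param grid_shape `c(rows, cols)` of the spot grid.
#' @param p Feature count.
#' @param n_background Background observation count.
#' @param n_shared Number of shared (non-spatial) modes.
#' @param shared_sd Score standard deviation of each shared mode.
#' @param field_amplitude Scale of the spatial field (signal strength of the
#'   planted mode).
#' @param noise_sd Residual Gaussian noise standard deviation.
#' @param seed Integer seed; all randomness is local to the generator.
#' @return A `spatial_scenario` parameter list.
#' @export
spatial_scenario <- function(grid_shape = c(16L, 16L), p = 30L,
                             n_background = 1000L, n_shared = 3L,
                             shared_sd = 1, field_amplitude = 3,
                             noise_sd = 1, seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 2L), p >= 2L,
            n_background >= 2L, n_shared >= 0L, field_amplitude >= 0,
            noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape), p = as.integer(p),
                 n_background = as.integer(n_background),
                 n_shared = as.integer(n_shared), shared_sd = shared_sd,
                 field_amplitude = field_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spatial_scenario")
}

#' Generate a spatial target / non-spatial background dataset
#'
#' Target rows are `field(s) * u* + sum_j z_ij w_j + noise` at each grid
#' location `s`; background rows carry the shared modes and noise but no
#' field term. The planted loading `u*` is a unit vector supported on a
#' random subset of features; the field is a one-period sinusoid along the
#' grid's long axis, standardized to mean 0 and unit SD over spots.
#'
#' @param scenario A `spatial_scenario`.
#' @return List with `target` (matrix, spots x features), `coords`
#'   (`spatial_coordinates`), `background` (matrix), and `truth` (list with
#'   `u_star`, `field`, `shared_loadings`).
#' @export
make_spatial_dataset <- function(scenario = spatial_scenario()) {
  stopifnot(inherits(scenario, "spatial_scenario"))
  sc <- scenario
  rng <- local_rng(sc$seed)
  on.exit(rng(), add = TRUE)

  rows <- sc$grid_shape[1]; cols <- sc$grid_shape[2]
  pts <- as.matrix(expand.grid(x = seq_len(cols), y = seq_len(rows)))
  n <- nrow(pts)
  long <- if (cols >= rows) pts[, 1] else pts[, 2]
  field <- sin(2 * pi * (long - min(long)) / (max(long) - min(long) + 1L))
  field <- (field - mean(field)) / stats::sd(field)

  support <- sample.int(sc$p, max(2L, round(sc$p / 3)))
  u_star <- numeric(sc$p)
  u_star[support] <- stats::rnorm(length(support))
  u_star <- u_star / sqrt(sum(u_star^2))

  Wsh <- matrix(stats::rnorm(sc$p * sc$n_shared), sc$p, sc$n_shared)
  if (sc$n_shared > 0) {
    Wsh <- qr.Q(qr(Wsh))  # orthonormal shared loadings
  }

  shared_part <- function(nobs) {
    if (sc$n_shared == 0) return(matrix(0, nobs, sc$p))
    Z <- matrix(stats::rnorm(nobs * sc$n_shared, sd = sc$shared_sd),
                nobs, sc$n_shared)
    Z %*% t(Wsh)
  }
  target <- sc$field_amplitude * field %o% u_star + shared_part(n) +
    matrix(stats::rnorm(n * sc$p, sd = sc$noise_sd), n, sc$p)
  background <- shared_part(sc$n_background) +
    matrix(stats::rnorm(sc$n_background * sc$p, sd = sc$noise_sd),
           sc$n_background, sc$p)
  ids <- sprintf("spot%03d", seq_len(n))
  rownames(target) <- ids
  colnames(target) <- colnames(background) <- sprintf("g%03d", seq_len(sc$p))
  rownames(background) <- sprintf("bg%03d", seq_len(sc$n_background))
  rownames(pts) <- ids
  list(target = target,
       coords = spatial_coordinates(pts, obs_ids = ids),
       background = background,
       truth = list(u_star = u_star, field = field, shared_loadings = Wsh))
}

#' Functional scenario parameters
#'
#' Defaults emulate a two-dose longitudinal design: 50 curves per group over
#' a 14-day domain sampled at days 0-9 and 14 (11 points), a cubic B-spline
#' basis with 5 functions, two shared modes of variation drawn at unit score
#' standard deviation in both groups, isotropic curve-level noise at unit
#' projection SD in every direction of function space, and one planted mode
#' drawn at score standard deviation `target_extra_sd` (default 3, i.e. a
#' signal-to-noise ratio of 3 over the unit background variation) in the
#' target only. Measurement noise is Gaussian with SD 0.3.
#'
#' @param n_target,n_background Curves per group.
#' @param D Basis size.
#' @param domain Time domain.
#' @param time_points Measurement times within the domain.
#' @param n_shared Number of shared modes.
#' @param shared_sd Score SD of shared modes (both groups).
#' @param target_extra_sd Score SD of the planted mode in the target group.
#' @param background_sd Score SD of the planted mode in the background
#'   group (default 0: the planted mode is target-only).
#' @param iso_sd SD of isotropic curve-level variation present in both
#'   groups: every direction of function space receives this projection
#'   variance (coefficient covariance `iso_sd^2 * G^-1`), so the background
#'   covariance operator is strictly positive definite, as the method
#'   requires.
#' @param measurement_noise_sd SD of i.i.d. measurement noise.
#' @param jitter_times If `TRUE`, each sample's interior time points are
#'   uniformly jittered by up to a quarter of the smallest gap.
#' @param seed Integer seed.
#' @return A `functional_scenario` parameter list.
#' @export
functional_scenario <- function(n_target = 50L, n_background = 50L, D = 5L,
                                domain = c(0, 14),
                                time_points = c(0:9, 14), n_shared = 2L,
                                shared_sd = 1, target_extra_sd = 3,
                                background_sd = 0, iso_sd = 1,
                                measurement_noise_sd = 0.3,
                                jitter_times = FALSE, seed = 1L) {
  stopifnot(n_target >= 2L, n_background >= 2L, D >= 1L,
            all(time_points >= domain[1]), all(time_points <= domain[2]),
            target_extra_sd >= 0, background_sd >= 0, iso_sd >= 0,
            measurement_noise_sd >= 0)
  structure(list(n_target = as.integer(n_target),
                 n_background = as.integer(n_background), D = as.integer(D),
                 domain = as.numeric(domain),
                 time_points = as.numeric(time_points),
                 n_shared = as.integer(n_shared), shared_sd = shared_sd,
                 target_extra_sd = target_extra_sd,
                 background_sd = background_sd, iso_sd = iso_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 jitter_times = isTRUE(jitter_times),
                 seed = as.integer(seed)),
            class = "functional_scenario")
}

#' Generate two groups of curves with a planted contrastive mode
#'
#' Every curve is `group mean + sum_j z_ij mode_j(t)` built in coefficient
#' space of a shared B-spline basis; modes are random unit-G-norm functions
#' orthogonalized in the G inner product so planted variances are exact.
#' Measurements are curve values at the scenario's time points plus Gaussian
#' noise.
#'
#' @param scenario A `functional_scenario`.
#' @return List with `target` and `background` (each a list of `times`,
#'   `values`, `coefficients`), `basis`, and `truth` (planted mode
#'   coefficients `v_star`, shared mode coefficients, and all drawn scores).
#' @export
make_functional_dataset <- function(scenario = functional_scenario()) {
  stopifnot(inherits(scenario, "functional_scenario"))
  sc <- scenario
  rng <- local_rng(sc$seed)
  on.exit(rng(), add = TRUE)

  basis <- make_basis("bspline", D = sc$D, domain = sc$domain)
  G <- basis$gram
  # random modes, G-orthonormalized (Gram-Schmidt in the G inner product)
  nmodes <- sc$n_shared + 1L
  M <- matrix(stats::rnorm(sc$D * nmodes), sc$D, nmodes)
  for (j in seq_len(nmodes)) {
    if (j > 1L) {
      prev <- M[, seq_len(j - 1L), drop = FALSE]
      M[, j] <- M[, j] - prev %*% crossprod(prev, G %*% M[, j])
    }
    M[, j] <- M[, j] / sqrt(drop(crossprod(M[, j], G %*% M[, j])))
  }
  v_star <- M[, nmodes]
  shared <- M[, seq_len(sc$n_shared), drop = FALSE]
  mu <- stats::rnorm(sc$D, sd = 0.5)
  Gh_inv <- solve(sqrt_psd(G))  # maps N(0, I) scores to isotropic-in-L2 noise

  draw_group <- function(nobs, planted_sd, prefix) {
    Zs <- matrix(stats::rnorm(nobs * sc$n_shared, sd = sc$shared_sd),
                 nobs, sc$n_shared)
    zp <- stats::rnorm(nobs, sd = planted_sd)
    A <- matrix(mu, nobs, sc$D, byrow = TRUE) + Zs %*% t(shared) +
      zp %o% v_star +
      matrix(stats::rnorm(nobs * sc$D, sd = sc$iso_sd), nobs, sc$D) %*% Gh_inv
    times <- values <- vector("list", nobs)
    for (i in seq_len(nobs)) {
      ti <- sc$time_points
      if (sc$jitter_times && length(ti) > 2L) {
        gap <- min(diff(sort(ti)))
        mid <- seq(2L, length(ti) - 1L)
        ti[mid] <- ti[mid] + stats::runif(length(mid), -gap / 4, gap / 4)
      }
      times[[i]] <- ti
      values[[i]] <- drop(basis$eval(ti) %*% A[i, ]) +
        stats::rnorm(length(ti), sd = sc$measurement_noise_sd)
    }
    names(times) <- names(values) <- sprintf("%s%03d", prefix, seq_len(nobs))
    list(times = times, values = values, coefficients = A,
         shared_scores = Zs, planted_scores = zp)
  }
  tg <- draw_group(sc$n_target, sc$target_extra_sd, "t")
  bg <- draw_group(sc$n_background, sc$background_sd, "b")
  list(target = tg, background = bg, basis = basis,
       truth = list(v_star = v_star, shared_modes = shared,
                    mean_coefficients = mu,
                    planted_scores_target = tg$planted_scores,
                    planted_scores_background = bg$planted_scores))
}

# Run code under a local RNG state: seeds deterministically, and the
# returned function restores the caller's RNG when called (use with
# on.exit). Avoids any dependence on or disturbance of global random state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
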