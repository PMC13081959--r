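# Count-matrix filters and normalizations: observation/feature QC for
# spot- or bin-level spatial counts, depth normalization with log transform,
# DESeq-style median-of-ratios size factors for bulk counts, and per-sample
# day-0 scaling for longitudinal trajectories.

#' Construct a count matrix container
#'
#' @param counts Nonnegative matrix (dense or sparse `Matrix`), observations
#'   in rows, features in columns.
#' @param feature_ids,obs_ids Optional identifiers (default dimnames).
#' @param mito_prefix Feature-id prefix marking mitochondrial features
#'   (default `"MT-"`), used by the mitochondrial-fraction filter.
#' @param mito_mask Optional logical per-feature mask overriding the prefix
#'   rule.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, feature_ids = NULL, obs_ids = NULL,
                         mito_prefix = "MT-", mito_mask = NULL) {
  if (!inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (min(counts) < 0) stop("count_matrix: counts must be nonnegative")
  feature_ids <- as.character(feature_ids %||% colnames(counts) %||%
                                paste0("g", seq_len(ncol(counts))))
  obs_ids <- as.character(obs_ids %||% rownames(counts) %||%
                            paste0("obs", seq_len(nrow(counts))))
  stopifnot(length(feature_ids) == ncol(counts),
            length(obs_ids) == nrow(counts))
  if (is.null(mito_mask)) {
    mito_mask <- startsWith(feature_ids, mito_prefix)
  }
  stopifnot(length(mito_mask) == ncol(counts))
  structure(list(counts = counts, feature_ids = feature_ids,
                 obs_ids = obs_ids, mito_mask = mito_mask),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d observations x %d features (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_mask)))
  invisible(x)
}

#' Filter observations and features of a count matrix
#'
#' Observation filters run first: observations with total counts below
#' `min_obs_counts`, above `max_obs_counts`, or with a mitochondrial count
#' fraction above `max_mito_frac` are removed (all strict inequalities).
#' Features expressed (count > 0) in fewer than `min_feature_obs` of the
#' surviving observations are then removed.
#'
#' @param M A `count_matrix`.
#' @param min_obs_counts Remove observations with total < this.
#' @param max_obs_counts Optional; remove observations with total > this.
#' @param min_feature_obs Remove features expressed in fewer than this many
#'   surviving observations.
#' @param max_mito_frac Optional; remove observations whose mitochondrial
#'   fraction exceeds this.
#' @return List with `matrix` (filtered `count_matrix`) and `report` (counts
#'   removed per rule).
#' @export
filter_counts <- function(M, min_obs_counts = 0, max_obs_counts = NULL,
                          min_feature_obs = 0, max_mito_frac = NULL) {
  stopifnot(inherits(M, "count_matrix"))
  totals <- Matrix::rowSums(M$counts)
  drop_low <- totals < min_obs_counts
  drop_high <- if (!is.null(max_obs_counts)) totals > max_obs_counts
               else rep(FALSE, length(totals))
  drop_mito <- rep(FALSE, length(totals))
  if (!is.null(max_mito_frac) && any(M$mito_mask)) {
    mt <- Matrix::rowSums(M$counts[, M$mito_mask, drop = FALSE])
    drop_mito <- mt / pmax(totals, 1) > max_mito_frac
  }
  keep_obs <- !(drop_low | drop_high | drop_mito)
  if (!any(keep_obs)) stop("filter_counts: all observations removed")
  sub <- M$counts[keep_obs, , drop = FALSE]
  expressed <- Matrix::colSums(sub > 0)
  keep_feat <- expressed >= min_feature_obs
  out <- count_matrix(sub[, keep_feat, drop = FALSE],
                      feature_ids = M$feature_ids[keep_feat],
                      obs_ids = M$obs_ids[keep_obs],
                      mito_mask = M$mito_mask[keep_feat])
  list(matrix = out,
       report = data.frame(
         rule = c("obs_min_counts", "obs_max_counts", "obs_mito_frac",
                  "feature_min_obs"),
         removed = c(sum(drop_low), sum(drop_high), sum(drop_mito),
                     sum(!keep_feat))))
}

#' Depth-normalize and log-transform counts
#'
#' `log(1 + scale * count / observation_total)` per entry; invariant to
#' per-observation sequencing depth.
#'
#' @param M A `count_matrix` or bare count matrix.
#' @param scale Scale factor (default `1e4`).
#' @return Dense numeric matrix of normalized values with ids as dimnames.
#' @export
depth_normalize_log <- function(M, scale = 1e4) {
  cm <- if (inherits(M, "count_matrix")) M else count_matrix(M)
  totals <- Matrix::rowSums(cm$counts)
  if (any(totals <= 0)) {
    stop("depth_normalize_log: zero-total observation(s): ",
         paste(utils::head(cm$obs_ids[totals <= 0], 5), collapse = ", "))
  }
  V <- log1p(scale * as.matrix(cm$counts) / totals)
  dimnames(V) <- list(cm$obs_ids, cm$feature_ids)
  V
}

#' Median-of-ratios size factors
#'
#' DESeq-style depth normalization for bulk counts: the per-feature
#' reference is the geometric mean over observations (features with any zero
#' count are excluded from the reference set), and each observation's size
#' factor is the median over reference features of `count / reference`.
#'
#' @param M A `count_matrix` or bare matrix (observations x features).
#' @return Numeric vector of per-observation size factors (named by obs id).
#' @export
median_of_ratios_size_factors <- function(M) {
  cm <- if (inherits(M, "count_matrix")) M else count_matrix(M)
  X <- as.matrix(cm$counts)
  all_pos <- apply(X, 2L, function(col) all(col > 0))
  if (!any(all_pos)) {
    stop("median_of_ratios_size_factors: no feature has nonzero counts in ",
         "every observation; consider a pseudocount")
  }
  Xp <- X[, all_pos, drop = FALSE]
  log_ref <- colMeans(log(Xp))
  sf <- apply(Xp, 1L, function(row) exp(stats::median(log(row) - log_ref)))
  names(sf) <- cm$obs_ids
  sf
}

#' Normalize counts by size factors
#'
#' @param M A `count_matrix` or bare matrix.
#' @param size_factors Per-observation factors
#'   (default [median_of_ratios_size_factors()]).
#' @return Dense matrix of `counts / size_factor` with ids as dimnames.
#' @export
normalize_by_size_factors <- function(M, size_factors = NULL) {
  cm <- if (inherits(M, "count_matrix")) M else count_matrix(M)
  if (is.null(size_factors)) size_factors <- median_of_ratios_size_factors(cm)
  V <- as.matrix(cm$counts) / size_factors
  dimnames(V) <- list(cm$obs_ids, cm$feature_ids)
  V
}

#' Scale trajectories by their pre-dose (time-zero) value
#'
#' Each trajectory is divided by its own value at `t = 0`, so every curve
#' starts at 1 and later values are fold changes from baseline. Trajectories
#' with a missing or zero time-zero value cannot be scaled and are excluded
#' with a reason.
#'
#' @param times,values Lists of per-sample time and value vectors.
#' @param sample_ids Optional identifiers.
#' @return List with `times`, `values` (normalized, excluded samples
#'   removed), `sample_ids`, and `excluded` (data frame of drops).
#' @export
day0_normalize <- function(times, values, sample_ids = NULL) {
  stopifnot(is.list(times), is.list(values), length(times) == length(values))
  n <- length(times)
  sample_ids <- as.character(sample_ids %||% names(times) %||%
                               paste0("s", seq_len(n)))
  keep <- rep(TRUE, n)
  why <- character(n)
  out_values <- values
  for (i in seq_len(n)) {
    i0 <- which(times[[i]] == 0)
    if (length(i0) != 1L) {
      keep[i] <- FALSE
      why[i] <- "no unique t = 0 measurement"
    } else if (values[[i]][i0] == 0) {
      keep[i] <- FALSE
      why[i] <- "zero value at t = 0"
    } else {
      out_values[[i]] <- values[[i]] / values[[i]][i0]
    }
  }
  list(times = times[keep], values = out_values[keep],
       sample_ids = sample_ids[keep],
       excluded = data.frame(sample_id = sample_ids[!keep],
                             reason = why[!keep], stringsAsFactors = FALSE))
}

#' Select highly variable features from a background dataset
#'
#' Ranks features by the variance of their depth-normalized log values and
#' returns the top `n_top` feature ids; target and background are then both
#' subset to this list before the contrastive decomposition.
#'
#' @param background A `count_matrix` of background counts, or an
#'   already-normalized value matrix (`normalized = TRUE`).
#' @param n_top Number of features to keep.
#' @param normalized Set `TRUE` if `background` already holds normalized
#'   values.
#' @return Character vector of `n_top` feature ids, most variable first.
#' @export
select_hvg <- function(background, n_top, normalized = FALSE) {
  V <- if (normalized) as.matrix(background)
       else depth_normalize_log(background)
  if (n_top > ncol(V)) {
    stop("select_hvg: n_top = ", n_top, " exceeds feature count ", ncol(V))
  }
  vars <- apply(V, 2L, stats::var)
  ids <- colnames(V) %||% paste0("g", seq_len(ncol(V)))
  ids[order(vars, decreasing = TRUE)][seq_len(n_top)]
}
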