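# Readers and writers for the formats the pipelines touch: Matrix Market
# triplet directories (CellRanger dialect: matrix.mtx features x
# observations, features.tsv, barcodes.tsv), dense delimited matrices with
# an id column, coordinate tables, and long-format curve tables.

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else " "
}

#' Read an expression matrix
#'
#' Two dialects: `mtx_triplet` expects a directory with `matrix.mtx`
#' (features x observations, transposed on read), `features.tsv` and
#' `barcodes.tsv`; `dense_delimited` expects a delimited text file with a
#' header row of feature ids and a first column of observation ids
#' (separator sniffed among tab/comma/space). The result is always
#' observations x features.
#'
#' @param path Directory (`mtx_triplet`) or file (`dense_delimited`).
#' @param dialect `"mtx_triplet"` or `"dense_delimited"`.
#' @return A `count_matrix` (values may be non-integer for normalized
#'   input).
#' @export
read_expression <- function(path, dialect = c("mtx_triplet",
                                              "dense_delimited")) {
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    feats <- file.path(path, "features.tsv")
    bcs <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feats, bcs)) {
      if (!file.exists(f)) stop("read_expression: missing file ", f)
    }
    M <- Matrix::t(Matrix::readMM(mtx))  # to observations x features
    feature_ids <- utils::read.delim(feats, header = FALSE,
                                     stringsAsFactors = FALSE)[[1]]
    obs_ids <- utils::read.delim(bcs, header = FALSE,
                                 stringsAsFactors = FALSE)[[1]]
    if (length(feature_ids) != ncol(M)) {
      stop("read_expression: features.tsv has ", length(feature_ids),
           " rows but matrix.mtx declares ", ncol(M), " features")
    }
    if (length(obs_ids) != nrow(M)) {
      stop("read_expression: barcodes.tsv has ", length(obs_ids),
           " rows but matrix.mtx declares ", nrow(M), " observations")
    }
    count_matrix(M, feature_ids = feature_ids, obs_ids = obs_ids)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                            check.names = FALSE, stringsAsFactors = FALSE)
    obs_ids <- as.character(df[[1]])
    V <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(V)) stop("read_expression: non-numeric values in ", path)
    count_matrix(V, feature_ids = colnames(df)[-1], obs_ids = obs_ids)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: either a Matrix Market triplet directory
#' (matrix stored features x observations) or a dense delimited file.
#'
#' @param M A `count_matrix`, or a bare matrix.
#' @param path Output directory (`mtx_triplet`) or file
#'   (`dense_delimited`).
#' @param dialect Output dialect.
#' @export
write_expression <- function(M, path, dialect = c("mtx_triplet",
                                                  "dense_delimited")) {
  dialect <- match.arg(dialect)
  cm <- if (inherits(M, "count_matrix")) M else count_matrix(M)
  if (dialect == "mtx_triplet") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    sp <- methods::as(methods::as(Matrix::Matrix(Matrix::t(cm$counts),
                                                 sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(cm$feature_ids, file.path(path, "features.tsv"))
    writeLines(cm$obs_ids, file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(id = cm$obs_ids, as.matrix(cm$counts),
                     check.names = FALSE)
    colnames(df) <- c("id", cm$feature_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a spatial coordinates table
#'
#' Expects a delimited file with columns `id`, `x`, `y` (further coordinate
#' columns allowed). When `obs_ids` is given, rows are aligned to that order
#' by id, so on-disk row order never matters downstream.
#'
#' @param path Delimited file.
#' @param obs_ids Optional observation ids (e.g. from the expression matrix)
#'   to align to.
#' @return A `spatial_coordinates` object.
#' @export
read_coords <- function(path, obs_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("read_coords: need columns id, x, y in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("read_coords: duplicate ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  pts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.null(obs_ids)) {
    idx <- match(obs_ids, ids)
    if (anyNA(idx)) {
      stop("read_coords: ids missing from coordinate table: ",
           paste(utils::head(obs_ids[is.na(idx)], 5), collapse = ", "))
    }
    pts <- pts[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  rownames(pts) <- NULL
  spatial_coordinates(pts, obs_ids = ids)
}

#' Write a coordinates table
#' @param coords A `spatial_coordinates` object.
#' @param path Output file (tab separated).
#' @export
write_coords <- function(coords, path) {
  stopifnot(inherits(coords, "spatial_coordinates"))
  df <- data.frame(id = coords$obs_ids, coords$points, check.names = FALSE)
  colnames(df) <- c("id", c("x", "y", "z")[seq_len(ncol(coords$points))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format functional measurements
#'
#' Expects columns `sample_id`, `group`, `time`, `value`. Times are sorted
#' ascending within each sample; irregular grids are preserved, nothing is
#' imputed. Exactly two group labels must be present and are designated
#' target/background by the caller.
#'
#' @param path Delimited file.
#' @param target_group,background_group The group labels to treat as target
#'   and background; defaults take the two labels in first-appearance order.
#' @return List with `target` and `background`, each holding `times`,
#'   `values` (named lists per sample), and `group` (the original label).
#' @export
read_long_functional <- function(path, target_group = NULL,
                                 background_group = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "time", "value")
  if (!all(need %in% colnames(df))) {
    stop("read_long_functional: need columns ",
         paste(need, collapse = ", "), " in ", path)
  }
  labs <- unique(df$group)
  if (length(labs) != 2L) {
    stop("read_long_functional: expected exactly 2 group labels, found ",
         length(labs), " (", paste(labs, collapse = ", "), ")")
  }
  target_group <- target_group %||% labs[1]
  background_group <- background_group %||% setdiff(labs, target_group)
  if (!all(c(target_group, background_group) %in% labs)) {
    stop("read_long_functional: group label(s) not present in file: ",
         paste(setdiff(c(target_group, background_group), labs),
               collapse = ", "))
  }
  dup <- duplicated(df[, c("sample_id", "time")])
  if (any(dup)) {
    stop("read_long_functional: duplicate (sample_id, time) rows, e.g. ",
         df$sample_id[dup][1], " at t = ", df$time[dup][1])
  }
  one_group <- function(lab) {
    sub <- df[df$group == lab, , drop = FALSE]
    sp <- split(sub, sub$sample_id)
    times <- lapply(sp, function(d) sort(d$time))
    values <- lapply(sp, function(d) d$value[order(d$time)])
    list(times = times, values = values, group = lab)
  }
  list(target = one_group(target_group),
       background = one_group(background_group))
}

#' Write functional measurements in long format
#'
#' @param target,background Lists with `times` and `values` (named lists per
#'   sample), as produced by [make_functional_dataset()].
#' @param path Output file (tab separated).
#' @param target_label,background_label Group labels to write.
#' @export
write_long_functional <- function(target, background, path,
                                  target_label = "target",
                                  background_label = "background") {
  one <- function(g, lab) {
    do.call(rbind, lapply(names(g$times), function(id) {
      data.frame(sample_id = id, group = lab, time = g$times[[id]],
                 value = g$values[[id]], stringsAsFactors = FALSE)
    }))
  }
  df <- rbind(one(target, target_label), one(background, background_label))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
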