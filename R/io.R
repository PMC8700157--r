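# Readers and writers for on-disk artifacts.  Everything is delimited text
# (CSV by default, TSV via `sep`): the problems are modest in size and
# inspectability wins over binary formats.

read_delim_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, row.names = NULL)
  df
}

#' Read a multi-class dataset from delimited text
#'
#' Either a single long table with a class-label column (`class_column`), or
#' one file per class (a character vector of paths, optionally named by class
#' label).  All remaining columns must be numeric features with a header row.
#'
#' @param path one path (long table) or a vector of per-class paths.
#' @param class_column name of the label column in the long-table layout.
#' @param sep field separator.
#' @return a `"jgl_data"` object.
#' @export
read_dataset <- function(path, class_column = NULL, sep = ",") {
  check_numeric <- function(df, file) {
    for (j in seq_along(df)) {
      v <- df[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
        stop(sprintf("non-numeric value in %s, column '%s', row %d",
                     file, names(df)[j], ifelse(is.na(bad), 1L, bad)))
      }
      if (anyNA(v))
        stop(sprintf("missing value in %s, column '%s', row %d",
                     file, names(df)[j], which(is.na(v))[1]))
    }
    as.matrix(df)
  }
  if (length(path) == 1L && !is.null(class_column)) {
    df <- read_delim_matrix(path, sep)
    if (!class_column %in% names(df))
      stop("class column '", class_column, "' not found in ", path)
    labels <- as.character(df[[class_column]])
    df <- df[setdiff(names(df), class_column)]
    x <- lapply(split(seq_along(labels), labels), function(i)
      check_numeric(df[i, , drop = FALSE], path))
    multiclass_dataset(x, class_labels = names(x))
  } else {
    labs <- names(path)
    if (is.null(labs)) labs <- paste0("class", seq_along(path))
    x <- lapply(path, function(pt) check_numeric(read_delim_matrix(pt, sep), pt))
    multiclass_dataset(x, class_labels = labs)
  }
}

#' Read precomputed covariance matrices
#'
#' One square delimited matrix file per class plus explicit sample counts.
#'
#' @param paths character vector of K file paths.
#' @param n per-class sample counts.
#' @param sep field separator.
#' @return a `"jgl_cov"` object.
#' @export
read_covariances <- function(paths, n, sep = ",") {
  S <- lapply(paths, function(pt) {
    m <- as.matrix(read_delim_matrix(pt, sep))
    rownames(m) <- colnames(m)
    m
  })
  covariance_set(S, n, class_labels = names(paths))
}

#' Write a precision set as delimited matrix files
#'
#' Writes one square matrix file per class (full double precision) plus a
#' `manifest.csv` listing the files and class sample order.
#'
#' @param theta list of K matrices or a `"jgl_fit"`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param sep field separator.
#' @return invisibly, the written file paths.
#' @export
write_precision_set <- function(theta, dir, prefix = "theta", sep = ",") {
  if (inherits(theta, "jgl_fit")) theta <- theta$theta
  theta <- as_theta_list(theta)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- names(theta)
  if (is.null(labs)) labs <- paste0("class", seq_along(theta))
  files <- character(length(theta))
  for (k in seq_along(theta)) {
    files[k] <- file.path(dir, sprintf("%s_%s.csv", prefix, labs[k]))
    m <- theta[[k]]
    df <- as.data.frame(m, check.names = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                       files[k], sep = sep, row.names = FALSE, quote = TRUE)
  }
  manifest <- data.frame(class = labs, file = basename(files))
  utils::write.table(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                     sep = sep, row.names = FALSE, quote = TRUE)
  invisible(files)
}

#' Read a precision set written by [write_precision_set()]
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used when writing.
#' @param sep field separator.
#' @return list of K matrices, named by class.
#' @export
read_precision_set <- function(dir, prefix = "theta", sep = ",") {
  manifest <- utils::read.table(file.path(dir, paste0(prefix, "_manifest.csv")),
                                header = TRUE, sep = sep)
  out <- lapply(seq_len(nrow(manifest)), function(k) {
    m <- as.matrix(read_delim_matrix(file.path(dir, manifest$file[k]), sep))
    rownames(m) <- colnames(m)
    m
  })
  names(out) <- manifest$class
  out
}

#' Edge list of a precision set
#'
#' Rows `(class, feature_i, feature_j, value)` for off-diagonal pairs i < j
#' with `|value| > zero_tol`, plus a `shared` flag marking edges whose
#' support is present in every class (the common-structure/class-specific
#' distinction used when visualizing joint networks).
#'
#' @param theta list of K matrices or a `"jgl_fit"`.
#' @param zero_tol selection threshold.
#' @return data frame with columns `class`, `feature_i`, `feature_j`,
#'   `value`, `shared`.
#' @export
edge_list <- function(theta, zero_tol = 1e-6) {
  if (inherits(theta, "jgl_fit")) theta <- theta$theta
  theta <- as_theta_list(theta)
  K <- length(theta)
  p <- nrow(theta[[1]])
  feat <- colnames(theta[[1]])
  if (is.null(feat)) feat <- paste0("V", seq_len(p))
  labs <- names(theta)
  if (is.null(labs)) labs <- paste0("class", seq_len(K))
  ut <- which(upper.tri(matrix(0, p, p)))
  sel <- lapply(theta, function(m) abs(m[ut]) > zero_tol)
  shared_cells <- Reduce(`&`, sel)
  ri <- row(matrix(0, p, p))[ut]; ci <- col(matrix(0, p, p))[ut]
  rows <- lapply(seq_len(K), function(k) {
    idx <- which(sel[[k]])
    if (!length(idx)) return(NULL)
    data.frame(class = labs[k], feature_i = feat[ri[idx]],
               feature_j = feat[ci[idx]], value = theta[[k]][ut][idx],
               shared = shared_cells[idx])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = character(), feature_i = character(),
                      feature_j = character(), value = numeric(),
                      shared = logical())
  rownames(out) <- NULL
  out
}

#' Write the edge list as delimited text
#'
#' @inheritParams edge_list
#' @param path output file.
#' @param sep field separator.
#' @return invisibly, the edge-list data frame.
#' @export
write_edge_list <- function(theta, path, zero_tol = 1e-6, sep = ",") {
  el <- edge_list(theta, zero_tol)
  utils::write.table(el, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(el)
}

#' Write a solver trace
#'
#' One row per iteration: iteration number, objective, step size, damping
#' factor, backtrack count, relative change and fixed-point residual.
#'
#' @param fit a `"jgl_fit"`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_trace <- function(fit, path, sep = ",") {
  utils::write.table(fit$trace, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(fit$trace)
}
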