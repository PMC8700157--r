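# Problem construction: multi-class data, per-class covariances, the smooth
# log-likelihood term f, its gradient, the composite penalty g, and F = f + g.

#' Multi-class dataset
#'
#' Bundles one numeric sample matrix per class (rows are observations,
#' columns are the p shared features).
#'
#' @param x list of K numeric matrices, each n_k x p, or a single matrix
#'   (taken as K = 1).  All matrices must share the same number of columns.
#' @param class_labels optional character vector of K class identifiers;
#'   defaults to the list names or `"class1"`, ... .
#' @return object of class `"jgl_data"` with elements `x` (list of matrices),
#'   `class_labels`, `K`, `p`, `n` (per-class sample counts) and `N`.
#' @examples
#' d <- multiclass_dataset(list(case = matrix(rnorm(20), 5), ctrl = matrix(rnorm(20), 5)))
#' d$K; d$n
#' @export
multiclass_dataset <- function(x, class_labels = NULL) {
  if (is.matrix(x) || is.data.frame(x)) x <- list(x)
  if (!is.list(x) || length(x) < 1L) stop("'x' must be a non-empty list of matrices")
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("missing values are not supported")
    m
  })
  p <- unique(vapply(x, ncol, integer(1)))
  if (length(p) != 1L) stop("all classes must have the same number of features")
  n <- vapply(x, nrow, integer(1))
  if (any(n < 1L)) stop("every class needs at least one sample")
  if (is.null(class_labels)) class_labels <- names(x)
  if (is.null(class_labels) || any(!nzchar(class_labels)))
    class_labels <- paste0("class", seq_along(x))
  feat <- colnames(x[[1]])
  if (is.null(feat)) feat <- paste0("V", seq_len(p))
  x <- lapply(x, function(m) { colnames(m) <- feat; m })
  names(x) <- class_labels
  structure(list(x = x, class_labels = class_labels, feature_names = feat,
                 K = length(x), p = p, n = n, N = sum(n)),
            class = "jgl_data")
}

#' @export
print.jgl_data <- function(x, ...) {
  cat("Multi-class dataset: K =", x$K, "classes, p =", x$p, "features\n")
  cat("  samples per class:", paste(sprintf("%s=%d", x$class_labels, x$n),
                                    collapse = ", "), "\n")
  invisible(x)
}

sym <- function(m) (m + t(m)) / 2

#' Per-class empirical covariance matrices
#'
#' Computes S(k) = (1/n_k) * sum of x_i' x_i over the samples of class k,
#' optionally after centering each column within the class.  The Gaussian
#' model behind the joint graphical lasso assumes mean zero; centering makes
#' real data conform to that assumption, while `center = FALSE` applies the
#' second-moment formula to the data as given.
#'
#' @param dataset a [multiclass_dataset()] object.
#' @param center logical; column-center each class before forming S(k)
#'   (default `TRUE`).
#' @return object of class `"jgl_cov"`: list with `S` (list of K symmetric
#'   p x p matrices), `n`, `N`, `p`, `K`, `class_labels`, `feature_names`.
#' @examples
#' d <- multiclass_dataset(list(matrix(rnorm(30), 10)))
#' cov <- class_covariances(d)
#' @export
class_covariances <- function(dataset, center = TRUE) {
  stopifnot(inherits(dataset, "jgl_data"))
  S <- lapply(dataset$x, function(m) {
    if (center) m <- scale(m, center = TRUE, scale = FALSE)
    s <- sym(crossprod(m) / nrow(m))
    dimnames(s) <- list(dataset$feature_names, dataset$feature_names)
    s
  })
  covariance_set(S, dataset$n, class_labels = dataset$class_labels)
}

#' Covariance set from precomputed matrices
#'
#' Wraps K precomputed covariance matrices and their class sample sizes into
#' the container the solvers consume.
#'
#' @param S list of K symmetric p x p matrices (or one matrix for K = 1).
#' @param n integer vector of per-class sample counts n_k (the likelihood
#'   weights).
#' @param class_labels optional class identifiers.
#' @return object of class `"jgl_cov"`.
#' @export
covariance_set <- function(S, n, class_labels = NULL) {
  if (is.matrix(S)) S <- list(S)
  K <- length(S)
  if (length(n) != K) stop("'n' must give one sample count per class")
  if (any(n < 1)) stop("sample counts must be positive")
  p <- unique(vapply(S, nrow, integer(1)))
  if (length(p) != 1L || any(vapply(S, ncol, integer(1)) != p))
    stop("all covariance matrices must be square with a common dimension")
  for (k in seq_len(K)) {
    if (max(abs(S[[k]] - t(S[[k]]))) > 1e-8 * max(1, max(abs(S[[k]]))))
      stop("covariance matrix ", k, " is not symmetric")
    S[[k]] <- sym(S[[k]])
    if (any(diag(S[[k]]) < 0)) stop("negative diagonal in covariance matrix ", k)
  }
  if (is.null(class_labels)) class_labels <- names(S)
  if (is.null(class_labels)) class_labels <- paste0("class", seq_len(K))
  feat <- colnames(S[[1]])
  if (is.null(feat)) feat <- paste0("V", seq_len(p))
  structure(list(S = S, n = as.numeric(n), N = sum(n), p = p, K = K,
                 class_labels = class_labels, feature_names = feat),
            class = "jgl_cov")
}

#' @export
print.jgl_cov <- function(x, ...) {
  cat("Covariance set: K =", x$K, ", p =", x$p, ", n =",
      paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Penalty specification
#'
#' The composite penalty g of the joint graphical lasso:
#' an off-diagonal l1 term with level `lambda1` plus a cross-class coupling
#' term with level `lambda2` -- either the fused penalty (pairwise absolute
#' differences between classes, over all cells including the diagonal) or the
#' group penalty (per-cell Euclidean norm across classes, off-diagonal only).
#'
#' @param family `"fused"` or `"group"`.
#' @param lambda1 nonnegative sparsity level.
#' @param lambda2 nonnegative coupling level.
#' @return object of class `"jgl_penalty"`.
#' @examples
#' penalty_spec("fused", 0.1, 0.05)
#' @export
penalty_spec <- function(family = c("fused", "group"), lambda1, lambda2) {
  family <- match.arg(family)
  if (lambda1 < 0 || lambda2 < 0) stop("penalty levels must be nonnegative")
  structure(list(family = family, lambda1 = lambda1, lambda2 = lambda2),
            class = "jgl_penalty")
}

#' @export
print.jgl_penalty <- function(x, ...) {
  cat(sprintf("%s penalty: lambda1 = %g, lambda2 = %g\n",
              x$family, x$lambda1, x$lambda2))
  invisible(x)
}

as_theta_list <- function(theta) {
  if (is.matrix(theta)) theta <- list(theta)
  theta
}

chol_or_null <- function(m) tryCatch(chol(m), error = function(e) NULL)

#' Is every class matrix positive definite?
#'
#' @param theta list of K symmetric matrices (or one matrix).
#' @return logical; `TRUE` when the Cholesky factorization succeeds for
#'   every class.
#' @export
is_pd <- function(theta) {
  theta <- as_theta_list(theta)
  all(vapply(theta, function(m) !is.null(chol_or_null(m)), logical(1)))
}

# Cholesky factors for every class; NULL if any class is indefinite.
theta_chols <- function(theta) {
  out <- vector("list", length(theta))
  for (k in seq_along(theta)) {
    ch <- chol_or_null(theta[[k]])
    if (is.null(ch)) return(NULL)
    out[[k]] <- ch
  }
  out
}

#' Smooth part of the objective
#'
#' The (weighted, negated) Gaussian log-likelihood
#' f(Theta) = -sum_k n_k { logdet Theta(k) - trace(S(k) Theta(k)) }.
#'
#' @param theta list of K positive-definite precision matrices.
#' @param cov a `"jgl_cov"` object.
#' @return scalar value of f.
#' @export
jgl_neg_loglik <- function(theta, cov) {
  theta <- as_theta_list(theta)
  stopifnot(length(theta) == cov$K)
  ch <- theta_chols(theta)
  if (is.null(ch)) stop("precision matrix is not positive definite")
  val <- 0
  for (k in seq_len(cov$K)) {
    ld <- 2 * sum(log(diag(ch[[k]])))
    val <- val - cov$n[k] * (ld - sum(cov$S[[k]] * theta[[k]]))
  }
  val
}

#' Gradient of the smooth part
#'
#' grad f(Theta)(k) = n_k (S(k) - Theta(k)^{-1}); each block is symmetrized to
#' remove floating-point drift.  Inverses come from the Cholesky factor.
#'
#' @inheritParams jgl_neg_loglik
#' @return list of K symmetric matrices.
#' @export
jgl_gradient <- function(theta, cov) {
  theta <- as_theta_list(theta)
  ch <- theta_chols(theta)
  if (is.null(ch)) stop("precision matrix is not positive definite")
  lapply(seq_len(cov$K), function(k)
    cov$n[k] * sym(cov$S[[k]] - chol2inv(ch[[k]])))
}

#' Penalty value g(Theta)
#'
#' Evaluates the l1 term over off-diagonals plus the fused or group coupling
#' term.  Note the asymmetry inherited from the model definition: the fused
#' coupling sums over all cells (diagonal included) while the l1 term and the
#' group coupling are off-diagonal only.
#'
#' @param theta list of K matrices.
#' @param pen a [penalty_spec()] object.
#' @return nonnegative scalar.
#' @export
jgl_penalty_value <- function(theta, pen) {
  theta <- as_theta_list(theta)
  K <- length(theta)
  p <- nrow(theta[[1]])
  off <- !diag(p)
  l1 <- sum(vapply(theta, function(m) sum(abs(m[off])), numeric(1)))
  val <- pen$lambda1 * l1
  if (pen$lambda2 > 0 && K >= 1) {
    if (pen$family == "fused") {
      if (K >= 2) {
        for (k in seq_len(K - 1)) for (l in (k + 1):K)
          val <- val + pen$lambda2 * sum(abs(theta[[k]] - theta[[l]]))
      }
    } else {
      sq <- Reduce(`+`, lapply(theta, function(m) m^2))
      val <- val + pen$lambda2 * sum(sqrt(sq[off]))
    }
  }
  val
}

#' Full objective F = f + g
#'
#' @inheritParams jgl_neg_loglik
#' @param pen a [penalty_spec()] object.
#' @return scalar objective value.
#' @export
jgl_objective <- function(theta, cov, pen) {
  jgl_neg_loglik(theta, cov) + jgl_penalty_value(theta, pen)
}
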