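# V-fold cross-validation over a (lambda1, lambda2) grid using the
# predictive negative log-likelihood.

#' Predictive negative log-likelihood score
#'
#' `sum_k n_k { trace(S_v(k) Theta_hat(k)) - logdet Theta_hat(k) }`, where
#' `S_v(k)` and `n_k` come from the held-out fold.
#'
#' @param theta_hat positive-definite precision set (list of K matrices or a
#'   `"jgl_fit"`).
#' @param test_cov `"jgl_cov"` of the held-out fold.
#' @return scalar score (smaller is better).
#' @export
cv_score <- function(theta_hat, test_cov) {
  if (inherits(theta_hat, "jgl_fit")) theta_hat <- theta_hat$theta
  theta_hat <- as_theta_list(theta_hat)
  ch <- theta_chols(theta_hat)
  if (is.null(ch)) stop("estimate is not positive definite")
  s <- 0
  for (k in seq_len(test_cov$K)) {
    ld <- 2 * sum(log(diag(ch[[k]])))
    s <- s + test_cov$n[k] * (sum(test_cov$S[[k]] * theta_hat[[k]]) - ld)
  }
  s
}

# Stratified fold ids: within each class, sizes differ by at most one.
fold_assignments <- function(n, V) {
  lapply(n, function(nk) {
    if (nk < V) stop("every class needs at least V samples for V-fold CV")
    sample(rep_len(seq_len(V), nk))
  })
}

#' V-fold cross-validation for penalty selection
#'
#' Splits each class into V folds (stratified, so every class appears in
#' every training set), fits the model on the training folds for every
#' `(lambda1, lambda2)` pair, scores the held-out fold with [cv_score()],
#' and sums the scores over folds.  The selected pair minimizes the summed
#' score.  Fits that fail or do not converge score `+Inf` rather than
#' aborting the grid; fits are warm-started along the grid within each fold.
#'
#' @param dataset a `"jgl_data"` object (or list of class matrices).
#' @param lambda1,lambda2 numeric vectors; the grid is their cross product,
#'   ordered with `lambda1` decreasing.
#' @param V number of folds (default 6).
#' @param penalty `"fused"` or `"group"`.
#' @param solver `"ista"`, `"mista"`, or `"admm"`.
#' @param control a [jgl_control()] object.
#' @param center centering convention, shared by training and test folds.
#' @param seed integer seed controlling the fold split.
#' @param refit fit the full dataset at the selected pair (default `TRUE`).
#' @return object of class `"jgl_cv"`: `table` (a data frame with `lambda1`,
#'   `lambda2`, `score`, `converged`), `best` (the selected pair), `folds`
#'   (per-class fold ids), `V`, `seed`, and `fit` (the refit, if requested).
#' @examples
#' sim <- jgl_simulate(p = 8, K = 2, n = c(60, 60), seed = 3)
#' cvr <- jgl_cv(sim$dataset, lambda1 = c(0.05, 0.2), lambda2 = 0.02,
#'               V = 3, seed = 1, refit = FALSE)
#' cvr$best
#' @export
jgl_cv <- function(dataset, lambda1, lambda2, V = 6L,
                   penalty = c("fused", "group"),
                   solver = c("ista", "mista", "admm"),
                   control = jgl_control(), center = TRUE, seed = NULL,
                   refit = TRUE) {
  penalty <- match.arg(penalty); solver <- match.arg(solver)
  if (!inherits(dataset, "jgl_data")) dataset <- multiclass_dataset(dataset)
  V <- as.integer(V)
  if (V < 2) stop("V must be at least 2")
  fn <- switch(solver, ista = jgl_ista, mista = jgl_mista, admm = jgl_admm)
  folds <- with_seed(seed, fold_assignments(dataset$n, V))
  grid <- expand.grid(lambda2 = sort(unique(lambda2)),
                      lambda1 = sort(unique(lambda1), decreasing = TRUE))
  grid <- grid[, c("lambda1", "lambda2")]
  scores <- matrix(0, nrow(grid), V)
  conv <- matrix(TRUE, nrow(grid), V)
  for (v in seq_len(V)) {
    train <- multiclass_dataset(
      lapply(seq_len(dataset$K), function(k)
        dataset$x[[k]][folds[[k]] != v, , drop = FALSE]),
      class_labels = dataset$class_labels)
    test <- multiclass_dataset(
      lapply(seq_len(dataset$K), function(k)
        dataset$x[[k]][folds[[k]] == v, , drop = FALSE]),
      class_labels = dataset$class_labels)
    cov_tr <- class_covariances(train, center = center)
    cov_te <- class_covariances(test, center = center)
    theta0 <- NULL
    for (g in seq_len(nrow(grid))) {
      pen <- penalty_spec(penalty, grid$lambda1[g], grid$lambda2[g])
      res <- tryCatch(fn(cov_tr, pen, control = control, theta0 = theta0),
                      error = function(e) NULL)
      if (is.null(res) || !res$converged) {
        scores[g, v] <- Inf
        conv[g, v] <- FALSE
      } else {
        theta0 <- res$theta
        scores[g, v] <- cv_score(res$theta, cov_te)
      }
    }
  }
  tab <- data.frame(lambda1 = grid$lambda1, lambda2 = grid$lambda2,
                    score = rowSums(scores), converged = apply(conv, 1, all))
  best_i <- which.min(tab$score)
  best <- c(lambda1 = tab$lambda1[best_i], lambda2 = tab$lambda2[best_i])
  fit <- NULL
  if (refit) {
    pen <- penalty_spec(penalty, best["lambda1"], best["lambda2"])
    fit <- fn(class_covariances(dataset, center = center), pen,
              control = control)
  }
  structure(list(table = tab, best = best, folds = folds, V = V, seed = seed,
                 penalty = penalty, solver = solver, fit = fit),
            class = "jgl_cv")
}

#' @export
print.jgl_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s penalty, %s solver)\n", x$V,
              x$penalty, x$solver))
  cat(sprintf("  selected lambda1 = %g, lambda2 = %g (score = %.6g)\n",
              x$best["lambda1"], x$best["lambda2"],
              min(x$table$score)))
  invisible(x)
}
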