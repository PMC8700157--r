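# Synthetic multi-class problem generator and edge-recovery metrics.
# The generator builds K sparse symmetric positive-definite ground-truth
# precision matrices that share a common edge set plus class-specific edges,
# then samples Gaussian data from the implied covariances.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-class Gaussian graphical model problem
#'
#' Builds a shared sparse base graph (Erdos-Renyi edge sampling or a chain)
#' with `edges_shared` edges, adds `edges_class` extra edges per class (drawn
#' disjointly, so class supports overlap in exactly the shared edges), and
#' assigns each edge a magnitude drawn uniformly from
#' `[-mag[2], -mag[1]] U [mag[1], mag[2]]`; shared edges keep the same value
#' in every class.  Positive definiteness is enforced by setting each
#' diagonal to the row l1 norm plus a margin of 0.1, after which the matrix
#' is rescaled to unit diagonal.  Finally `n[k]` Gaussian samples are drawn
#' from each class covariance `solve(Theta(k))`.
#'
#' @param p feature dimension (>= 2).
#' @param K number of classes.
#' @param n per-class sample sizes (recycled to length K).
#' @param edges_shared number of edges in the common base graph (default p,
#'   about two edges per node).
#' @param edges_class number of additional class-specific edges per class
#'   (default `round(p / 4)`).
#' @param mag length-2 positive range of edge magnitudes.
#' @param base `"er"` (random pairs) or `"chain"` (consecutive pairs) for the
#'   shared graph.
#' @param seed integer seed; the problem is fully reproducible from it.
#' @return object of class `"jgl_sim"`: `truth` (list of K precision
#'   matrices), `support` (list of K logical adjacency matrices), `dataset`
#'   (a `"jgl_data"`), `sigma` (list of covariances), and `gen_params`.
#' @examples
#' sim <- jgl_simulate(p = 20, K = 2, n = c(100, 100), seed = 42)
#' sum(sim$support[[1]] & sim$support[[2]]) / 2  # shared edge count
#' @export
jgl_simulate <- function(p = 50, K = 2, n = 300, edges_shared = p,
                         edges_class = round(p / 4), mag = c(0.2, 0.8),
                         base = c("er", "chain"), seed = NULL) {
  base <- match.arg(base)
  stopifnot(p >= 2, K >= 1, all(n >= 1), length(mag) == 2, all(mag > 0))
  n <- rep_len(as.integer(n), K)
  npairs <- p * (p - 1) / 2
  if (edges_shared + K * edges_class > npairs)
    stop("requested more edges than available pairs for p = ", p)
  with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, p, p)))
    shared <- if (base == "chain") {
      idx <- cbind(seq_len(min(edges_shared, p - 1)),
                   seq_len(min(edges_shared, p - 1)) + 1L)
      (idx[, 2] - 1L) * p + idx[, 1]
    } else sample(pairs, edges_shared)
    remaining <- setdiff(pairs, shared)
    specific <- vector("list", K)
    for (k in seq_len(K)) {
      specific[[k]] <- if (edges_class > 0) sample(remaining, edges_class)
                       else integer(0)
      remaining <- setdiff(remaining, specific[[k]])
    }
    rmag <- function(m) sample(c(-1, 1), m, replace = TRUE) *
      runif(m, mag[1], mag[2])
    shared_vals <- rmag(length(shared))
    truth <- support <- sigma <- vector("list", K)
    for (k in seq_len(K)) {
      th <- matrix(0, p, p)
      th[shared] <- shared_vals
      th[specific[[k]]] <- rmag(length(specific[[k]]))
      th <- th + t(th)
      diag(th) <- rowSums(abs(th)) + 0.1
      d <- 1 / sqrt(diag(th))
      th <- sym(th * outer(d, d))          # unit diagonal, still PD
      truth[[k]] <- th
      support[[k]] <- abs(th) > 0 & !diag(p)
      sigma[[k]] <- sym(solve(th))
    }
    x <- lapply(seq_len(K), function(k)
      MASS::mvrnorm(n[k], mu = rep(0, p), Sigma = sigma[[k]]))
    dataset <- multiclass_dataset(x)
    structure(list(truth = truth, support = support, dataset = dataset,
                   sigma = sigma,
                   gen_params = list(p = p, K = K, n = n,
                                     edges_shared = edges_shared,
                                     edges_class = edges_class, mag = mag,
                                     base = base, seed = seed)),
              class = "jgl_sim")
  })
}

#' @export
print.jgl_sim <- function(x, ...) {
  gp <- x$gen_params
  cat(sprintf("Synthetic JGL problem: p = %d, K = %d, n = %s\n", gp$p, gp$K,
              paste(gp$n, collapse = "/")))
  cat(sprintf("  %d shared + %d class-specific edges per class (%s base)\n",
              gp$edges_shared, gp$edges_class, gp$base))
  invisible(x)
}

#' True/false positive edge counts
#'
#' Counts, over off-diagonal unordered pairs i < j in every class, the
#' selected edges (`|theta_hat| > zero_tol`) that are true edges (TP) and
#' non-edges (FP) of the ground truth.
#'
#' @param theta_hat estimated precision set (list of K matrices or a
#'   `"jgl_fit"`).
#' @param truth ground-truth precision set (list of K matrices or a
#'   `"jgl_sim"`).
#' @param zero_tol magnitude below which an estimated entry counts as zero.
#' @return list with `TP`, `FP`, `total_selected`, `total_true` (edges in the
#'   truth) and `total_null`.
#' @export
count_edges <- function(theta_hat, truth, zero_tol = 1e-6) {
  if (inherits(theta_hat, "jgl_fit")) theta_hat <- theta_hat$theta
  if (inherits(truth, "jgl_sim")) truth <- truth$truth
  theta_hat <- as_theta_list(theta_hat); truth <- as_theta_list(truth)
  stopifnot(length(theta_hat) == length(truth))
  p <- nrow(truth[[1]])
  ut <- upper.tri(matrix(0, p, p))
  tp <- fp <- sel <- ntrue <- 0L
  for (k in seq_along(truth)) {
    est <- abs(theta_hat[[k]][ut]) > zero_tol
    tru <- truth[[k]][ut] != 0
    tp <- tp + sum(est & tru)
    fp <- fp + sum(est & !tru)
    sel <- sel + sum(est)
    ntrue <- ntrue + sum(tru)
  }
  list(TP = tp, FP = fp, total_selected = sel, total_true = ntrue,
       total_null = length(truth) * sum(ut) - ntrue)
}

#' Off-diagonal mean squared error
#'
#' `MSE = 2 / (K p (p - 1)) * sum_k sum_{i<j} (theta_hat - theta)^2`, the
#' mean over all off-diagonal entries.
#'
#' @inheritParams count_edges
#' @return nonnegative scalar.
#' @export
mse_offdiag <- function(theta_hat, truth) {
  if (inherits(theta_hat, "jgl_fit")) theta_hat <- theta_hat$theta
  if (inherits(truth, "jgl_sim")) truth <- truth$truth
  theta_hat <- as_theta_list(theta_hat); truth <- as_theta_list(truth)
  K <- length(truth); p <- nrow(truth[[1]])
  ut <- upper.tri(matrix(0, p, p))
  s <- sum(vapply(seq_len(K), function(k)
    sum((theta_hat[[k]][ut] - truth[[k]][ut])^2), numeric(1)))
  2 * s / (K * p * (p - 1))
}

#' ROC sweep over the sparsity penalty
#'
#' Fits the model along a decreasing grid of `lambda1` values at fixed
#' `lambda2` (warm-starting each fit at the previous solution) and records
#' the true/false positive edge counts against the generating truth.
#'
#' @param problem a `"jgl_sim"` object (or a list with `truth` and
#'   `dataset`).
#' @param lambda1_grid numeric vector of sparsity levels (any order; solved
#'   from sparsest down).
#' @param lambda2 fixed coupling level.
#' @param penalty `"fused"` or `"group"`.
#' @param solver `"ista"`, `"mista"`, or `"admm"`.
#' @param control a [jgl_control()] object.
#' @param zero_tol selection threshold.
#' @param center passed to [class_covariances()].
#' @return data frame of class `"jgl_roc"` with columns `lambda1`, `TP`,
#'   `FP`, `tpr`, `fpr`, `mse`, `converged`.
#' @export
roc_sweep <- function(problem, lambda1_grid, lambda2 = 0.05,
                      penalty = c("fused", "group"),
                      solver = c("ista", "mista", "admm"),
                      control = jgl_control(), zero_tol = 1e-6,
                      center = TRUE) {
  penalty <- match.arg(penalty); solver <- match.arg(solver)
  stopifnot(length(lambda1_grid) >= 1)
  cov <- class_covariances(problem$dataset, center = center)
  fn <- switch(solver, ista = jgl_ista, mista = jgl_mista, admm = jgl_admm)
  grid <- sort(lambda1_grid, decreasing = TRUE)
  theta0 <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pen <- penalty_spec(penalty, grid[i], lambda2)
    fit <- fn(cov, pen, control = control, theta0 = theta0)
    theta0 <- fit$theta
    ce <- count_edges(fit$theta, problem$truth, zero_tol)
    rows[[i]] <- data.frame(lambda1 = grid[i], TP = ce$TP, FP = ce$FP,
                            tpr = ce$TP / max(ce$total_true, 1),
                            fpr = ce$FP / max(ce$total_null, 1),
                            mse = mse_offdiag(fit$theta, problem$truth),
                            converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("jgl_roc", "data.frame")
  out
}

#' Normalized area under an edge-selection ROC sweep
#'
#' Trapezoidal area of the true-positive rate against the false-positive
#' rate, with the curve anchored at (0, 0) and (1, 1).
#'
#' @param roc a `"jgl_roc"` data frame from [roc_sweep()].
#' @return scalar in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  x <- c(0, roc$fpr, 1)
  y <- c(0, roc$tpr, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
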