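# Exact proximal operators for the composite penalty g.  The prox separates
# across matrix cells (i, j); each cell is a K-vector problem solved in
# closed form (group) or by exact enumeration over fusion patterns (fused).

#' Soft-thresholding operator
#'
#' `sgn(x) * max(|x| - lam, 0)`, elementwise; the proximal operator of the
#' l1 norm.  Values with `|x| == lam` map to exactly zero.
#'
#' @param x numeric vector, matrix or array.
#' @param lam nonnegative threshold.
#' @return same shape as `x`.
#' @examples
#' soft_threshold(c(1.2, -0.3), 0.5)
#' @export
soft_threshold <- function(x, lam) {
  if (lam < 0) stop("threshold must be nonnegative")
  sign(x) * pmax(abs(x) - lam, 0)
}

#' Prox of the fused-penalty cell problem
#'
#' Exact minimizer of
#' \deqn{\frac12\sum_k(\theta_k-a_k)^2+\alpha\sum_k|\theta_k|
#'   +\beta\sum_{k<l}|\theta_k-\theta_l|}
#' over a K-vector.  The all-pairs fusion term on sorted values is a chain
#' with weight `beta * r * (K - r)` between ranks r and r + 1, solved exactly;
#' the l1 part is then applied by soft-thresholding the fusion-only solution
#' (the two operations commute for fused-lasso problems).
#'
#' @param a numeric K-vector.
#' @param alpha nonnegative l1 level.
#' @param beta nonnegative fusion level.
#' @return numeric K-vector.
#' @examples
#' fused_prox_vec(c(0, 4), alpha = 1, beta = 1)   # (0, 2)
#' @export
fused_prox_vec <- function(a, alpha, beta) {
  if (length(a) < 1L) stop("empty vector")
  if (alpha < 0 || beta < 0) stop("penalty levels must be nonnegative")
  drop(.fused_prox_cpp(matrix(as.numeric(a), ncol = 1), alpha, beta))
}

#' Exact weighted chain fused lasso
#'
#' Minimizes `1/2 sum (y_i - theta_i)^2 + sum w_i |theta_i - theta_{i+1}|`
#' exactly, by enumerating block/sign patterns of the piecewise-constant
#' minimizer (so intended for short chains, m <= 14; here m is the class
#' dimension K).
#'
#' @param y numeric vector (length m).
#' @param w nonnegative weights (length m - 1).
#' @return numeric vector of length m.
#' @export
weighted_chain_fused <- function(y, w) {
  if (length(w) != length(y) - 1L) stop("weights must have length m - 1")
  if (length(y) == 1L) return(as.numeric(y))
  .chain_fused_cpp(as.numeric(y), as.numeric(w))
}

#' Prox of the group-penalty cell problem
#'
#' Exact minimizer of
#' \deqn{\frac12\sum_k(\theta_k-a_k)^2+t_1\sum_k|\theta_k|
#'   +t_2(\sum_k\theta_k^2)^{1/2}:}
#' soft-threshold by `t1`, then shrink the whole vector by the factor
#' `(1 - t2 / ||S_t1(a)||_2)_+` (zero vector when the norm is below `t2`).
#'
#' @param a numeric K-vector.
#' @param t1,t2 nonnegative penalty levels.
#' @return numeric K-vector.
#' @examples
#' group_prox_vec(c(3, 4), 0, 2.5)   # (1.5, 2)
#' @export
group_prox_vec <- function(a, t1, t2) {
  if (t1 < 0 || t2 < 0) stop("penalty levels must be nonnegative")
  s <- soft_threshold(as.numeric(a), t1)
  nrm <- sqrt(sum(s^2))
  if (nrm <= t2) return(numeric(length(a)))
  s * (1 - t2 / nrm)
}

#' Proximal operator of the composite penalty over a matrix set
#'
#' Computes `prox_{eta g}(A)` for the full K-matrix argument
#' `A = Theta - eta * grad f(Theta)`, cell by cell: for the fused family every
#' cell (diagonal included) gets the fused cell prox, with the l1 level
#' `eta * lambda1` applied off-diagonal only; for the group family diagonal
#' cells pass through unchanged and off-diagonal cells get the group cell
#' prox.  The output is exactly symmetric.  Positive definiteness of the
#' result is not guaranteed and is the solver's responsibility.
#'
#' @param A list of K symmetric matrices (or one matrix).
#' @param eta positive step size.
#' @param pen a [penalty_spec()] object.
#' @return list of K symmetric matrices.
#' @export
prox_g <- function(A, eta, pen) {
  A <- as_theta_list(A)
  K <- length(A)
  p <- nrow(A[[1]])
  if (eta <= 0) stop("step size must be positive")
  tolA <- 1e-6 * max(1, max(vapply(A, function(m) max(abs(m)), numeric(1))))
  for (k in seq_len(K))
    if (max(abs(A[[k]] - t(A[[k]]))) > tolA)
      stop("prox input must be symmetric")
  A <- lapply(A, sym)
  if (pen$lambda1 == 0 && pen$lambda2 == 0) return(A)

  t1 <- eta * pen$lambda1
  t2 <- eta * pen$lambda2
  # stack cells as columns of a K x p^2 matrix; operate on upper triangle
  # (incl. diagonal for the fused family) and mirror back
  flat <- do.call(rbind, lapply(A, as.vector))
  dim(flat) <- c(K, p * p)
  idx_mat <- matrix(seq_len(p * p), p, p)
  if (pen$family == "fused") {
    ut <- which(upper.tri(idx_mat, diag = TRUE))
    dg <- which(row(idx_mat)[ut] == col(idx_mat)[ut])
    alpha <- rep(t1, length(ut))
    alpha[dg] <- 0
    res <- .fused_prox_cpp(flat[, ut, drop = FALSE], alpha, t2)
  } else {
    ut <- which(upper.tri(idx_mat))
    sub <- flat[, ut, drop = FALSE]
    st <- soft_threshold(sub, t1)
    nrm <- sqrt(.colSums(st^2, K, length(ut)))
    scale <- ifelse(nrm > t2, 1 - t2 / nrm, 0)
    res <- st * rep(scale, each = K)
  }
  out <- A
  lower <- t(idx_mat)[ut]  # mirror positions
  for (k in seq_len(K)) {
    m <- out[[k]]
    m[ut] <- res[k, ]
    m[lower] <- res[k, ]
    out[[k]] <- m
  }
  out
}
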