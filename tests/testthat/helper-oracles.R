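# Independent oracles used across the test suite.  They deliberately share
# no code path with the package's own operators: the cell-prox oracle solves
# the prox problems by a generic ADMM splitting, gradients are checked by
# finite differences, and covariances by brute-force summation loops.

# Batched ADMM solver for the K-vector cell problems
#   min 1/2 ||theta - a||^2 + alpha ||theta||_1 + beta * pen(theta),
# pen = sum_{k<l} |theta_k - theta_l| (fused) or ||theta||_2 (group).
# Columns of A are independent problems; alpha may vary per column.
prox_oracle <- function(A, alpha, beta, family = c("fused", "group"),
                        iters = 12000, rho = 1) {
  family <- match.arg(family)
  A <- as.matrix(A)
  K <- nrow(A); M <- ncol(A)
  alpha <- rep_len(alpha, M)
  soft <- function(x, lam) sign(x) * pmax(abs(x) - lam, 0)
  lam1 <- matrix(rep(alpha, each = K), K, M) / rho
  if (family == "fused" && K > 1) {
    pairs <- t(combn(K, 2))
    D <- matrix(0, nrow(pairs), K)
    D[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
    D[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- -1
    Mmat <- diag(K) * (1 + rho) + rho * crossprod(D)
    ch <- chol(Mmat)
    z1 <- A; u1 <- 0 * A
    z2 <- D %*% A; u2 <- 0 * z2
    for (it in seq_len(iters)) {
      rhs <- A + rho * (z1 - u1) + rho * crossprod(D, z2 - u2)
      th <- backsolve(ch, forwardsolve(t(ch), rhs))
      z1 <- soft(th + u1, lam1)
      dz <- D %*% th
      z2 <- soft(dz + u2, beta / rho)
      u1 <- u1 + th - z1
      u2 <- u2 + dz - z2
    }
    th
  } else {
    # group penalty (also covers fused with K = 1, where pen vanishes)
    co <- 1 + 2 * rho
    z1 <- A; u1 <- 0 * A; z2 <- A; u2 <- 0 * A
    for (it in seq_len(iters)) {
      th <- (A + rho * (z1 - u1) + rho * (z2 - u2)) / co
      z1 <- soft(th + u1, lam1)
      s <- th + u2
      if (family == "group" && beta > 0) {
        nrm <- sqrt(colSums(s^2))
        z2 <- s * rep(ifelse(nrm > 0, pmax(1 - (beta / rho) / nrm, 0), 0),
                      each = K)
      } else z2 <- s
      u1 <- u1 + th - z1
      u2 <- u2 + th - z2
    }
    th
  }
}

# objective of the cell problem, for direct minimality checks
cell_objective <- function(theta, a, alpha, beta, family) {
  pen <- if (family == "fused") {
    if (length(theta) > 1) sum(abs(outer(theta, theta, "-"))) / 2 else 0
  } else sqrt(sum(theta^2))
  0.5 * sum((theta - a)^2) + alpha * sum(abs(theta)) + beta * pen
}

# full-matrix prox oracle: cell problems assembled like prox_g
prox_g_oracle <- function(A, eta, pen) {
  K <- length(A); p <- nrow(A[[1]])
  flat <- do.call(rbind, lapply(A, as.vector))
  out <- lapply(A, function(m) m)
  idx <- matrix(seq_len(p * p), p, p)
  if (pen$family == "fused") {
    cells <- which(upper.tri(idx, diag = TRUE))
    alpha <- ifelse(row(idx)[cells] == col(idx)[cells], 0, eta * pen$lambda1)
  } else {
    cells <- which(upper.tri(idx))
    alpha <- rep(eta * pen$lambda1, length(cells))
  }
  res <- prox_oracle(flat[, cells, drop = FALSE], alpha, eta * pen$lambda2,
                     pen$family)
  mirror <- t(idx)[cells]
  for (k in seq_len(K)) {
    m <- out[[k]]
    m[cells] <- res[k, ]; m[mirror] <- res[k, ]
    out[[k]] <- m
  }
  out
}

# random symmetric positive-definite matrix with unit-scale eigenvalues
rand_pd <- function(p, jitter = 0.5) {
  q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  ev <- runif(p, jitter, 1 / jitter)
  m <- q %*% (ev * t(q))
  (m + t(m)) / 2
}

# random small covariance-set / precision-set pair
rand_problem <- function(p, K, n = rep(50, K)) {
  S <- lapply(seq_len(K), function(k) rand_pd(p))
  theta <- lapply(seq_len(K), function(k) rand_pd(p))
  list(cov = covariance_set(S, n), theta = theta)
}

frob_diff <- function(a, b)
  sqrt(sum(mapply(function(x, y) sum((x - y)^2), a, b)))
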