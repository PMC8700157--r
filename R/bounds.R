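# Boundedness diagnostics for the solution and the solver iterates, and the
# safe step size that guarantees a linear contraction factor.  These are
# runtime diagnostics: the bounds involve constants whose published closed
# forms are typographically ambiguous, so the implemented reading is
# documented here and in the methods vignette, and nothing in the solvers
# depends on them except the line-search fallback step.

#' Spectral bounds for the solution and the iterates
#'
#' Evaluates, as diagnostics:
#' * a per-class lower bound on the solution's spectral norm,
#'   `n_k / (p * lambda_c + n_k ||S(k)||_2)` with the coupling constant
#'   `lambda_c = K lambda1^2 + 2 K lambda1 lambda2 + lambda2^2`;
#' * an upper bound on the solution,
#'   `N / (p * lambda1) + sum_k sum_i 1 / s_{k,i,i}` (reported as
#'   unavailable when `lambda1 = 0` or a covariance diagonal vanishes);
#' * iterate-norm bounds: upper
#'   `M = ||Theta0||_F + 2 N / (p * lambda1) + 2 sum_k sum_i 1 / s_{k,i,i}`
#'   and lower `m = exp(-C1 / n_max) * M^(1 - K p)` with `C1 = F(Theta0)`;
#' * the safe step size `eta_safe = a_l^2 / n_max`, where `a_l` is the
#'   smallest eigenvalue of the starting point (a conservative stand-in for
#'   the smallest eigenvalue along the iterate path), which lies strictly
#'   inside the interval `(0, 2 a_l^2 / n_max)` that makes the contraction
#'   factor `gamma_t = max(eta n_max / a_l^2 - 1, 1 - eta n_min / b_m^2)`
#'   smaller than one.
#'
#' @param cov a `"jgl_cov"` object.
#' @param pen a [penalty_spec()] object.
#' @param theta0 positive-definite starting point (default as in
#'   [jgl_ista()]).
#' @return object of class `"jgl_bounds"`: `lambda_c`, `lower` (per class),
#'   `upper`, `M`, `m`, `C1`, `n_min`, `n_max`, `a_l`, `b_m`, `eta_safe`,
#'   `gamma_safe`.
#' @export
jgl_bounds <- function(cov, pen, theta0 = NULL) {
  if (is.null(theta0)) theta0 <- default_theta0(cov, pen)
  theta0 <- as_theta_list(theta0)
  if (!is_pd(theta0)) stop("theta0 must be positive definite")
  K <- cov$K
  lam1 <- pen$lambda1; lam2 <- pen$lambda2
  lambda_c <- K * lam1^2 + 2 * K * lam1 * lam2 + lam2^2
  spec <- vapply(cov$S, function(s)
    max(abs(eigen(s, symmetric = TRUE, only.values = TRUE)$values)), numeric(1))
  lower <- cov$n / (cov$p * lambda_c + cov$n * spec)
  diags <- unlist(lapply(cov$S, diag))
  inv_diag_sum <- if (any(diags <= 0)) NA_real_ else sum(1 / diags)
  upper <- if (lam1 > 0 && !is.na(inv_diag_sum))
    cov$N / (cov$p * lam1) + inv_diag_sum else NA_real_
  th0_f <- set_fnorm(theta0)
  M <- if (!is.na(upper)) th0_f + 2 * cov$N / (cov$p * lam1) + 2 * inv_diag_sum
       else NA_real_
  C1 <- jgl_objective(theta0, cov, pen)
  n_max <- max(cov$n); n_min <- min(cov$n)
  m <- if (!is.na(M)) exp(-C1 / n_max) * M^(1 - K * cov$p) else NA_real_
  ev0 <- lapply(theta0, function(t)
    eigen(t, symmetric = TRUE, only.values = TRUE)$values)
  a_l <- min(vapply(ev0, min, numeric(1)))
  b_m <- max(vapply(ev0, max, numeric(1)))
  eta_safe <- a_l^2 / n_max
  gamma_safe <- max(eta_safe * n_max / a_l^2 - 1, 1 - eta_safe * n_min / b_m^2)
  structure(list(lambda_c = lambda_c, lower = lower, upper = upper,
                 M = M, m = m, C1 = C1, n_min = n_min, n_max = n_max,
                 a_l = a_l, b_m = b_m, eta_safe = eta_safe,
                 gamma_safe = gamma_safe),
            class = "jgl_bounds")
}

#' @export
print.jgl_bounds <- function(x, ...) {
  cat("Boundedness diagnostics\n")
  cat(sprintf("  lambda_c = %.4g; solution spectral bounds: [%.4g, %s]\n",
              x$lambda_c, max(x$lower),
              ifelse(is.na(x$upper), "unavailable", sprintf("%.4g", x$upper))))
  cat(sprintf("  iterate norm bounds: [%s, %s]\n",
              ifelse(is.na(x$m), "unavailable", sprintf("%.4g", x$m)),
              ifelse(is.na(x$M), "unavailable", sprintf("%.4g", x$M))))
  cat(sprintf("  safe step eta = %.4g (contraction gamma = %.4g)\n",
              x$eta_safe, x$gamma_safe))
  invisible(x)
}

#' Safe step size
#'
#' The midpoint `a_l^2 / n_max` of the admissible interval
#' `(0, 2 a_l^2 / n_max)` in which the linear contraction factor stays below
#' one; `a_l` is the smallest iterate eigenvalue bound and `n_max` the
#' largest class sample size.
#'
#' @param bounds a `"jgl_bounds"` object, or `NULL` if `a_l`/`n_max` are
#'   given directly.
#' @param a_l,n_max override the bound constants directly.
#' @return positive step size.
#' @export
safe_step_size <- function(bounds = NULL, a_l = bounds$a_l,
                           n_max = bounds$n_max) {
  if (is.null(a_l) || is.null(n_max) || !is.finite(a_l) || a_l <= 0)
    stop("eigenvalue bound unavailable; use backtracking instead")
  a_l^2 / n_max
}
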