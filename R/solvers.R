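# Solvers for the joint graphical lasso: proximal gradient with backtracking
# (ISTA), a modified ISTA whose step sizes come from the self-concordance of
# the log-determinant barrier (no line search), and an ADMM reference solver.

#' Solver control parameters
#'
#' @param tol convergence tolerance for the stopping rule.
#' @param max_iter maximum number of iterations.
#' @param stop_rule `"relative_error"` (default): stop when
#'   `sum_k ||Theta_{t+1}(k) - Theta_t(k)||_F / max(sum_k ||Theta_t(k)||_F, 1)`
#'   drops below `tol`; or `"objective_error"`: stop when
#'   `F(Theta_t) - F(Theta*) <= tol`, with `F(Theta*)` taken from a reference
#'   solve at `tol / 100` under the relative-error rule (used for
#'   convergence-rate experiments).
#' @param c backtracking shrink factor in (0, 1).
#' @param eta0 initial step size for the first iteration.
#' @param max_backtracks backtracking attempts per iteration before falling
#'   back to the safe step size.
#' @param bb_clip two positive numbers; the Barzilai-Borwein step is clipped
#'   to this range.
#' @param halving_cap maximum step-halvings per M-ISTA iteration.
#' @param exact_hessian logical; M-ISTA's curvature scalar lambda_t.  `TRUE`
#'   (default) uses the Hessian quadratic form
#'   `sqrt(sum_k n_k trace((Theta(k)^{-1} d(k))^2))`; `FALSE` uses the
#'   heuristic variant `sum_k n_k ||Theta(k)^{-1} d(k)||_F`.
#' @param debug_checks logical; verify positive definiteness and descent at
#'   every M-ISTA iteration (always on for ISTA, where the line search needs
#'   them anyway).
#' @param verbose integer verbosity (0 silent, 1 per-iteration).
#' @return list of class `"jgl_control"`.
#' @export
jgl_control <- function(tol = 1e-5, max_iter = 1000L,
                        stop_rule = c("relative_error", "objective_error"),
                        c = 0.5, eta0 = 1.0, max_backtracks = 50L,
                        bb_clip = c(1e-8, 1e8), halving_cap = 60L,
                        exact_hessian = TRUE, debug_checks = FALSE,
                        verbose = 0L) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(tol > 0, max_iter >= 1, c > 0, c < 1, eta0 > 0,
            length(bb_clip) == 2, all(bb_clip > 0))
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 stop_rule = stop_rule, c = c, eta0 = eta0,
                 max_backtracks = as.integer(max_backtracks),
                 bb_clip = bb_clip, halving_cap = as.integer(halving_cap),
                 exact_hessian = exact_hessian, debug_checks = debug_checks,
                 verbose = as.integer(verbose)),
            class = "jgl_control")
}

default_theta0 <- function(cov, pen) {
  lapply(seq_len(cov$K), function(k) {
    d <- 1 / (diag(cov$S[[k]]) + pen$lambda1)
    if (any(!is.finite(d)))
      stop("zero covariance diagonal with lambda1 = 0: supply theta0")
    m <- diag(d, cov$p)
    dimnames(m) <- list(cov$feature_names, cov$feature_names)
    m
  })
}

frob2 <- function(x) sum(x^2)
set_inner <- function(a, b) sum(mapply(function(u, v) sum(u * v), a, b))
set_fnorm <- function(a) sqrt(sum(vapply(a, frob2, numeric(1))))

#' Quadratic majorization model
#'
#' `Q_eta(Theta', Theta) = f(Theta) + <Theta' - Theta, grad f(Theta)> +
#'  (1 / 2 eta) ||Theta' - Theta||_F^2` (inner products summed over classes).
#'
#' @param theta_new,theta lists of K matrices; `theta` must be positive
#'   definite.
#' @param eta positive step size.
#' @param cov a `"jgl_cov"` object.
#' @param f_theta,grad optional precomputed `jgl_neg_loglik(theta, cov)` and
#'   `jgl_gradient(theta, cov)`.
#' @return scalar model value.
#' @export
quadratic_model <- function(theta_new, theta, eta, cov,
                            f_theta = NULL, grad = NULL) {
  theta_new <- as_theta_list(theta_new); theta <- as_theta_list(theta)
  if (is.null(f_theta)) f_theta <- jgl_neg_loglik(theta, cov)
  if (is.null(grad)) grad <- jgl_gradient(theta, cov)
  d <- mapply(function(a, b) a - b, theta_new, theta, SIMPLIFY = FALSE)
  f_theta + set_inner(d, grad) + frob2_set(d) / (2 * eta)
}

frob2_set <- function(a) sum(vapply(a, frob2, numeric(1)))

#' Relative-change stopping quantity
#'
#' `sum_k ||new(k) - old(k)||_F / max(sum_k ||old(k)||_F, 1)`.
#'
#' @param theta_new,theta_old lists of K matrices of matching shape.
#' @return nonnegative scalar.
#' @export
relative_change <- function(theta_new, theta_old) {
  theta_new <- as_theta_list(theta_new); theta_old <- as_theta_list(theta_old)
  num <- sum(mapply(function(a, b) sqrt(frob2(a - b)), theta_new, theta_old))
  den <- max(sum(vapply(theta_old, function(m) sqrt(frob2(m)), numeric(1))), 1)
  num / den
}

#' Fixed-point optimality residual
#'
#' `||Theta - prox_{eta g}(Theta - eta grad f(Theta))||_F / (1 + ||Theta||_F)`;
#' zero exactly at a minimizer, for any `eta > 0`.
#'
#' @param theta positive-definite precision set.
#' @param cov,pen problem data.
#' @param eta positive probe step (default 1 / max n_k, a likelihood-scale
#'   step).
#' @return nonnegative scalar.
#' @export
fixed_point_residual <- function(theta, cov, pen, eta = 1 / max(cov$n)) {
  theta <- as_theta_list(theta)
  g <- jgl_gradient(theta, cov)
  a <- mapply(function(t, gr) t - eta * gr, theta, g, SIMPLIFY = FALSE)
  pr <- prox_g(a, eta, pen)
  d <- mapply(function(t, q) t - q, theta, pr, SIMPLIFY = FALSE)
  sqrt(frob2_set(d)) / (1 + set_fnorm(theta))
}

#' Barzilai-Borwein initial step size
#'
#' `eta = <dTheta, dTheta> / <dTheta, dGrad>` over the class-stacked
#' matrices; falls back when the curvature inner product is nonpositive, and
#' is clipped to `clip`.
#'
#' @param d_theta,d_grad lists of K matrices: successive iterate and gradient
#'   differences.
#' @param fallback positive step returned when the denominator is <= 0.
#' @param clip length-2 positive range.
#' @return positive scalar step.
#' @export
bb_step <- function(d_theta, d_grad, fallback, clip = c(1e-8, 1e8)) {
  num <- frob2_set(as_theta_list(d_theta))
  den <- set_inner(as_theta_list(d_theta), as_theta_list(d_grad))
  eta <- if (den > 0 && num > 0) num / den else fallback
  min(max(eta, clip[1]), clip[2])
}

# Log-det and inverse from a shared Cholesky factorization.
theta_state <- function(theta, cov) {
  ch <- theta_chols(theta)
  if (is.null(ch)) return(NULL)
  inv <- lapply(ch, chol2inv)
  ld <- vapply(ch, function(u) 2 * sum(log(diag(u))), numeric(1))
  f <- 0
  for (k in seq_len(cov$K))
    f <- f - cov$n[k] * (ld[k] - sum(cov$S[[k]] * theta[[k]]))
  grad <- lapply(seq_len(cov$K), function(k)
    cov$n[k] * sym(cov$S[[k]] - inv[[k]]))
  list(theta = theta, inv = inv, f = f, grad = grad)
}

new_trace_row <- function(t, F, eta, alpha, backtracks, rel, resid,
                          dikin = NA_real_) {
  data.frame(iter = t, objective = F, eta = eta, alpha = alpha,
             backtracks = backtracks, rel_change = rel, residual = resid,
             alpha_lambda = dikin)
}

finish_fit <- function(theta, cov, pen, control, trace, converged, solver) {
  theta <- lapply(theta, function(m) {
    dimnames(m) <- list(cov$feature_names, cov$feature_names); m
  })
  names(theta) <- cov$class_labels
  structure(list(theta = theta, trace = trace, converged = converged,
                 iterations = nrow(trace), solver = solver, penalty = pen,
                 objective = trace$objective[nrow(trace)],
                 control = control),
            class = "jgl_fit")
}

#' @export
print.jgl_fit <- function(x, ...) {
  cat(sprintf("Joint graphical lasso fit (%s, %s penalty)\n", x$solver,
              x$penalty$family))
  cat(sprintf("  lambda1 = %g, lambda2 = %g\n", x$penalty$lambda1,
              x$penalty$lambda2))
  cat(sprintf("  %d iterations, converged: %s, objective = %.6g\n",
              x$iterations, x$converged, x$objective))
  K <- length(x$theta); p <- nrow(x$theta[[1]])
  nz <- vapply(x$theta, function(m) sum(abs(m[!diag(p)]) > 1e-6) / 2, numeric(1))
  cat("  off-diagonal edges per class:", paste(round(nz), collapse = ", "), "\n")
  invisible(x)
}

# Objective-error stopping needs F(Theta*): get it from a tighter
# relative-error solve with the same solver.
reference_objective <- function(solver_fn, cov, pen, control, theta0) {
  ref_ctl <- control
  ref_ctl$stop_rule <- "relative_error"
  ref_ctl$tol <- control$tol / 100
  ref_ctl$max_iter <- max(control$max_iter * 4L, 2000L)
  ref <- solver_fn(cov, pen, ref_ctl, theta0)
  ref$objective
}

#' One backtracking proximal-gradient step
#'
#' Shrinks `eta` by the factor `control$c` until the prox-gradient update is
#' positive definite (Cholesky check first) and satisfies the majorization
#' condition `f(Theta_new) <= Q_eta(Theta_new, Theta)`.  If
#' `max_backtracks` is exhausted, the safe step derived from current-iterate
#' eigenvalue bounds is used (flagged with `backtracks = -1`).
#'
#' @param theta positive-definite precision set (list of K matrices).
#' @param eta starting step size.
#' @param cov,pen problem data.
#' @param control a [jgl_control()] object.
#' @return list with `theta` (the accepted update), `eta`, `backtracks`, and
#'   the new iterate's cached `state`.
#' @export
ista_step <- function(theta, eta, cov, pen, control = jgl_control()) {
  st <- theta_state(as_theta_list(theta), cov)
  if (is.null(st)) stop("iterate is not positive definite")
  ista_step_(st, eta, cov, pen, control)
}

ista_step_ <- function(st, eta, cov, pen, control) {
  for (bt in 0:control$max_backtracks) {
    a <- mapply(function(t, g) t - eta * g, st$theta, st$grad, SIMPLIFY = FALSE)
    cand <- prox_g(a, eta, pen)
    cand_st <- theta_state(cand, cov)          # NULL unless PD
    if (!is.null(cand_st)) {
      q <- st$f + set_inner(mapply(function(x, y) x - y, cand, st$theta,
                                   SIMPLIFY = FALSE), st$grad) +
        frob2_set(mapply(function(x, y) x - y, cand, st$theta,
                         SIMPLIFY = FALSE)) / (2 * eta)
      if (cand_st$f <= q)
        return(list(theta = cand, eta = eta, backtracks = bt, state = cand_st))
    }
    eta <- eta * control$c
  }
  # fall back to the safe step from current-iterate spectral bounds
  al <- min(vapply(st$inv, function(m) 1 / max(eigen(m, symmetric = TRUE,
                                                     only.values = TRUE)$values),
                   numeric(1)))
  eta <- al^2 / max(cov$n)
  a <- mapply(function(t, g) t - eta * g, st$theta, st$grad, SIMPLIFY = FALSE)
  cand <- prox_g(a, eta, pen)
  cand_st <- theta_state(cand, cov)
  if (is.null(cand_st)) stop("backtracking failed and the safe step left the cone")
  list(theta = cand, eta = eta, backtracks = -1L, state = cand_st)
}

#' ISTA solver with backtracking line search
#'
#' Proximal gradient descent on the joint graphical lasso objective: each
#' iteration takes a gradient step on the smooth likelihood term, applies the
#' exact penalty prox, and backtracks the step size until the update is
#' positive definite and majorized.  The next iteration's step is initialized
#' by the Barzilai-Borwein rule.
#'
#' @param cov a `"jgl_cov"` object ([class_covariances()] or
#'   [covariance_set()]).
#' @param pen a [penalty_spec()] object.
#' @param control a [jgl_control()] object.
#' @param theta0 optional positive-definite starting point; defaults to the
#'   diagonal matrices `diag(1 / (s_{k,i,i} + lambda1))`.
#' @return object of class `"jgl_fit"`: the estimated precision matrices
#'   (`$theta`), a per-iteration `$trace` data frame (objective, step size,
#'   backtrack count, relative change, fixed-point residual), `$converged`,
#'   `$iterations`, `$objective`.
#' @examples
#' sim <- jgl_simulate(p = 10, K = 2, n = c(50, 50), seed = 1)
#' cov <- class_covariances(sim$dataset)
#' fit <- jgl_ista(cov, penalty_spec("fused", 0.05, 0.02))
#' fit
#' @export
jgl_ista <- function(cov, pen, control = jgl_control(), theta0 = NULL) {
  stopifnot(inherits(cov, "jgl_cov"), inherits(pen, "jgl_penalty"))
  if (is.null(theta0)) theta0 <- default_theta0(cov, pen)
  theta0 <- as_theta_list(theta0)
  st <- theta_state(theta0, cov)
  if (is.null(st)) stop("theta0 is not positive definite")

  F_star <- if (control$stop_rule == "objective_error")
    reference_objective(jgl_ista, cov, pen, control, theta0) else NULL

  eta <- control$eta0
  F_cur <- st$f + jgl_penalty_value(st$theta, pen)
  rows <- vector("list", control$max_iter)
  converged <- FALSE
  for (t in seq_len(control$max_iter)) {
    step <- ista_step_(st, eta, cov, pen, control)
    new_st <- step$state
    F_new <- new_st$f + jgl_penalty_value(step$theta, pen)
    rel <- relative_change(step$theta, st$theta)
    rows[[t]] <- new_trace_row(t, F_new, step$eta, NA_real_, step$backtracks,
                               rel, NA_real_)
    if (control$verbose > 0)
      message(sprintf("iter %4d  F = %.8g  eta = %.3g  bt = %d  rel = %.3g",
                      t, F_new, step$eta, step$backtracks, rel))
    d_theta <- mapply(function(a, b) a - b, step$theta, st$theta, SIMPLIFY = FALSE)
    d_grad <- mapply(function(a, b) a - b, new_st$grad, st$grad, SIMPLIFY = FALSE)
    eta <- bb_step(d_theta, d_grad, fallback = step$eta, clip = control$bb_clip)
    st <- new_st
    F_cur <- F_new
    done <- switch(control$stop_rule,
                   relative_error = rel <= control$tol,
                   objective_error = (F_cur - F_star) <= control$tol)
    if (done) { converged <- TRUE; break }
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  trace$residual[nrow(trace)] <- fixed_point_residual(st$theta, cov, pen)
  finish_fit(st$theta, cov, pen, control, trace, converged, "ista")
}

# curvature scalar lambda_t for M-ISTA
mista_lambda <- function(st, d, n, exact) {
  if (exact) {
    s <- 0
    for (k in seq_along(d)) {
      m <- st$inv[[k]] %*% d[[k]]
      s <- s + n[k] * sum(m * t(m))      # trace((Theta^{-1} d)^2)
    }
    sqrt(max(s, 0))
  } else {
    sum(vapply(seq_along(d), function(k)
      n[k] * sqrt(frob2(st$inv[[k]] %*% d[[k]])), numeric(1)))
  }
}

#' Modified ISTA (self-concordant step-size selection)
#'
#' Proximal gradient descent without a line search: the search direction
#' `d_t = prox_{eta g}(Theta_t - eta grad f) - Theta_t` is damped by
#' `alpha_t = beta_t / (lambda_t (lambda_t + beta_t))` with
#' `beta_t = ||d_t||_F^2 / eta` and `lambda_t` the Hessian quadratic-form
#' norm of the direction.  When `alpha_t > 1`, `eta` is halved while that
#' reduces `alpha_t`; if halving stops helping, the damping is capped at
#' `alpha = 1` (valid because `alpha_t > 1` implies `lambda_t < 1`).
#' Because every accepted step keeps the self-concordant Dikin condition
#' `alpha * lambda_t < 1`, the iterates stay positive definite with no
#' Cholesky-driven backtracking; descent of the objective is guaranteed by
#' the self-concordance of the log-determinant.
#'
#' @inheritParams jgl_ista
#' @return object of class `"jgl_fit"`; the trace additionally records the
#'   damping factor `alpha` per iteration.
#' @export
jgl_mista <- function(cov, pen, control = jgl_control(), theta0 = NULL) {
  stopifnot(inherits(cov, "jgl_cov"), inherits(pen, "jgl_penalty"))
  if (is.null(theta0)) theta0 <- default_theta0(cov, pen)
  theta0 <- as_theta_list(theta0)
  st <- theta_state(theta0, cov)
  if (is.null(st)) stop("theta0 is not positive definite")

  F_star <- if (control$stop_rule == "objective_error")
    reference_objective(jgl_mista, cov, pen, control, theta0) else NULL

  eta <- control$eta0
  rows <- vector("list", control$max_iter)
  converged <- FALSE
  for (t in seq_len(control$max_iter)) {
    halvings <- 0L
    prev_alpha <- Inf
    repeat {
      a <- mapply(function(th, g) th - eta * g, st$theta, st$grad,
                  SIMPLIFY = FALSE)
      d <- mapply(function(pr, th) pr - th, prox_g(a, eta, pen), st$theta,
                  SIMPLIFY = FALSE)
      beta_t <- frob2_set(d) / eta
      if (beta_t == 0) { alpha_t <- 0; break }       # exact fixed point
      lambda_t <- mista_lambda(st, d, cov$n, control$exact_hessian)
      alpha_t <- beta_t / (lambda_t * (lambda_t + beta_t))
      if (alpha_t <= 1) break
      # alpha_t > 1 forces lambda_t < 1, so the full prox step already
      # satisfies the Dikin condition alpha * lambda_t < 1 and any damping
      # alpha <= alpha_t keeps the guaranteed decrease.  Halve eta while it
      # actually shrinks alpha_t; once halving stops helping (in the
      # small-step regime alpha_t grows as eta shrinks), cap alpha at 1.
      if (alpha_t >= prev_alpha || halvings >= control$halving_cap) {
        alpha_t <- 1
        break
      }
      prev_alpha <- alpha_t
      eta <- eta / 2
      halvings <- halvings + 1L
    }
    if (alpha_t == 0) {
      rel <- 0
      rows[[t]] <- new_trace_row(t, st$f + jgl_penalty_value(st$theta, pen),
                                 eta, 0, halvings, rel, NA_real_)
      converged <- TRUE
      break
    }
    theta_new <- mapply(function(th, dk) th + alpha_t * dk, st$theta, d,
                        SIMPLIFY = FALSE)
    new_st <- theta_state(theta_new, cov)
    if (is.null(new_st))
      stop("M-ISTA iterate left the positive-definite cone")
    F_new <- new_st$f + jgl_penalty_value(theta_new, pen)
    if (control$debug_checks) {
      F_old <- st$f + jgl_penalty_value(st$theta, pen)
      if (F_new > F_old + 1e-8 * max(1, abs(F_old)))
        warning("M-ISTA objective increased at iteration ", t)
    }
    rel <- relative_change(theta_new, st$theta)
    rows[[t]] <- new_trace_row(t, F_new, eta, alpha_t, halvings, rel, NA_real_,
                               dikin = alpha_t * lambda_t)
    if (control$verbose > 0)
      message(sprintf("iter %4d  F = %.8g  eta = %.3g  alpha = %.3g  rel = %.3g",
                      t, F_new, eta, alpha_t, rel))
    d_theta <- mapply(function(x, y) x - y, theta_new, st$theta, SIMPLIFY = FALSE)
    d_grad <- mapply(function(x, y) x - y, new_st$grad, st$grad, SIMPLIFY = FALSE)
    eta <- bb_step(d_theta, d_grad, fallback = eta, clip = control$bb_clip)
    st <- new_st
    done <- switch(control$stop_rule,
                   relative_error = rel <= control$tol,
                   objective_error =
                     (F_new - F_star) <= control$tol)
    if (done) { converged <- TRUE; break }
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  trace$residual[nrow(trace)] <- fixed_point_residual(st$theta, cov, pen)
  finish_fit(st$theta, cov, pen, control, trace, converged, "mista")
}

#' ADMM reference solver
#'
#' Standard consensus ADMM for the joint graphical lasso, included as an
#' independent cross-check for the proximal-gradient solvers.  The
#' per-class likelihood update is the closed-form eigenvalue update of the
#' penalized log-determinant subproblem; the coupling update is the penalty
#' prox at step `1 / rho`.  Iterates until the fixed-point residual of the
#' consensus variable falls below `control$tol`.
#'
#' @inheritParams jgl_ista
#' @param rho positive augmented-Lagrangian parameter; defaults to the mean
#'   class sample size (the likelihood term carries weights n_k, so this
#'   keeps the two ADMM blocks on comparable scales).
#' @return object of class `"jgl_fit"` (trace records the residual every
#'   iteration).
#' @export
jgl_admm <- function(cov, pen, control = jgl_control(), theta0 = NULL,
                     rho = mean(cov$n)) {
  stopifnot(inherits(cov, "jgl_cov"), inherits(pen, "jgl_penalty"), rho > 0)
  K <- cov$K; p <- cov$p
  if (is.null(theta0)) theta0 <- default_theta0(cov, pen)
  Z <- as_theta_list(theta0)
  U <- replicate(K, matrix(0, p, p), simplify = FALSE)
  theta <- Z
  max_iter <- max(control$max_iter, 5000L)
  rows <- vector("list", 0L)
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    # Theta-update: argmin n_k(-logdet + tr(S Theta)) + rho/2 ||Theta - Z + U||^2
    for (k in seq_len(K)) {
      Ek <- sym(rho * (Z[[k]] - U[[k]]) - cov$n[k] * cov$S[[k]])
      ee <- eigen(Ek, symmetric = TRUE)
      th_eig <- (ee$values + sqrt(ee$values^2 + 4 * rho * cov$n[k])) / (2 * rho)
      theta[[k]] <- sym(ee$vectors %*% (th_eig * t(ee$vectors)))
    }
    Zold <- Z
    Z <- prox_g(mapply(function(a, b) a + b, theta, U, SIMPLIFY = FALSE),
                1 / rho, pen)
    U <- mapply(function(u, th, z) u + th - z, U, theta, Z, SIMPLIFY = FALSE)
    if (t %% 10 == 0 || t == max_iter) {
      prim <- sqrt(frob2_set(mapply(function(a, b) a - b, theta, Z,
                                    SIMPLIFY = FALSE)))
      dual <- sqrt(frob2_set(mapply(function(a, b) a - b, Z, Zold,
                                    SIMPLIFY = FALSE)))
      res <- if (is_pd(Z)) fixed_point_residual(Z, cov, pen) else NA_real_
      Fv <- if (is_pd(Z)) jgl_objective(Z, cov, pen) else NA_real_
      rows[[length(rows) + 1L]] <-
        new_trace_row(t, Fv, 1 / rho, NA_real_, 0L, prim + dual, res)
      if (!is.na(res) && res <= control$tol) { converged <- TRUE; break }
    }
  }
  trace <- do.call(rbind, rows)
  finish_fit(Z, cov, pen, control, trace, converged, "admm")
}

#' Fit a joint graphical lasso model
#'
#' Convenience front end: forms per-class covariances from a dataset (or
#' accepts a precomputed `"jgl_cov"`) and dispatches to the requested solver.
#'
#' @param data a `"jgl_data"` dataset, a list of per-class sample matrices,
#'   or a `"jgl_cov"` covariance set.
#' @param penalty `"fused"` or `"group"`.
#' @param lambda1,lambda2 nonnegative penalty levels.
#' @param solver `"ista"`, `"mista"`, or `"admm"`.
#' @param center column-center each class before forming covariances
#'   (ignored for covariance input).
#' @param control a [jgl_control()] object.
#' @param theta0 optional starting point.
#' @return object of class `"jgl_fit"`.
#' @examples
#' sim <- jgl_simulate(p = 8, K = 2, n = c(40, 40), seed = 7)
#' fit <- jgl(sim$dataset, "group", lambda1 = 0.05, lambda2 = 0.02)
#' @export
jgl <- function(data, penalty = c("fused", "group"), lambda1, lambda2,
                solver = c("ista", "mista", "admm"), center = TRUE,
                control = jgl_control(), theta0 = NULL) {
  solver <- match.arg(solver)
  pen <- penalty_spec(match.arg(penalty), lambda1, lambda2)
  cov <- if (inherits(data, "jgl_cov")) data else {
    if (!inherits(data, "jgl_data")) data <- multiclass_dataset(data)
    class_covariances(data, center = center)
  }
  fn <- switch(solver, ista = jgl_ista, mista = jgl_mista, admm = jgl_admm)
  fn(cov, pen, control = control, theta0 = theta0)
}
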