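# Solver behavior: quadratic model, steps, stopping quantities, bounds,
# cross-solver agreement.

test_that("quadratic model matches independent term-by-term evaluation", {
  set.seed(21)
  pr <- rand_problem(4, 2, n = c(20, 30))
  th2 <- lapply(1:2, function(k) rand_pd(4))

  # Theta' = Theta: both correction terms vanish
  expect_equal(quadratic_model(pr$theta, pr$theta, 0.3, pr$cov),
               jgl_neg_loglik(pr$theta, pr$cov))

  # eta -> large leaves f + linear term
  g <- jgl_gradient(pr$theta, pr$cov)
  lin <- jgl_neg_loglik(pr$theta, pr$cov) +
    sum(mapply(function(a, b, gr) sum((a - b) * gr), th2, pr$theta, g))
  expect_equal(quadratic_model(th2, pr$theta, 1e12, pr$cov), lin,
               tolerance = 1e-6)

  # random eta: add the quadratic correction explicitly
  eta <- 0.7
  quad <- sum(mapply(function(a, b) sum((a - b)^2), th2, pr$theta)) / (2 * eta)
  expect_equal(quadratic_model(th2, pr$theta, eta, pr$cov), lin + quad,
               tolerance = 1e-8)
})

test_that("backtracking step accepts good steps and enforces feasibility", {
  set.seed(22)
  pr <- rand_problem(3, 1, n = 40)
  pen <- penalty_spec("fused", 0.1, 0)
  ctl <- jgl_control()

  # tiny step: majorization already satisfied, no backtracking
  st <- ista_step(pr$theta, 1e-6, pr$cov, pen, ctl)
  expect_identical(st$backtracks, 0L)
  expect_equal(st$eta, 1e-6)

  # scalar problem moves toward 1/s
  cv1 <- covariance_set(matrix(2, 1, 1), n = 1)
  s1 <- ista_step(matrix(1, 1, 1), 0.1, cv1, penalty_spec("fused", 0.5, 0),
                  ctl)
  # gradient at theta=1 is (2 - 1) = 1; no thresholding on a 1x1 diagonal
  expect_equal(s1$theta[[1]][1, 1], 1 - 0.1 * 1)

  # huge starting step gets cut until the iterate is positive definite
  s2 <- ista_step(pr$theta, 1e6, pr$cov, pen, ctl)
  expect_gt(s2$backtracks, 0)
  expect_true(is_pd(s2$theta))
  expect_lt(s2$eta, 1e6)
})

test_that("scalar and separable problems have known solutions", {
  # p=1: solution 1/s regardless of lambda1 (no off-diagonal to penalize)
  cv1 <- covariance_set(matrix(2, 1, 1), n = 5)
  for (solver in list(jgl_ista, jgl_mista)) {
    fit <- solver(cv1, penalty_spec("fused", 3, 0), jgl_control(tol = 1e-10))
    expect_equal(fit$theta[[1]][1, 1], 0.5, tolerance = 1e-6)
  }

  # lambda2 = 0: K = 2 equals two independent single-class solves
  set.seed(23)
  pr <- rand_problem(6, 2, n = c(40, 60))
  for (fam in c("fused", "group")) {
    pen <- penalty_spec(fam, 0.08, 0)
    joint <- jgl_ista(pr$cov, pen, jgl_control(tol = 1e-6, max_iter = 3000))
    for (k in 1:2) {
      single <- jgl_ista(covariance_set(pr$cov$S[[k]], pr$cov$n[k]),
                         penalty_spec(fam, 0.08, 0),
                         jgl_control(tol = 1e-6, max_iter = 3000))
      expect_lt(frob_diff(joint$theta[k], single$theta), 1e-4)
    }
  }

  # group family, huge lambda1: empty support, diagonals 1/s_ii
  fitg <- jgl_ista(pr$cov, penalty_spec("group", 1e4, 0.1),
                   jgl_control(tol = 1e-10, max_iter = 2000))
  for (k in 1:2) {
    off <- fitg$theta[[k]][upper.tri(fitg$theta[[k]])]
    expect_true(all(off == 0))
    expect_equal(unname(diag(fitg$theta[[k]])), unname(1 / diag(pr$cov$S[[k]])),
                 tolerance = 1e-6)
  }
})

test_that("Barzilai-Borwein step handles the canonical cases", {
  d <- list(matrix(c(1, 0, 0, 2), 2))
  expect_equal(bb_step(d, d, fallback = 9), 1)
  expect_equal(bb_step(d, lapply(d, function(m) 2 * m), fallback = 9), 0.5)
  expect_equal(bb_step(d, lapply(d, function(m) -m), fallback = 9), 9)
  expect_equal(bb_step(d, lapply(d, function(m) 1e-20 * m), fallback = 9,
                       clip = c(1e-8, 1e3)), 1e3)
})

test_that("stopping quantities behave as defined", {
  a <- list(matrix(c(1, 2, 2, 5), 2)); b <- list(matrix(c(2, 2, 2, 6), 2))
  expect_equal(relative_change(a, a), 0)
  expect_equal(relative_change(b, a),
               sqrt(2) / max(sqrt(sum(a[[1]]^2)), 1))
  tiny <- list(matrix(1e-8, 1, 1))
  expect_equal(relative_change(list(matrix(2e-8, 1, 1)), tiny), 1e-8)

  # fixed point of the scalar problem has zero residual
  cv1 <- covariance_set(matrix(2, 1, 1), n = 1)
  expect_lt(fixed_point_residual(matrix(0.5, 1, 1), cv1,
                                 penalty_spec("fused", 0.3, 0)), 1e-14)

  # residual decreases along the solve and grows under perturbation
  set.seed(24)
  sim <- jgl_simulate(p = 8, K = 2, n = c(60, 60), seed = 101)
  cov <- class_covariances(sim$dataset)
  pen <- penalty_spec("fused", 0.05, 0.02)
  fit <- jgl_ista(cov, pen, jgl_control(tol = 1e-8, max_iter = 3000))
  r_end <- fixed_point_residual(fit$theta, cov, pen)
  th0 <- jglprox:::default_theta0(cov, pen)
  expect_lt(r_end, fixed_point_residual(th0, cov, pen))
  pert <- lapply(fit$theta, function(m) m + diag(0.05, nrow(m)))
  expect_gt(fixed_point_residual(pert, cov, pen), r_end)
})

test_that("bounds diagnostics have the documented structure", {
  set.seed(25)
  pr <- rand_problem(4, 2, n = c(30, 50))
  pen <- penalty_spec("fused", 0.2, 0.1)
  b <- jgl_bounds(pr$cov, pen)
  expect_true(all(b$lower > 0))
  expect_true(b$upper > max(b$lower))
  expect_true(b$M > 0 && b$m > 0 && b$m < b$M)
  expect_gt(b$eta_safe, 0)
  expect_lt(b$gamma_safe, 1)

  # K=1, lambda2=0: coupling constant reduces to lambda1^2
  b1 <- jgl_bounds(covariance_set(pr$cov$S[[1]], 30),
                   penalty_spec("fused", 0.2, 0))
  expect_equal(b1$lambda_c, 0.2^2)

  # diagonal S with equal entries: hand-computable bounds
  cvd <- covariance_set(diag(2, 3), n = 10)
  pend <- penalty_spec("fused", 0.5, 0)
  bd <- jgl_bounds(cvd, pend)
  expect_equal(unname(bd$lower), 10 / (3 * 0.25 + 10 * 2))
  expect_equal(bd$upper, 10 / (3 * 0.5) + 3 / 2)

  # upper bound nonincreasing in lambda1
  u <- vapply(c(0.1, 0.2, 0.5, 1), function(l1)
    jgl_bounds(pr$cov, penalty_spec("fused", l1, 0.1))$upper, numeric(1))
  expect_true(all(diff(u) <= 0))

  # safe step arithmetic
  expect_equal(safe_step_size(a_l = 1, n_max = 2), 0.5)
  expect_equal(safe_step_size(a_l = 1, n_max = 4), 0.25)
  expect_lt(safe_step_size(bd), 2 * bd$a_l^2 / bd$n_max)
  expect_error(safe_step_size(a_l = NA, n_max = 2), "unavailable")
})

test_that("solvers descend monotonically and agree with each other", {
  set.seed(26)
  sim <- jgl_simulate(p = 12, K = 2, n = c(80, 80), seed = 77)
  cov <- class_covariances(sim$dataset)
  for (fam in c("fused", "group")) {
    pen <- penalty_spec(fam, 0.06, 0.03)
    fi <- jgl_ista(cov, pen, jgl_control(tol = 1e-8, max_iter = 4000))
    fm <- jgl_mista(cov, pen, jgl_control(tol = 1e-8, max_iter = 4000))
    fa <- jgl_admm(cov, pen, jgl_control(tol = 1e-7))
    expect_true(all(diff(fi$trace$objective) <= 1e-12))
    expect_true(all(diff(fm$trace$objective) <= 1e-12))
    al <- fm$trace$alpha
    expect_true(all(al > 0 & al <= 1))
    expect_true(is_pd(fi$theta) && is_pd(fm$theta) && is_pd(fa$theta))
    expect_lt(frob_diff(fi$theta, fm$theta), 1e-3)
    expect_lt(frob_diff(fi$theta, fa$theta), 1e-3)
    # unpenalized ADMM recovers the per-class MLE
  }
  fa0 <- jgl_admm(cov, penalty_spec("fused", 0, 0), jgl_control(tol = 1e-9))
  for (k in 1:2)
    expect_lt(max(abs(fa0$theta[[k]] - solve(cov$S[[k]]))), 1e-4)
})

test_that("objective-error stopping terminates against a tighter reference", {
  set.seed(27)
  sim <- jgl_simulate(p = 6, K = 2, n = c(50, 50), seed = 5)
  cov <- class_covariances(sim$dataset)
  pen <- penalty_spec("fused", 0.08, 0.03)
  fit <- jgl_ista(cov, pen, jgl_control(tol = 1e-4, max_iter = 3000,
                                        stop_rule = "objective_error"))
  expect_true(fit$converged)
  ref <- jgl_ista(cov, pen, jgl_control(tol = 1e-9, max_iter = 5000))
  expect_lte(fit$objective - ref$objective, 1e-4 * 1.01)
})
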