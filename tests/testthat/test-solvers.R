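test_that("soft thresholding implements the shrinkage operator", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(c(-0.1, 0.05, 0.2), 0.2), c(0, 0, 0))
  v <- c(-2, -0.3, 0, 0.7, 5)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(sign(soft_threshold(v, 0.4)), sign(v) * (abs(v) > 0.4))
  expect_error(soft_threshold(v, -1), ">= 0")
})

test_that("Lipschitz bound matches a dense eigensolver and scales as c^2", {
  expect_equal(lipschitz_bound(diag(2)), 2.0)
  expect_equal(lipschitz_bound(diag(2), "half-objective"), 1.0)
  A <- with_seed(1, matrix(rnorm(20 * 50), 20, 50))
  lmax <- max(eigen(crossprod(A), symmetric = TRUE,
                    only.values = TRUE)$values)
  expect_equal(lipschitz_bound(A), 2 * lmax, tolerance = 1e-6)
  expect_equal(lipschitz_bound(3 * A), 9 * lipschitz_bound(A),
               tolerance = 1e-6)
  expect_error(lipschitz_bound(matrix(0, 3, 3)), "zero matrix")
})

test_that("LASSO objective agrees with elementwise recomputation", {
  prob <- tiny_lasso(1, n = 5, p = 5)
  x <- with_seed(2, rnorm(5))
  manual <- 0
  for (i in 1:5) {
    ri <- sum(prob$A[i, ] * x) - prob$y[i]
    manual <- manual + 0.5 * ri^2
  }
  manual <- manual + 0.3 * sum(abs(x))
  expect_equal(objective(prob$A, prob$y, x, 0.3), manual, tolerance = 1e-12)
  expect_equal(objective(prob$A, prob$y, numeric(5), 1),
               0.5 * sum(prob$y^2))
  expect_equal(objective(prob$A, prob$y, prob$xt, 0), 0, tolerance = 1e-18)
})

test_that("one ISTA step solves the separable proximal subproblem", {
  prob <- tiny_lasso(3, n = 10, p = 8, k = 3)
  cfg <- solver_config(alpha = 0.05, iter_max = 1)
  fit <- ista(prob$A, prob$y, cfg)
  mu <- fit$mu
  # closed-form prox of the first step from x = 0
  grad_pt <- mu * as.numeric(crossprod(prob$A, prob$y))
  expect_equal(fit$x, sign(grad_pt) * pmax(abs(grad_pt) - 0.05, 0),
               tolerance = 1e-12)
  # each coordinate minimizes (1/(2mu)) (x - v)^2 + (alpha/mu) |x|
  lam <- 0.05 / mu
  for (i in seq_along(grad_pt)) {
    f1 <- function(z) (z - grad_pt[i])^2 / (2 * mu) + lam * abs(z)
    grid <- seq(grad_pt[i] - 0.2, grad_pt[i] + 0.2, length.out = 4001)
    expect_lte(f1(fit$x[i]), min(f1(grid)) + 1e-10)
  }
})

test_that("ISTA with alpha = 0 converges to the least-squares solution", {
  A <- with_seed(4, matrix(rnorm(64), 8, 8) + 3 * diag(8))
  xt <- with_seed(5, rnorm(8))
  y <- as.numeric(A %*% xt)
  fit <- ista(A, y, solver_config(alpha = 0, epsilon = 1e-12,
                                  iter_max = 20000))
  expect_lt(rel_l2(fit$x, solve(crossprod(A), crossprod(A, y))), 1e-6)
})

test_that("all solvers return zero for zero data and are deterministic", {
  prob <- tiny_lasso(6, n = 12, p = 20, k = 3)
  z <- numeric(12)
  for (meth in c("RS-FISTA", "FISTA", "ISTA", "Landweber", "CG", "NOSER",
                 "Newton-Raphson")) {
    fit <- eit_reconstruct(prob$A, z, meth, solver_config(iter_max = 5))
    expect_equal(max(abs(fit$x)), 0, info = meth)
    f1 <- eit_reconstruct(prob$A, prob$y, meth, solver_config(iter_max = 20))
    f2 <- eit_reconstruct(prob$A, prob$y, meth, solver_config(iter_max = 20))
    expect_identical(f1$x, f2$x, info = meth)
    expect_length(f1$residual_history, f1$iterations)
    expect_length(f1$objective_history, f1$iterations)
  }
})

test_that("the Nesterov t-sequence follows its recurrence", {
  t <- nesterov_t_sequence(4)
  expect_equal(t[1], 1)
  expect_equal(t[2], (1 + sqrt(5)) / 2, tolerance = 1e-15)
  expect_equal(t[3], (1 + sqrt(1 + 4 * t[2]^2)) / 2, tolerance = 1e-15)
})

test_that("FISTA reproduces a step-by-step reference implementation", {
  prob <- tiny_lasso(7, n = 10, p = 15, k = 3)
  cfg <- solver_config(alpha = 0.03, iter_max = 6, epsilon = 1e-300)
  fit <- fista(prob$A, prob$y, NULL, cfg)
  # independent transliteration of the accelerated update
  mu <- fit$mu
  x_old <- x <- z <- numeric(15)
  t_k <- 1
  for (k in 1:6) {
    x_new <- soft_threshold(
      z - mu * as.numeric(crossprod(prob$A, prob$A %*% z - prob$y)), 0.03)
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- x_new + ((t_k - 1) / t_next) * (x_new - x)
    x_old <- x; x <- x_new; t_k <- t_next
  }
  expect_equal(fit$x, x, tolerance = 1e-14)
})

test_that("FISTA satisfies the O(1/k^2) objective bound", {
  prob <- tiny_lasso(42)
  cfg_ref <- solver_config(iter_max = 1e5, epsilon = 1e-300, alpha = 1e-4)
  ref <- fista(prob$A, prob$y, NULL, cfg_ref)
  F_star <- ref$objective_history[ref$iterations]
  L <- lipschitz_bound(prob$A)
  run <- fista(prob$A, prob$y, NULL,
               solver_config(iter_max = 300, epsilon = 1e-300, alpha = 1e-4))
  k <- seq_len(run$iterations)
  bound <- 2 * L * sum(ref$x^2) / (k + 1)^2   # x0 = 0
  expect_true(all(run$objective_history - F_star <= bound + 1e-10))
})

test_that("adaptive regularization solver honors its closed forms", {
  # A = I, fixed lambda (gamma = 0): x = y / (1 + lambda)
  y <- c(1, -2, 3)
  rs <- regularization_solver(diag(3), y,
                              solver_config(rs_lambda0 = 0.5, rs_gamma = 0,
                                            rs_tol = 1e-12, rs_iter_max = 1))
  expect_equal(rs$x0, y / 1.5, tolerance = 1e-12)
  # heavy damping crushes the solution
  rs2 <- regularization_solver(diag(3), y,
                               solver_config(rs_lambda0 = 1e6, rs_gamma = 0,
                                             rs_tol = 1e-12, rs_iter_max = 1))
  expect_lt(sqrt(sum(rs2$x0^2)), 1e-5 * sqrt(sum(y^2)))
  expect_error(regularization_solver(diag(3), y,
                                     solver_config(rs_lambda0 = -1)),
               "positive")
})

test_that("adaptive lambda trace is non-increasing while misfit persists", {
  prob <- tiny_lasso(8, n = 15, p = 40, k = 4)
  rs <- regularization_solver(prob$A, prob$y,
                              solver_config(rs_tol = 1e-10, rs_iter_max = 30))
  expect_true(all(diff(rs$trace$lambda) <= 0))
  expect_gt(nrow(rs$trace), 1L)
})

test_that("RS-FISTA matches an independent coordinate-descent LASSO solver", {
  prob <- tiny_lasso(42)
  cfg <- solver_config(alpha = 1e-3, iter_max = 5000, epsilon = 1e-300)
  fit <- rs_fista(prob$A, prob$y, cfg)
  lam <- 1e-3 / fit$mu
  g <- glmnet::glmnet(prob$A, prob$y, alpha = 1, lambda = lam / 30,
                      standardize = FALSE, intercept = FALSE, thresh = 1e-16)
  x_cd <- as.numeric(stats::coef(g))[-1]
  expect_lt(rel_l2(fit$x, x_cd), 1e-3)
})

test_that("RS-FISTA recovers a sparse truth on a determined system", {
  prob <- with_seed(43, {
    A <- matrix(rnorm(100 * 30), 100, 30)
    xt <- numeric(30)
    xt[sample(30, 5)] <- c(2, -1.5, 1, 3, -2)
    list(A = A, xt = xt, y = as.numeric(A %*% xt))
  })
  fit <- rs_fista(prob$A, prob$y,
                  solver_config(iter_max = 500, epsilon = 1e-300))
  expect_lt(rel_l2(fit$x, prob$xt), 1e-3)
})

test_that("the warm start is closer to the solution than the cold start", {
  prob <- tiny_lasso(42)
  ref <- fista(prob$A, prob$y, NULL,
               solver_config(alpha = 1e-4, iter_max = 5e4, epsilon = 1e-300))
  cfg <- solver_config(alpha = 1e-4, iter_max = 50, epsilon = 1e-300)
  rs <- rs_fista(prob$A, prob$y, cfg)
  expect_lt(sqrt(sum((rs$x0 - ref$x)^2)), sqrt(sum(ref$x^2)))
  # early-iteration advantage: strictly better at a short equal budget ...
  cold <- fista(prob$A, prob$y, NULL, cfg)
  expect_lte(rs$objective_history[rs$iterations],
             cold$objective_history[cold$iterations] + 1e-12)
  # ... and never materially worse once both runs are near convergence
  cfg2 <- solver_config(alpha = 1e-4, iter_max = 2000, epsilon = 1e-300)
  rs2 <- rs_fista(prob$A, prob$y, cfg2)
  cold2 <- fista(prob$A, prob$y, NULL, cfg2)
  expect_lte(rs2$objective_history[rs2$iterations],
             cold2$objective_history[cold2$iterations] * (1 + 1e-3))
})

test_that("Landweber: first step, fixed point, consistency", {
  prob <- with_seed(9, {
    # controlled spectrum so the relaxed iteration converges quickly
    U <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
    V <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
    A <- U %*% diag(seq(1, 2, length.out = 10)) %*% t(V)
    xt <- rnorm(10)
    list(A = A, xt = xt, y = as.numeric(A %*% xt))
  })
  f1 <- landweber(prob$A, prob$y, solver_config(iter_max = 1))
  expect_equal(f1$x,
               f1$relaxation * as.numeric(crossprod(prob$A, prob$y)),
               tolerance = 1e-12)
  # converges on a consistent well-conditioned system
  fit <- landweber(prob$A, prob$y, solver_config(iter_max = 5000))
  expect_lt(sqrt(sum((prob$A %*% fit$x - prob$y)^2)) /
              sqrt(sum(prob$y^2)), 1e-6)
  expect_true(all(diff(fit$residual_history) <= 1e-12))
})

test_that("CGNR solves small SPD systems exactly with conjugate directions", {
  A <- with_seed(10, {
    M <- matrix(rnorm(25), 5, 5)
    crossprod(M) + diag(5)
  })
  xt <- with_seed(11, rnorm(5))
  y <- as.numeric(A %*% xt)
  fit <- cg_normal(A, y, solver_config(iter_max = 5))
  expect_lte(fit$iterations, 5L)
  expect_lt(rel_l2(fit$x, solve(A, y)), 1e-8)
  # directions mutually A'A-conjugate
  G <- crossprod(A)
  P <- do.call(cbind, fit$directions)
  cross <- crossprod(P, G %*% P)
  off <- abs(cross[upper.tri(cross)]) / max(abs(diag(cross)))
  expect_lt(max(off), 1e-8)
})

test_that("NOSER is the one-step diagonally regularized Gauss-Newton", {
  prob <- tiny_lasso(12, n = 20, p = 12, k = 3)
  cfg <- solver_config(newton_r = 0.1)
  fit <- noser(prob$A, prob$y, cfg)
  expect_identical(fit$iterations, 1L)
  G <- crossprod(prob$A)
  direct <- solve(G + 0.1 * diag(diag(G)), crossprod(prob$A, prob$y))
  expect_equal(fit$x, as.numeric(direct), tolerance = 1e-10)
  # r -> 0 on a well-conditioned system: least-squares solution
  fit0 <- noser(prob$A, prob$y, solver_config(newton_r = 1e-12))
  expect_lt(rel_l2(fit0$x, solve(G, crossprod(prob$A, prob$y))), 1e-6)
})

test_that("Newton-Raphson starts at the Tikhonov solution and converges", {
  prob <- tiny_lasso(13, n = 20, p = 12, k = 3)
  cfg <- solver_config(newton_r = 0.1, iter_max = 1)
  f1 <- newton_raphson(prob$A, prob$y, cfg)
  G <- crossprod(prob$A)
  tikh <- solve(G + 0.1 * diag(12), crossprod(prob$A, prob$y))
  expect_equal(f1$x, as.numeric(tikh), tolerance = 1e-10)
  fit <- newton_raphson(prob$A, prob$y,
                        solver_config(newton_r = 0.1, iter_max = 500,
                                      epsilon = 1e-14))
  expect_lt(rel_l2(fit$x, solve(G, crossprod(prob$A, prob$y))), 1e-6)
})

test_that("the reconstruction front end validates and normalizes method names", {
  prob <- tiny_lasso(14, n = 8, p = 6, k = 2)
  expect_error(eit_reconstruct(prob$A, prob$y, "TV"), "available")
  a <- eit_reconstruct(prob$A, prob$y, "rs_FISTA", solver_config(iter_max = 10))
  b <- rs_fista(prob$A, prob$y, solver_config(iter_max = 10))
  expect_identical(a$x, b$x)
  expect_identical(eit_reconstruct(prob$A, prob$y, "noser")$method, "NOSER")
})
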