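test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-0.5, 1.0), 0.0)
  x <- matrix(c(1, -0.2, 0.05, 3), 2)
  expect_equal(soft_threshold(x, 0), x) # identity at eps = 0
  expect_equal(soft_threshold(matrix(c(1, -0.2, 0.05, 3), 2, byrow = TRUE), 0.1),
               matrix(c(0.9, -0.1, 0, 2.9), 2, byrow = TRUE))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("symmetric SVT matches hand-computable cases", {
  expect_equal(symmetric_svt(diag(c(3, 0.5)), 1), diag(c(2, 0)))
  expect_equal(symmetric_svt(matrix(0, 3, 3), 0.7), matrix(0, 3, 3))
  # symmetrizes to [[0,1],[1,0]] with singular values (1,1) -> (0.5,0.5)
  expect_equal(symmetric_svt(matrix(c(0, 0, 2, 0), 2), 0.5),
               matrix(c(0, 0.5, 0.5, 0), 2))
  expect_error(symmetric_svt(matrix(1, 2, 3), 1), "square")
})

test_that("symmetric SVT solves the nuclear-norm prox over symmetric matrices", {
  set.seed(101)
  for (rep in 1:10) {
    Q <- matrix(rnorm(16), 4)
    eps <- runif(1, 0.1, 2)
    P_impl <- symmetric_svt(Q, eps)
    P_oracle <- nuclear_prox_oracle((Q + t(Q)) / 2, eps)
    expect_lt(sqrt(sum((P_impl - P_oracle)^2)), 1e-4)
    expect_true(isSymmetric(P_impl))
  }
})

test_that("eta1 follows the spectral-norm formula", {
  expect_equal(sglrr:::compute_eta1(beta = 0, mu = 1, norm_L2 = 7, norm_X2 = 2), 5)
  expect_equal(sglrr:::compute_eta1(beta = 1, mu = 0.1, norm_L2 = 3, norm_X2 = 0), 6.1)
  expect_equal(sglrr:::compute_eta1(beta = 0, mu = 0, norm_L2 = 3, norm_X2 = 2), 0)
})

test_that("Z step reduces to SVT of the gradient-step point", {
  set.seed(5)
  X <- matrix(rnorm(15), 3, 5)
  XtX <- crossprod(X)
  Zero_n <- matrix(0, 5, 5)
  Zero_mn <- matrix(0, 3, 5)
  mu <- 0.3
  eta1 <- mu * (1 + norm(X, "2")^2)
  # zero state, beta = 0: Q = (mu/eta1) X'X
  Z1 <- sglrr:::update_Z(Zero_n, Zero_n, Zero_n, Zero_n, Zero_mn, Zero_mn,
                         X, XtX, beta = 0, mu = mu, eta1 = eta1)
  expect_equal(Z1, symmetric_svt((mu / eta1) * XtX, 1 / eta1))
  # zero data, zero state: stays at zero
  Z0 <- sglrr:::update_Z(Zero_n, diag(5), Zero_n, Zero_n, Zero_mn, Zero_mn,
                         Zero_mn, Zero_n, beta = 1, mu = mu, eta1 = 10)
  expect_equal(Z0, Zero_n)
  expect_error(sglrr:::update_Z(Zero_n, Zero_n, Zero_n, Zero_n, Zero_mn,
                                Zero_mn, X, XtX, 0, mu, eta1 = 0), "positive")
})

test_that("Z step agrees with a numerical minimizer of the linearized subproblem", {
  set.seed(23)
  X <- matrix(rnorm(20), 4, 5)
  XtX <- crossprod(X)
  L <- graph_laplacian(1 - diag(5))$L
  Z <- crossprod(matrix(rnorm(25), 5)) / 5
  J <- pmax(Z - 0.1, 0)
  E <- matrix(rnorm(20, sd = 0.1), 4, 5)
  Y1 <- matrix(rnorm(20, sd = 0.1), 4, 5)
  Y2 <- matrix(rnorm(25, sd = 0.1), 5, 5)
  beta <- 0.5
  mu <- 0.7
  eta1 <- sglrr:::compute_eta1(beta, mu, norm(L, "2"), norm(X, "2"))
  Z_impl <- sglrr:::update_Z(Z, L, J, Y2, E, Y1, X, XtX, beta, mu, eta1)
  # the linearized subproblem min ||Z||_* + <g, Z-Zk> + eta1/2 ||Z-Zk||_F^2
  # over symmetric Z is the symmetric nuclear prox at Q = Zk - g/eta1
  G <- sglrr:::grad_q_Z(Z, L, J, Y2, E, Y1, X, XtX, beta, mu)
  Q <- Z - G / eta1
  Z_oracle <- nuclear_prox_oracle((Q + t(Q)) / 2, 1 / eta1)
  expect_lt(sqrt(sum((Z_impl - Z_oracle)^2)), 1e-4)
})

test_that("E and J updates are the stated elementwise shrinkages", {
  A <- matrix(c(1, 0.05, -0.2, 3), 2)
  mu <- 2
  X <- A
  Zn <- matrix(0, 2, 2)
  Y1 <- matrix(0, 2, 2)
  expect_equal(sglrr:::update_E(X, Zn, Y1, mu, gamma = 0.2),
               matrix(c(0.9, 0, -0.1, 2.9), 2))
  expect_equal(sglrr:::update_E(X, Zn, Y1, mu, gamma = 8), matrix(0, 2, 2))
  expect_equal(sglrr:::update_E(X, Zn, Y1, mu, gamma = 0), X)

  B <- matrix(c(0.5, -0.3, -0.3, 0.2), 2)
  Y2 <- matrix(0, 2, 2)
  expect_equal(sglrr:::update_J(B, Y2, mu = 1, lambda = 0.1),
               matrix(c(0.4, 0, 0, 0.1), 2))
  expect_equal(sglrr:::update_J(-abs(B), Y2, 1, 0.1), matrix(0, 2, 2))
  nonneg <- matrix(c(0.5, 0.3, 0.3, 0.2), 2)
  expect_equal(sglrr:::update_J(nonneg, Y2, 1, 0), nonneg)
})

test_that("zero data converges immediately to the zero solution", {
  x <- expression_matrix(matrix(0, 3, 4))
  g <- knn_graph(x, k = 1)
  sol <- solve_sglrr(x, g)
  expect_true(sol$converged)
  expect_equal(sol$n_iter, 1L)
  expect_equal(sol$Z, matrix(0, 4, 4))
  expect_equal(unname(sol$E), matrix(0, 3, 4))
})

test_that("solver meets its contract on 2-subspace data", {
  d <- subspace_data(2, 3, 30, 20, noise_sigma = 0.01, seed = 42)
  g <- knn_graph(d$x, k = 5)
  ctl <- sglrr_control()
  sol <- solve_sglrr(d$x, g, ctl)
  expect_true(sol$converged)
  last <- sol$residuals[sol$n_iter, ]
  expect_lte(last$primal, ctl$tol_primal)
  expect_lte(max(abs(sol$Z - t(sol$Z))), 1e-3)
  expect_true(all(sol$J >= 0)) # exact nonnegativity
  expect_true(all(diff(sol$residuals$mu) >= 0)) # mu nondecreasing
  expect_lte(max(sol$residuals$mu), ctl$mu_max)
})

test_that("clean single-subspace data needs almost no error term", {
  d <- subspace_data(1, 3, 20, 15, noise_sigma = 0, seed = 9)
  g <- knn_graph(d$x, k = 5)
  sol <- solve_sglrr(d$x, g, sglrr_control(gamma = 50))
  expect_lte(sqrt(sum(sol$E^2)) / sqrt(sum(d$x^2)), 1e-3)
})

test_that("solver is deterministic: identical inputs give identical iterates", {
  d <- subspace_data(2, 2, 15, 8, noise_sigma = 0.05, seed = 3)
  g <- knn_graph(d$x, k = 3)
  s1 <- solve_sglrr(d$x, g)
  s2 <- solve_sglrr(d$x, g)
  expect_identical(s1$Z, s2$Z)
  expect_identical(s1$residuals, s2$residuals)
})

test_that("with lambda = beta = 0 within-subspace affinity dominates", {
  d <- subspace_data(2, 2, 30, 15, noise_sigma = 1e-4, seed = 77)
  g <- knn_graph(d$x, k = 5)
  sol <- solve_sglrr(d$x, g, sglrr_control(lambda = 0, beta = 0))
  H <- affinity_matrix(sol$Z, tol_sym = 1e-3)$H
  same <- outer(d$labels, d$labels, "==") & upper.tri(H)
  diff <- outer(d$labels, d$labels, "!=") & upper.tri(H)
  expect_gt(mean(H[same]), mean(H[diff]))
})

test_that("non-convergence warns and reports converged = FALSE", {
  d <- subspace_data(2, 2, 15, 8, noise_sigma = 0.05, seed = 3)
  g <- knn_graph(d$x, k = 3)
  expect_warning(sol <- solve_sglrr(d$x, g, sglrr_control(max_iter = 3)),
                 "did not converge")
  expect_false(sol$converged)
  expect_equal(sol$n_iter, 3L)
})

test_that("control validates its arguments", {
  expect_error(sglrr_control(gamma = 0))
  expect_error(sglrr_control(rho = 1))
  expect_error(sglrr_control(mu0 = 10, mu_max = 1))
})
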