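#' Solver settings for the sgLRR objective
#'
#' Collects the regularization weights and LADMAP (linearized ADMM with
#' adaptive penalty) controls for [solve_sglrr()].
#'
#' The objective solved is
#' \deqn{\min_{Z,E} \|Z\|_* + \lambda\|Z\|_1 + \beta\,tr(Z L Z^T) + \gamma\|E\|_1
#'       \quad s.t.\ X = XZ + E,\ Z = Z^T,}
#' where the nuclear norm drives Z toward low rank, the elementwise L1 term
#' (carried by an auxiliary variable J) sparsifies it, the trace term couples
#' representation rows of neighboring samples through the graph Laplacian L,
#' and E absorbs sparse gross corruption.
#'
#' No canonical values for `lambda`, `beta`, `gamma` exist for expression
#' data; the defaults are working starting points and should be treated as
#' tunable.
#'
#' @param lambda Weight of the sparsity penalty on Z (via J), >= 0.
#' @param beta Weight of the graph-regularization term tr(ZLZ^T), >= 0.
#' @param gamma Weight of the L1 penalty on the error matrix E, > 0.
#' @param mu0 Initial ADMM penalty, > 0.
#' @param rho Penalty growth factor per iteration, > 1.
#' @param mu_max Penalty cap; mu is nondecreasing and never exceeds it.
#' @param tol_primal Relative primal feasibility tolerance
#'   ||X - XZ - E||_F / ||X||_F.
#' @param tol_change Tolerance on max(||Z - J||_inf, iterate change in Z).
#' @param max_iter Iteration cap.
#' @param k_neighbors Neighbor count used when the caller builds the graph.
#' @param scale_mu0 If `TRUE`, mu0 is divided by the spectral norm of X so
#'   the initial penalty is scale-free.
#' @return A list of class `sglrr_control`.
#' @export
sglrr_control <- function(lambda = 0.1, beta = 1.0, gamma = 0.5,
                          mu0 = 1e-2, rho = 1.1, mu_max = 1e6,
                          tol_primal = 1e-4, tol_change = 1e-4,
                          max_iter = 500L, k_neighbors = 5L,
                          scale_mu0 = FALSE) {
  stopifnot(lambda >= 0, beta >= 0, gamma > 0, mu0 > 0, rho > 1,
            mu0 <= mu_max, tol_primal > 0, tol_change > 0, max_iter >= 1)
  structure(list(lambda = lambda, beta = beta, gamma = gamma, mu0 = mu0,
                 rho = rho, mu_max = mu_max, tol_primal = tol_primal,
                 tol_change = tol_change, max_iter = as.integer(max_iter),
                 k_neighbors = as.integer(k_neighbors),
                 scale_mu0 = isTRUE(scale_mu0)),
            class = "sglrr_control")
}

#' Elementwise soft-thresholding (shrinkage) operator
#'
#' `sgn(x) * max(|x| - eps, 0)`, the proximal operator of `eps * |.|`.
#'
#' @param x Numeric scalar, vector or matrix.
#' @param eps Threshold, >= 0.
#' @return Same shape as `x`.
#' @examples
#' soft_threshold(c(1.2, -0.5), 0.5)
#' @export
soft_threshold <- function(x, eps) {
  if (length(eps) != 1L || is.na(eps) || eps < 0) {
    stop("eps must be a single nonnegative number", call. = FALSE)
  }
  sign(x) * pmax(abs(x) - eps, 0)
}

#' Symmetric singular-value thresholding
#'
#' Proximal operator of the nuclear norm restricted to symmetric matrices:
#' symmetrizes Q, takes its skinny SVD (positive singular values only) and
#' soft-thresholds the singular values by `eps`. The result minimizes
#' `eps * ||P||_* + 0.5 * ||P - Q||_F^2` over symmetric P.
#'
#' @param Q Square numeric matrix.
#' @param eps Threshold on the singular values, > 0 (0 allowed, then only
#'   symmetrization happens).
#' @return Symmetric matrix of the same size.
#' @examples
#' symmetric_svt(diag(c(3, 0.5)), 1) # diag(2, 0)
#' @export
symmetric_svt <- function(Q, eps) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square", call. = FALSE)
  if (!all(is.finite(Q))) stop("Q must be finite", call. = FALSE)
  if (length(eps) != 1L || is.na(eps) || eps < 0) {
    stop("eps must be a single nonnegative number", call. = FALSE)
  }
  Qs <- (Q + t(Q)) / 2
  sv <- svd(Qs)
  # skinny SVD: drop numerically zero singular values
  keep <- sv$d > 1e-10 * sv$d[1L] & sv$d > 0
  if (!any(keep)) return(matrix(0, nrow(Q), ncol(Q)))
  d <- pmax(sv$d[keep] - eps, 0)
  P <- sv$u[, keep, drop = FALSE] %*% (d * t(sv$v[, keep, drop = FALSE]))
  (P + t(P)) / 2 # kill roundoff asymmetry
}

# Lipschitz-type constant of the linearized Z-subproblem:
# eta1 = 2*beta*||L||_2 + mu*(1 + ||X||_2^2), spectral norms.
compute_eta1 <- function(beta, mu, norm_L2, norm_X2) {
  2 * beta * norm_L2 + mu * (1 + norm_X2^2)
}

# gradient of the smooth part q(Z) of the augmented Lagrangian at Z_k
grad_q_Z <- function(Z, L, J, Y2, E, Y1, X, XtX, beta, mu) {
  beta * (Z %*% t(L) + Z %*% L) +
    mu * (Z - J + Y2 / mu) +
    mu * (XtX %*% Z - crossprod(X, X - E + Y1 / mu))
}

# one linearized proximal step for Z: Q = Z - grad/eta1, then symmetric SVT
update_Z <- function(Z, L, J, Y2, E, Y1, X, XtX, beta, mu, eta1) {
  if (eta1 <= 0) stop("eta1 must be positive", call. = FALSE)
  G <- grad_q_Z(Z, L, J, Y2, E, Y1, X, XtX, beta, mu)
  symmetric_svt(Z - G / eta1, 1 / eta1)
}

update_E <- function(X, Z_next, Y1, mu, gamma) {
  soft_threshold(X - X %*% Z_next + Y1 / mu, gamma / mu)
}

update_J <- function(Z_next, Y2, mu, lambda) {
  pmax(soft_threshold(Z_next + Y2 / mu, lambda / mu), 0)
}

#' Solve the sgLRR objective by LADMAP
#'
#' Linearized alternating-direction method with adaptive penalty. Each
#' iteration (all variables zero-initialized, the LADMAP convention):
#' a linearized proximal step for Z solved in closed form by
#' [symmetric_svt()]; elementwise shrinkage for the error E and for the
#' nonnegative sparse auxiliary J; gradient-ascent multiplier updates; and
#' the penalty update `mu <- min(rho * mu, mu_max)`. Stops when both the
#' relative primal residual `||X - XZ - E||_F / ||X||_F` falls below
#' `tol_primal` and `max(||Z - J||_inf, change in Z)` falls below
#' `tol_change`.
#'
#' @param x Expression matrix (features x samples).
#' @param graph A `knn_graph` on the same samples (see [knn_graph()]), or any
#'   list carrying a Laplacian `L`.
#' @param control Solver settings from [sglrr_control()].
#' @return Object of class `sglrr_solution`: `Z` (n x n, symmetric), `E`
#'   (m x n sparse error), `J` (nonnegative sparse companion of Z),
#'   `converged`, `n_iter`, and `residuals`, a data frame with one row per
#'   iteration (columns `primal`, `zj_inf`, `z_change`, `mu`).
#' @export
solve_sglrr <- function(x, graph, control = sglrr_control()) {
  X <- expression_matrix(x)
  if (!inherits(control, "sglrr_control")) {
    stop("control must come from sglrr_control()", call. = FALSE)
  }
  L <- graph$L
  n <- ncol(X)
  if (is.null(L) || nrow(L) != n) {
    stop("graph Laplacian must be n x n for the n samples of x", call. = FALSE)
  }

  XtX <- crossprod(X)
  norm_XF <- sqrt(sum(X^2))
  norm_X2 <- if (norm_XF == 0) 0 else svd(X, nu = 0, nv = 0)$d[1L]
  norm_L2 <- max(abs(eigen(L, symmetric = TRUE, only.values = TRUE)$values))

  ctl <- control
  mu <- if (ctl$scale_mu0 && norm_X2 > 0) ctl$mu0 / norm_X2 else ctl$mu0
  Z <- J <- matrix(0, n, n)
  E <- Y1 <- matrix(0, nrow(X), n)
  Y2 <- matrix(0, n, n)

  hist_primal <- hist_zj <- hist_dz <- hist_mu <- numeric(ctl$max_iter)
  converged <- FALSE
  it <- 0L
  while (it < ctl$max_iter) {
    it <- it + 1L
    eta1 <- compute_eta1(ctl$beta, mu, norm_L2, norm_X2)
    Z_new <- update_Z(Z, L, J, Y2, E, Y1, X, XtX, ctl$beta, mu, eta1)
    E_new <- update_E(X, Z_new, Y1, mu, ctl$gamma)
    J_new <- update_J(Z_new, Y2, mu, ctl$lambda)
    if (!all(is.finite(Z_new)) || !all(is.finite(E_new))) {
      stop("non-finite iterate at iteration ", it,
           "; consider a smaller rho or larger mu0", call. = FALSE)
    }

    R1 <- X - X %*% Z_new - E_new
    R2 <- Z_new - J_new
    Y1 <- Y1 + mu * R1
    Y2 <- Y2 + mu * R2

    primal <- if (norm_XF > 0) sqrt(sum(R1^2)) / norm_XF else sqrt(sum(R1^2))
    zj_inf <- max(abs(R2))
    z_change <- max(abs(Z_new - Z))
    hist_primal[it] <- primal
    hist_zj[it] <- zj_inf
    hist_dz[it] <- z_change
    hist_mu[it] <- mu

    Z <- Z_new
    E <- E_new
    J <- J_new

    if (primal <= ctl$tol_primal && max(zj_inf, z_change) <= ctl$tol_change) {
      converged <- TRUE
      break
    }
    mu <- min(ctl$rho * mu, ctl$mu_max)
  }
  if (!converged) {
    warning("sgLRR solver did not converge in ", ctl$max_iter,
            " iterations (primal residual ", signif(hist_primal[it], 3), ")",
            call. = FALSE)
  }
  structure(list(
    Z = Z, E = E, J = J,
    converged = converged, n_iter = it,
    residuals = data.frame(iteration = seq_len(it),
                           primal = hist_primal[seq_len(it)],
                           zj_inf = hist_zj[seq_len(it)],
                           z_change = hist_dz[seq_len(it)],
                           mu = hist_mu[seq_len(it)]),
    control = ctl
  ), class = "sglrr_solution")
}

#' @export
print.sglrr_solution <- function(x, ...) {
  cat(sprintf("sgLRR solution: %d x %d representation, %s after %d iterations\n",
              nrow(x$Z), ncol(x$Z),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  last <- x$residuals[x$n_iter, ]
  cat(sprintf("  primal residual %.3e, ||Z - J||_inf %.3e\n",
              last$primal, last$zj_inf))
  invisible(x)
}
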