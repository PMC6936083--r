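#' Fit the sgLRR subspace-clustering model
#'
#' One-stop fitting function: builds the k-nearest-neighbor graph over the
#' sample columns, solves the graph-regularized low-rank representation
#' objective with symmetric and sparse constraints by LADMAP, converts the
#' representation into an angular-similarity affinity matrix, and (when
#' `n_clusters` is given) partitions the samples by normalized-cuts spectral
#' clustering.
#'
#' The model expresses each sample as a linear combination of all samples,
#' `X = XZ + E`, with Z simultaneously low-rank (nuclear norm), sparse
#' (elementwise L1 via the nonnegative auxiliary J), symmetric (so mutual
#' similarities agree) and smooth over the neighbor graph
#' (`beta * tr(Z L Z^T)`); E absorbs sparse gross errors (L1). A
#' near-block-diagonal Z reveals the subspace membership of the samples.
#'
#' @param x Expression matrix, features x samples (see
#'   [expression_matrix()]); a data frame is coerced.
#' @param n_clusters Number of clusters to extract; `NULL` skips the
#'   clustering step (the representation and affinity are still computed).
#' @param lambda,beta,gamma Regularization weights, see [sglrr_control()].
#' @param k_neighbors Neighbors for the graph Laplacian (default 5).
#' @param control Full solver settings; overrides the individual weight
#'   arguments when supplied.
#' @param normalization Optional preprocessing of the columns: `"none"`
#'   (default), `"per_sample_l2"`, or `"log2p1"`.
#' @param seed Seed for the k-means++ step of the clustering.
#' @param n_init k-means restarts inside the spectral step.
#' @return Object of class `sglrr` with components `Z` (symmetric n x n
#'   representation), `E` (sparse error), `J`, `affinity`
#'   (an `affinity_matrix`), `graph` (the `knn_graph`), `clustering` (an
#'   `ncut_clustering` or `NULL`), `labels` (named cluster labels or
#'   `NULL`), `converged`, `n_iter`, `residuals`, `control`, `x` (the
#'   normalized input) and `call`.
#' @seealso [solve_sglrr()], [affinity_matrix()], [ncut_cluster()],
#'   [repeated_cluster_metrics()]
#' @examples
#' d <- subspace_data(2, 3, 30, 15, noise_sigma = 0.01, seed = 7)
#' fit <- sglrr(d$x, n_clusters = 2, seed = 7)
#' table(fit$labels, d$labels)
#' @export
sglrr <- function(x, n_clusters = NULL, lambda = 0.1, beta = 1.0,
                  gamma = 0.5, k_neighbors = 5L, control = NULL,
                  normalization = c("none", "per_sample_l2", "log2p1"),
                  seed = NULL, n_init = 20L) {
  cl <- match.call()
  x <- expression_matrix(x)
  normalization <- match.arg(normalization)
  x <- normalize_expression(x, normalization)
  if (is.null(control)) {
    control <- sglrr_control(lambda = lambda, beta = beta, gamma = gamma,
                             k_neighbors = k_neighbors)
  }
  n <- ncol(x)
  if (!is.null(n_clusters) && (n_clusters < 1L || n_clusters > n)) {
    stop("n_clusters must be between 1 and the number of samples (", n, ")",
         call. = FALSE)
  }

  graph <- knn_graph(x, k = control$k_neighbors)
  sol <- solve_sglrr(x, graph, control)
  aff <- affinity_matrix(sol$Z, tol_sym = 10 * control$tol_primal)

  clustering <- NULL
  labels <- NULL
  if (!is.null(n_clusters)) {
    clustering <- ncut_cluster(aff, k = n_clusters, seed = seed,
                               n_init = n_init)
    labels <- stats::setNames(clustering$labels, colnames(x))
  }

  structure(list(
    Z = sol$Z, E = sol$E, J = sol$J,
    affinity = aff, graph = graph,
    clustering = clustering, labels = labels,
    converged = sol$converged, n_iter = sol$n_iter,
    residuals = sol$residuals,
    control = control, normalization = normalization,
    x = x, call = cl
  ), class = "sglrr")
}

#' @export
print.sglrr <- function(x, ...) {
  cat("sgLRR fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  data: %d features x %d samples (normalization: %s)\n",
              nrow(x$x), ncol(x$x), x$normalization))
  cat(sprintf("  solver: %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (!is.null(x$labels)) {
    cat(sprintf("  clusters: %d\n", x$clustering$n_clusters))
    print(table(cluster = x$labels))
  } else {
    cat("  clustering: not requested\n")
  }
  invisible(x)
}

#' @export
summary.sglrr <- function(object, ...) {
  sv <- svd(object$Z, nu = 0, nv = 0)$d
  r <- sum(sv > 1e-10 * max(sv, .Machine$double.eps))
  last <- object$residuals[object$n_iter, ]
  out <- list(
    call = object$call,
    dims = dim(object$x),
    converged = object$converged,
    n_iter = object$n_iter,
    primal_residual = last$primal,
    zj_residual = last$zj_inf,
    rank_Z = r,
    asym_Z = max(abs(object$Z - t(object$Z))),
    error_mass = sum(abs(object$E)) / max(sum(abs(object$x)), .Machine$double.eps),
    control = object$control,
    cluster_sizes = if (!is.null(object$labels)) table(object$labels) else NULL
  )
  class(out) <- "summary.sglrr"
  out
}

#' @export
print.summary.sglrr <- function(x, ...) {
  cat("sgLRR fit summary\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  data: %d features x %d samples\n", x$dims[1L], x$dims[2L]))
  cat(sprintf("  lambda = %g, beta = %g, gamma = %g, k = %d\n",
              x$control$lambda, x$control$beta, x$control$gamma,
              x$control$k_neighbors))
  cat(sprintf("  %s after %d iterations (primal %.2e, ||Z-J||_inf %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$primal_residual, x$zj_residual))
  cat(sprintf("  rank(Z) = %d, max|Z - Z'| = %.2e, |E|_1 / |X|_1 = %.3f\n",
              x$rank_Z, x$asym_Z, x$error_mass))
  if (!is.null(x$cluster_sizes)) {
    cat("  cluster sizes:\n")
    print(x$cluster_sizes)
  }
  invisible(x)
}

#' @export
coef.sglrr <- function(object, ...) object$Z

#' @export
fitted.sglrr <- function(object, ...) object$x %*% object$Z

#' @export
residuals.sglrr <- function(object, ...) object$E

#' Heat map of the learned affinity matrix
#'
#' Plots H with samples optionally ordered by cluster label so the block
#' structure is visible.
#'
#' @param x An `sglrr` fit.
#' @param order_by_cluster Reorder samples by cluster label when available.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sglrr <- function(x, order_by_cluster = TRUE, ...) {
  H <- x$affinity$H
  ord <- if (order_by_cluster && !is.null(x$labels)) order(x$labels)
         else seq_len(nrow(H))
  n <- nrow(H)
  graphics::image(seq_len(n), seq_len(n), H[ord, rev(ord)],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "sample", ylab = "sample",
                  main = "sgLRR affinity matrix", useRaster = TRUE, ...)
  invisible(x)
}
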