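#' k-nearest-neighbor graph over the sample columns
#'
#' Builds the binary sample-adjacency graph that carries the manifold
#' (local-geometry) penalty: an edge `w_ij = 1` is set whenever sample i is
#' among the k nearest neighbors of sample j *or* vice versa (the OR rule,
#' which makes W symmetric by construction). Distances are computed between
#' sample columns; a sample is never its own neighbor, so the diagonal of W
#' is zero. Distance ties are broken toward the lower sample index, making
#' the graph deterministic; duplicate columns (distance 0) always include
#' each other.
#'
#' @param x Expression matrix, features x samples (validated via
#'   [expression_matrix()]).
#' @param k Number of nearest neighbors, `1 <= k <= n-1`. The conventional
#'   default for expression data is 5.
#' @param metric Distance between sample columns; Euclidean by default, any
#'   method accepted by [stats::dist()].
#' @return An object of class `knn_graph`: list with the binary weight matrix
#'   `W`, diagonal degree matrix `D`, unnormalized Laplacian `L = D - W`
#'   (symmetric positive semi-definite, rows summing to zero) and `k`.
#' @examples
#' x <- expression_matrix(rbind(c(0, 1, 10)))
#' g <- knn_graph(x, k = 1)
#' g$W
#' @export
knn_graph <- function(x, k = 5L, metric = "euclidean") {
  x <- expression_matrix(x)
  n <- ncol(x)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n - 1L) {
    stop("k must satisfy 1 <= k <= n-1 (n = ", n, "), got ", k, call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(t(x), method = metric))
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    cand <- setdiff(seq_len(n), j)
    # order() is stable: equal distances resolve to the lower sample index
    nb <- cand[order(dmat[cand, j])][seq_len(k)]
    W[nb, j] <- 1
  }
  W <- pmax(W, t(W)) # OR rule: i in N_k(j) or j in N_k(i)
  out <- c(graph_laplacian(W), list(k = k, metric = metric))
  class(out) <- "knn_graph"
  out
}

#' Degree matrix and unnormalized graph Laplacian
#'
#' Given a binary symmetric weight matrix with zero diagonal, returns the
#' diagonal degree matrix `D` (`d_ii` = row sum of W) and the Laplacian
#' `L = D - W`.
#'
#' @param W Symmetric binary weight matrix with zero diagonal.
#' @return List with components `W`, `D` and `L`.
#' @export
graph_laplacian <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (!isSymmetric(unname(W), tol = 0)) {
    stop("W must be exactly symmetric", call. = FALSE)
  }
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  deg <- rowSums(W)
  D <- diag(deg, nrow(W))
  list(W = W, D = D, L = D - W)
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("k-nearest-neighbor graph: %d samples, k = %d (%s distance)\n",
              nrow(x$W), x$k, x$metric))
  cat(sprintf("  edges: %d, degree range: [%d, %d]\n",
              sum(x$W) / 2, min(diag(x$D)), max(diag(x$D))))
  invisible(x)
}
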