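# run expr with a locally set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# k-means++ seeding: first center uniform, later centers with prob
# proportional to squared distance from the nearest chosen center
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- colSums((t(X) - X[idx[1L], ])^2)
    for (j in seq_len(k - 1L)) {
      if (sum(d2) <= 0) {
        # all remaining points coincide with chosen centers; take any unused
        left <- setdiff(seq_len(n), idx[seq_len(j)])
        idx[j + 1L] <- left[1L]
      } else {
        idx[j + 1L] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, colSums((t(X) - X[idx[j + 1L], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

kmeans_pp <- function(X, k, n_init = 20L, iter_max = 100L) {
  if (nrow(unique(X)) < k) {
    stop("fewer than k distinct points in the spectral embedding", call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_centers(X, k)
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Normalized-cuts spectral clustering of an affinity matrix
#'
#' Ng-Jordan-Weiss realization of normalized cuts: form the symmetric
#' normalized Laplacian `I - D^{-1/2} H D^{-1/2}`, take the k eigenvectors of
#' smallest eigenvalue, row-normalize the n x k embedding to unit length, and
#' cluster the rows by k-means (squared Euclidean distance, k-means++
#' initialization, `n_init` restarts keeping the lowest within-cluster sum of
#' squares).
#'
#' @param H An `affinity_matrix` from [affinity_matrix()], or a plain
#'   symmetric nonnegative matrix with unit diagonal.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Optional integer seed controlling the k-means++ draws; the
#'   caller's RNG state is left untouched.
#' @param n_init Number of k-means restarts.
#' @return Object of class `ncut_clustering`: `labels` (integer vector in
#'   `1..k`), `n_clusters`, and `withinss` (total within-cluster sum of
#'   squares of the winning k-means run).
#' @examples
#' H <- affinity_matrix(diag(4))
#' ncut_cluster(H, k = 1)$labels
#' @export
ncut_cluster <- function(H, k, seed = NULL, n_init = 20L) {
  Hm <- if (inherits(H, "affinity_matrix")) H$H else as.matrix(H)
  n <- nrow(Hm)
  if (n != ncol(Hm)) stop("H must be square", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  if (k == 1L) {
    return(structure(list(labels = rep(1L, n), n_clusters = 1L, withinss = 0),
                     class = "ncut_clustering"))
  }
  deg <- rowSums(Hm)
  if (any(deg <= 0)) stop("zero-degree sample in affinity matrix", call. = FALSE)
  s <- 1 / sqrt(deg)
  A <- Hm * outer(s, s) # D^{-1/2} H D^{-1/2}
  A <- (A + t(A)) / 2
  # smallest eigenvalues of I - A are the largest of A
  U <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  fit <- with_seed(seed, kmeans_pp(U, k, n_init = n_init))
  structure(list(labels = as.integer(fit$cluster), n_clusters = k,
                 withinss = fit$tot.withinss),
            class = "ncut_clustering")
}

#' @export
print.ncut_clustering <- function(x, ...) {
  cat(sprintf("normalized-cuts clustering: %d samples in %d clusters\n",
              length(x$labels), x$n_clusters))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Repeated spectral clustering with averaged evaluation metrics
#'
#' k-means++ initialization is random, so single clustering runs differ;
#' the standard protocol is to repeat the clustering and report the mean of
#' each evaluation metric. Each repeat uses a seed derived deterministically
#' from the master seed.
#'
#' @param H Affinity matrix (see [ncut_cluster()]).
#' @param k Number of clusters.
#' @param true_labels Ground-truth labels, length n.
#' @param n_repeats Number of repeats (conventionally 50).
#' @param seed Master seed; fixes the whole experiment.
#' @param n_init k-means restarts within each repeat.
#' @return Object of class `repeated_clustering`: `mean` and `sd` (named
#'   vectors over acc/mcc/ri/nmi), `per_run` (n_repeats x 4 matrix),
#'   `labels` (from the first repeat) and `n_repeats`.
#' @export
repeated_cluster_metrics <- function(H, k, true_labels, n_repeats = 50L,
                                     seed = NULL, n_init = 20L) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_repeats))
  per_run <- matrix(NA_real_, n_repeats, 4L,
                    dimnames = list(NULL, c("acc", "mcc", "ri", "nmi")))
  first <- NULL
  for (r in seq_len(n_repeats)) {
    cl <- ncut_cluster(H, k, seed = seeds[r], n_init = n_init)
    if (r == 1L) first <- cl
    per_run[r, ] <- unlist(clustering_metrics(true_labels, cl$labels))
  }
  structure(list(
    mean = colMeans(per_run),
    sd = apply(per_run, 2L, stats::sd),
    per_run = per_run,
    labels = first$labels,
    n_repeats = n_repeats
  ), class = "repeated_clustering")
}

#' @export
print.repeated_clustering <- function(x, ...) {
  cat(sprintf("clustering metrics over %d repeats (mean +/- sd):\n",
              x$n_repeats))
  for (m in names(x$mean)) {
    cat(sprintf("  %-4s %6.4f +/- %6.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
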