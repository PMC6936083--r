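#' Union-of-subspaces synthetic expression data
#'
#' Generates the data structure the representation model assumes: each
#' cluster of samples lies on its own low-dimensional linear subspace of
#' feature space, with additive Gaussian measurement noise and optional
#' sparse gross corruption (mimicking heavy-tailed expression artifacts).
#' When `n_subspaces * subspace_dim <= ambient_dim` the subspace bases are
#' carved from one random orthonormal frame, so their spans are disjoint
#' (the independent-subspace regime); otherwise each basis is drawn
#' independently.
#'
#' Subspace coefficients are standard normal, which is scale-free for the
#' cosine-based affinity downstream. Corruption hits each entry
#' independently with probability `corruption_fraction` and adds a value
#' uniform on `[-corruption_scale, corruption_scale]`.
#'
#' @param n_subspaces Number of subspaces (clusters), >= 1.
#' @param subspace_dim Intrinsic dimension of each subspace, >= 1.
#' @param ambient_dim Number of features m.
#' @param samples_per_subspace Samples drawn from each subspace.
#' @param noise_sigma Standard deviation of the elementwise Gaussian noise.
#' @param corruption_fraction Probability that an entry is corrupted,
#'   in `[0, 1]`.
#' @param corruption_scale Half-width of the uniform corruption magnitude.
#' @param nonneg_shift If `TRUE`, shift the matrix by its minimum and clip
#'   at 0 to mimic nonnegative expression intensities (off by default).
#' @param seed Optional integer seed; output is bit-reproducible given it.
#' @return List with `x` (validated expression matrix, `ambient_dim` x
#'   `n_subspaces * samples_per_subspace`) and `labels` (integer vector of
#'   generating subspaces, 1-based, balanced by construction).
#' @examples
#' d <- subspace_data(2, 2, 10, 5, noise_sigma = 0, seed = 1)
#' qr(d$x)$rank <= 4
#' @export
subspace_data <- function(n_subspaces = 3L, subspace_dim = 4L,
                          ambient_dim = 50L, samples_per_subspace = 40L,
                          noise_sigma = 0.01, corruption_fraction = 0,
                          corruption_scale = 0, nonneg_shift = FALSE,
                          seed = NULL) {
  n_subspaces <- as.integer(n_subspaces)
  subspace_dim <- as.integer(subspace_dim)
  ambient_dim <- as.integer(ambient_dim)
  samples_per_subspace <- as.integer(samples_per_subspace)
  stopifnot(n_subspaces >= 1L, subspace_dim >= 1L,
            samples_per_subspace >= 1L, noise_sigma >= 0,
            corruption_fraction >= 0, corruption_fraction <= 1,
            corruption_scale >= 0)
  if (subspace_dim > ambient_dim) {
    stop("subspace_dim must not exceed ambient_dim", call. = FALSE)
  }
  n <- n_subspaces * samples_per_subspace
  if (n < 2L) stop("need at least 2 samples in total", call. = FALSE)

  with_seed(seed, {
    independent <- n_subspaces * subspace_dim <= ambient_dim
    if (independent) {
      frame <- qr.Q(qr(matrix(stats::rnorm(ambient_dim * n_subspaces * subspace_dim),
                              ambient_dim)))
      bases <- lapply(seq_len(n_subspaces), function(s) {
        frame[, (s - 1L) * subspace_dim + seq_len(subspace_dim), drop = FALSE]
      })
    } else {
      bases <- lapply(seq_len(n_subspaces), function(s) {
        qr.Q(qr(matrix(stats::rnorm(ambient_dim * subspace_dim), ambient_dim)))
      })
    }
    X <- matrix(0, ambient_dim, n)
    labels <- integer(n)
    for (s in seq_len(n_subspaces)) {
      cols <- (s - 1L) * samples_per_subspace + seq_len(samples_per_subspace)
      coef <- matrix(stats::rnorm(subspace_dim * samples_per_subspace),
                     subspace_dim)
      X[, cols] <- bases[[s]] %*% coef
      labels[cols] <- s
    }
    if (noise_sigma > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sigma),
                      nrow(X))
    }
    if (corruption_fraction > 0 && corruption_scale > 0) {
      hit <- stats::runif(length(X)) < corruption_fraction
      X[hit] <- X[hit] + stats::runif(sum(hit), -corruption_scale,
                                      corruption_scale)
    }
    if (nonneg_shift) {
      X <- pmax(X - min(X), 0)
    }
    x <- expression_matrix(
      X,
      feature_ids = paste0("gene_", seq_len(ambient_dim)),
      sample_ids = paste0("sample_", seq_len(n))
    )
    list(x = x, labels = labels)
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits the expression matrix in the TSV layout [read_expression_matrix()]
#' reads, plus a `sample_id,label` CSV.
#'
#' @param data A list from [subspace_data()].
#' @param matrix_path Output path for the expression TSV.
#' @param labels_path Output path for the labels CSV.
#' @return Invisibly, a list of the two paths.
#' @export
write_subspace_data <- function(data, matrix_path, labels_path) {
  write_expression_matrix(data$x, matrix_path)
  write_labels(stats::setNames(data$labels, colnames(data$x)), labels_path)
  invisible(list(matrix = matrix_path, labels = labels_path))
}
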