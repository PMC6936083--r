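#' Angular-similarity affinity matrix from a symmetric representation
#'
#' Converts the low-rank representation Z* into the affinity graph used for
#' spectral clustering. Z* is decomposed by skinny SVD (positive singular
#' values only), the rows of `M = U sqrt(Sigma)` give each sample a
#' principal-direction coordinate, and the affinity is the squared cosine of
#' the angle between those rows:
#' \deqn{H_{ij} = (m_i^T m_j / (\|m_i\| \|m_j\|))^2.}
#' Squaring removes the sign ambiguity of singular vectors; cosines make H
#' invariant to positive rescaling of Z. For symmetric Z the alternative
#' `N = sqrt(Sigma) V^T` yields the identical H. A sample whose row of M is
#' zero (isolated sample) gets unit self-affinity and zero elsewhere so the
#' graph stays valid for normalized cuts.
#'
#' @param Z Square matrix, symmetric to within `tol_sym` (symmetrized
#'   internally).
#' @param tol_sym Maximum tolerated asymmetry `max|Z - Z^T|`.
#' @return Object of class `affinity_matrix`: list with `H` (symmetric,
#'   entries in `[0, 1]`, unit diagonal) and `rank_used` (skinny-SVD rank).
#' @export
affinity_matrix <- function(Z, tol_sym = 1e-6) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n != ncol(Z)) stop("Z must be square", call. = FALSE)
  asym <- max(abs(Z - t(Z)))
  if (asym > tol_sym) {
    stop("Z is asymmetric beyond tolerance (max|Z - Z'| = ",
         signif(asym, 3), ")", call. = FALSE)
  }
  Zs <- (Z + t(Z)) / 2
  sv <- svd(Zs)
  keep <- sv$d > 1e-10 * sv$d[1L] & sv$d > 0
  r <- sum(keep)
  if (r == 0L) {
    # zero representation: every sample isolated
    H <- diag(n)
  } else {
    M <- sv$u[, keep, drop = FALSE] * rep(sqrt(sv$d[keep]), each = n)
    rn <- sqrt(rowSums(M^2))
    nz <- rn > 0
    H <- matrix(0, n, n)
    if (any(nz)) {
      Mn <- M[nz, , drop = FALSE] / rn[nz]
      H[nz, nz] <- tcrossprod(Mn)^2
    }
    H <- pmin(pmax((H + t(H)) / 2, 0), 1)
    diag(H) <- 1
  }
  structure(list(H = H, rank_used = r), class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity matrix: %d samples, skinny-SVD rank %d\n",
              nrow(x$H), x$rank_used))
  invisible(x)
}

#' Write an affinity matrix as a dense TSV (e.g. for heat-map inspection)
#'
#' @param a An `affinity_matrix` (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity <- function(a, path) {
  H <- if (inherits(a, "affinity_matrix")) a$H else as.matrix(a)
  utils::write.table(H, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
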