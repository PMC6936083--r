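# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# Numerical minimizer of eps*||P||_* + 0.5*||P - Q||_F^2 over symmetric P.
# Smoothing continuation: minimize eps*sum(sqrt(sigma^2 + delta^2)) +
# 0.5*||P - Q||_F^2 by BFGS on the upper-triangle parametrization,
# warm-started while delta -> 1e-9. The smoothed objective is differentiable
# everywhere, so BFGS does not stall at zero singular values.
nuclear_prox_oracle <- function(Q, eps) {
  n <- nrow(Q)
  ut <- upper.tri(diag(n), diag = TRUE)
  to_mat <- function(p) {
    P <- matrix(0, n, n)
    P[ut] <- p
    P <- P + t(P)
    diag(P) <- diag(P) / 2
    P
  }
  p <- ((Q + t(Q)) / 2)[ut]
  for (delta in 10^seq(-1, -9)) {
    f <- function(pp) {
      P <- to_mat(pp)
      eps * sum(sqrt(svd(P)$d^2 + delta^2)) + 0.5 * sum((P - Q)^2)
    }
    g <- function(pp) {
      P <- to_mat(pp)
      sv <- svd(P)
      G <- eps * (sv$u %*% (sv$d / sqrt(sv$d^2 + delta^2) * t(sv$v))) + (P - Q)
      G <- (G + t(G)) / 2
      gr <- 2 * G
      diag(gr) <- diag(G) # shared off-diagonal parameters
      gr[ut]
    }
    p <- stats::optim(p, f, g, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))$par
  }
  to_mat(p)
}

permutations_of <- function(s) {
  if (s == 1L) return(list(1L))
  out <- list()
  for (perm in permutations_of(s - 1L)) {
    for (pos in seq_len(s)) {
      out[[length(out) + 1L]] <- append(perm, s, after = pos - 1L)
    }
  }
  out
}

# accuracy by exhaustive enumeration of all one-to-one cluster-to-class
# mappings (contingency table padded square, all permutations tried)
accuracy_oracle <- function(true_labels, pred_labels) {
  C <- unname(as.matrix(table(true_labels, pred_labels)))
  s <- max(dim(C))
  Cp <- matrix(0, s, s)
  Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  best <- 0
  for (perm in permutations_of(s)) {
    hit <- sum(Cp[cbind(seq_len(s), perm)])
    if (hit > best) best <- hit
  }
  best / length(true_labels)
}

# pair confusion by explicit double loop over all unordered pairs
pair_counts_oracle <- function(true_labels, pred_labels) {
  n <- length(true_labels)
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      st <- true_labels[i] == true_labels[j]
      sp <- pred_labels[i] == pred_labels[j]
      if (st && sp) tp <- tp + 1
      else if (!st && sp) fp <- fp + 1
      else if (st && !sp) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# NMI by direct entropy summation over the contingency table (base 2)
nmi_oracle <- function(true_labels, pred_labels) {
  C <- unname(as.matrix(table(true_labels, pred_labels)))
  n <- sum(C)
  h <- function(p) if (p > 0) -p * log2(p) else 0
  h_true <- sum(vapply(rowSums(C) / n, h, 0))
  h_pred <- sum(vapply(colSums(C) / n, h, 0))
  if (h_true == 0 && h_pred == 0) return(1)
  if (h_true == 0 || h_pred == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(C))) {
    for (j in seq_len(ncol(C))) {
      pij <- C[i, j] / n
      if (pij > 0) {
        mi <- mi + pij * log2(pij / ((sum(C[i, ]) / n) * (sum(C[, j]) / n)))
      }
    }
  }
  2 * mi / (h_true + h_pred)
}

random_partition <- function(n, max_k = 4L) {
  sample.int(sample.int(max_k, 1L), n, replace = TRUE)
}

# shared small fixture: three independent 4-dim subspaces in 50 dims
clean_fixture <- function(seed, ...) {
  subspace_data(n_subspaces = 3L, subspace_dim = 4L, ambient_dim = 50L,
                samples_per_subspace = 40L, noise_sigma = 0.01, seed = seed,
                ...)
}
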