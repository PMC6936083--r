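check_label_pair <- function(true_labels, pred_labels, min_n = 1L) {
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(pred_labels), ")", call. = FALSE)
  }
  if (length(true_labels) < min_n) {
    stop("need at least ", min_n, " samples", call. = FALSE)
  }
  invisible(NULL)
}

# maximum-trace one-to-one matching of predicted clusters to true classes,
# solved as maximum-weight bipartite matching on the contingency table
best_matching_weight <- function(C) {
  C <- unname(as.matrix(C))
  if (all(C == 0)) return(0)
  g <- igraph::graph_from_biadjacency_matrix(C, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight
}

#' Clustering accuracy with optimal label matching
#'
#' Fraction of samples whose predicted cluster maps onto their true class
#' under the best one-to-one cluster-to-class assignment (Kuhn-Munkres on
#' the contingency table), so the value is invariant to how clusters are
#' numbered.
#'
#' @param true_labels,pred_labels Equal-length label vectors (any atomic
#'   type; compared as factors).
#' @return Accuracy in `[0, 1]`.
#' @examples
#' clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' @export
clustering_accuracy <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels, min_n = 1L)
  C <- table(true_labels, pred_labels)
  best_matching_weight(C) / length(true_labels)
}

#' Pair-counting confusion over unordered sample pairs
#'
#' Classifies every unordered pair of samples by agreement of the two
#' partitions: TP = same true class and same predicted cluster; FP =
#' different true classes, same predicted cluster; FN = same true class,
#' different predicted clusters; TN = different in both. The four counts
#' always sum to `n(n-1)/2`.
#'
#' @inheritParams clustering_accuracy
#' @return List of class `pair_counts` with fields `TP`, `FP`, `TN`, `FN`.
#' @export
pair_counts <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels, min_n = 2L)
  C <- table(true_labels, pred_labels)
  n <- length(true_labels)
  total <- choose(n, 2)
  TP <- sum(choose(C, 2))
  FN <- sum(choose(rowSums(C), 2)) - TP
  FP <- sum(choose(colSums(C), 2)) - TP
  TN <- total - TP - FP - FN
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN), class = "pair_counts")
}

#' Pairwise Matthews correlation coefficient
#'
#' MCC over the pair-counting confusion: `(TP*TN - FP*FN) / sqrt((TP+FP)
#' (TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]` with 1 at perfect agreement and 0
#' for no association. When any denominator factor is zero the coefficient
#' is undefined and the no-association value 0 is returned.
#'
#' @param true_labels,pred_labels Label vectors, or a single `pair_counts`
#'   object passed as `true_labels`.
#' @return MCC in `[-1, 1]`.
#' @export
pair_mcc <- function(true_labels, pred_labels = NULL) {
  pc <- if (inherits(true_labels, "pair_counts")) true_labels
        else pair_counts(true_labels, pred_labels)
  f <- c(pc$TP + pc$FP, pc$TP + pc$FN, pc$TN + pc$FP, pc$TN + pc$FN)
  if (any(f == 0)) return(0)
  # divide factor-wise to avoid overflow in the product
  (pc$TP * pc$TN - pc$FP * pc$FN) / prod(sqrt(f))
}

#' Rand index
#'
#' Fraction of unordered sample pairs on which the two partitions agree:
#' `(TP + TN) / (n(n-1)/2)`.
#'
#' @inheritParams pair_mcc
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(true_labels, pred_labels = NULL) {
  pc <- if (inherits(true_labels, "pair_counts")) true_labels
        else pair_counts(true_labels, pred_labels)
  (pc$TP + pc$TN) / (pc$TP + pc$FP + pc$TN + pc$FN)
}

#' Normalized mutual information
#'
#' `2 I(X;Y) / (H(X) + H(Y))` with plug-in probabilities from the
#' contingency table and base-2 logarithms. Two single-cluster partitions
#' are identical and score 1; if exactly one partition has zero entropy the
#' normalization is degenerate and 0 is returned.
#'
#' @inheritParams clustering_accuracy
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels, min_n = 1L)
  C <- table(true_labels, pred_labels)
  n <- sum(C)
  p_true <- rowSums(C) / n
  p_pred <- colSums(C) / n
  h_true <- -sum(ifelse(p_true > 0, p_true * log2(p_true), 0))
  h_pred <- -sum(ifelse(p_pred > 0, p_pred * log2(p_pred), 0))
  if (h_true == 0 && h_pred == 0) return(1)
  if (h_true == 0 || h_pred == 0) return(0)
  P <- C / n
  E <- outer(p_true, p_pred)
  mi <- sum(ifelse(P > 0, P * log2(P / E), 0))
  2 * mi / (h_true + h_pred)
}

#' All four clustering metrics at once
#'
#' @inheritParams clustering_accuracy
#' @return Named list with `acc`, `mcc`, `ri`, `nmi`, all on the 0-1 scale
#'   (MCC in `[-1, 1]`).
#' @export
clustering_metrics <- function(true_labels, pred_labels) {
  pc <- pair_counts(true_labels, pred_labels)
  list(acc = clustering_accuracy(true_labels, pred_labels),
       mcc = pair_mcc(pc),
       ri = rand_index(pc),
       nmi = nmi(true_labels, pred_labels))
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("pair counts: TP=%g FP=%g TN=%g FN=%g (total %g pairs)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}
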