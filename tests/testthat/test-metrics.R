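test_that("accuracy uses optimal one-to-one label matching", {
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.75)
  expect_equal(clustering_accuracy(letters[c(1, 2, 1, 2)], c(9, 7, 9, 7)), 1.0)
  expect_error(clustering_accuracy(1:3, 1:4), "length")
})

test_that("pair counts match the worked example and always sum to n(n-1)/2", {
  pc <- pair_counts(c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_equal(pc[c("TP", "FP", "TN", "FN")],
               list(TP = 1, FP = 2, TN = 2, FN = 1))
  pc2 <- pair_counts(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(pc2[c("TP", "FP", "TN", "FN")],
               list(TP = 2, FP = 0, TN = 4, FN = 0))
  expect_equal(with(pc, TP + FP + TN + FN), 6)
})

test_that("MCC covers perfect, inverse and uncorrelated cases", {
  expect_equal(pair_mcc(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.0)
  expect_equal(pair_mcc(structure(list(TP = 3, FP = 0, TN = 5, FN = 0),
                                  class = "pair_counts")), 1.0)
  expect_equal(pair_mcc(structure(list(TP = 0, FP = 2, TN = 0, FN = 3),
                                  class = "pair_counts")), -1.0)
  # degenerate denominator factor -> no-association value 0
  expect_equal(pair_mcc(c(1, 2), c(1, 1)), 0)
})

test_that("Rand index counts pair agreements", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.5)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(rand_index(c(1, 1), c(1, 2)), 0.0)
})

test_that("NMI handles identical, independent and degenerate partitions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.0)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 2, 2)),
               nmi_oracle(c(1, 1, 2, 2), c(1, 2, 2, 2)))
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1.0) # both single-cluster
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 1)), 0.0) # one entropy zero
})

test_that("all metrics agree with exhaustive oracles on random partitions", {
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    a <- random_partition(n)
    b <- random_partition(n)
    expect_equal(clustering_accuracy(a, b), accuracy_oracle(a, b),
                 tolerance = 1e-12)
    pc <- pair_counts(a, b)
    po <- pair_counts_oracle(a, b)
    expect_equal(pc$TP, po$TP)
    expect_equal(pc$FP, po$FP)
    expect_equal(pc$TN, po$TN)
    expect_equal(pc$FN, po$FN)
    m <- with(po, if (any(c(TP + FP, TP + FN, TN + FP, TN + FN) == 0)) 0
              else (TP * TN - FP * FN) /
                sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
    expect_equal(pair_mcc(a, b), m, tolerance = 1e-12)
    expect_equal(rand_index(a, b), (po$TP + po$TN) / choose(n, 2),
                 tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to relabeling and NMI is symmetric", {
  set.seed(91)
  a <- random_partition(15)
  b <- random_partition(15)
  b_relab <- match(b, unique(b)) + 10L
  expect_equal(clustering_accuracy(a, b), clustering_accuracy(a, b_relab))
  expect_equal(pair_mcc(a, b), pair_mcc(a, b_relab))
  expect_equal(rand_index(a, b), rand_index(a, b_relab))
  expect_equal(nmi(a, b), nmi(a, b_relab))
  expect_equal(nmi(a, b), nmi(b, a))
  # accuracy at least the best single-cluster mapping
  expect_gte(clustering_accuracy(a, rep(1, 15)), max(table(a)) / 15)
})
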