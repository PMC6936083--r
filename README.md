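# sglrr

Subspace clustering of expression matrices by **graph-regularized low-rank
representation with symmetric and sparse constraints (sgLRR)**.

## The problem

Bulk and single-cell expression datasets often pool samples from several
biological conditions — for instance tumor samples from multiple cancer
types — and the task is to recover those groups without labels. Samples of
one group approximately span a low-dimensional linear subspace of feature
(gene) space, so the data matrix is a union of subspaces, a structure that
distance-based clustering handles poorly but self-representation methods
exploit directly.

## The model

Given an observation matrix `X ∈ R^(m×n)` (m features, n samples), sgLRR
finds a representation `Z` expressing every sample as a linear combination
of all samples:

```
min_{Z,E}  ||Z||_* + λ||Z||_1 + β tr(Z L Zᵀ) + γ||E||_1
s.t.       X = XZ + E,   Z = Zᵀ
```

* `||Z||_*` (nuclear norm) drives Z toward low rank: ideally Z is block
  diagonal with one block per subspace.
* `λ||Z||_1` sparsifies Z so between-group affinities vanish.
* `β tr(Z L Zᵀ)` is a manifold (graph-Laplacian) penalty: `L = D − W` comes
  from the k-nearest-neighbor graph of the sample columns, and the term
  pulls representation rows of neighboring samples together, preserving
  local geometry.
* `Z = Zᵀ` forces mutual similarities to agree, avoiding the lossy
  post-hoc symmetrization `(|Z| + |Zᵀ|)/2`.
* `γ||E||_1` absorbs sparse gross corruption of individual entries.

The problem is solved by linearized ADMM with adaptive penalty (LADMAP);
the Z-step has a closed form via symmetric singular-value thresholding.
The solution `Z*` is converted to an affinity
`H_ij = cos²(m_i, m_j)` where `m_i` are rows of `M = U√Σ` from the skinny
SVD of `Z*`, and H is partitioned by normalized-cuts spectral clustering
(symmetric normalized Laplacian, k-means++ with restarts). Agreement with
reference labels is measured by accuracy under optimal (Kuhn–Munkres) label
matching, pairwise Matthews correlation, Rand index and normalized mutual
information.

## Worked example

```r
library(sglrr)

# three independent 4-dim subspaces in 50-dim feature space, 40 samples each
d <- subspace_data(n_subspaces = 3, subspace_dim = 4, ambient_dim = 50,
                   samples_per_subspace = 40, noise_sigma = 0.01, seed = 42)
fit <- sglrr(d$x, n_clusters = 3, seed = 42)
fit
#> sgLRR fit
#>   call: sglrr(x = d$x, n_clusters = 3, seed = 42)
#>   data: 50 features x 120 samples (normalization: none)
#>   solver: converged after 144 iterations
#>   clusters: 3
#> cluster
#>  1  2  3
#> 40 40 40

summary(fit)
#> sgLRR fit summary
#>   ...
#>   lambda = 0.1, beta = 1, gamma = 0.5, k = 5
#>   converged after 144 iterations (primal 4.73e-06, ||Z-J||_inf 8.59e-05)
#>   rank(Z) = 114, max|Z - Z'| = 0.00e+00, |E|_1 / |X|_1 = 0.083

# averaged evaluation against the generating labels (k-means++ is random,
# so the convention is to repeat the clustering and report means)
repeated_cluster_metrics(fit$affinity, k = 3, true_labels = d$labels,
                         n_repeats = 50, seed = 42)
#> clustering metrics over 50 repeats (mean +/- sd):
#>   acc  1.0000 +/- 0.0000
#>   mcc  1.0000 +/- 0.0000
#>   ri   1.0000 +/- 0.0000
#>   nmi  1.0000 +/- 0.0000
```

The solver converged to primal feasibility ~5e-6, the learned representation
is exactly symmetric, about 8% of the input's L1 mass went into the sparse
error term, and all 120 samples are assigned to their generating subspace
(all four metrics = 1).

`coef(fit)` returns Z, `residuals(fit)` the sparse error E, `fitted(fit)`
the reconstruction XZ, and `plot(fit)` draws the affinity heat map with
samples ordered by cluster.

### Command line

```sh
Rscript exec/sglrr --input matrix.tsv --n-clusters 3 \
    --labels labels.csv --lambda 0.1 --beta 1.0 --gamma 0.5 --seed 42
```

writes `labels.csv`, `residuals.csv` and (with reference labels)
`metrics.json` to the output directory.

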