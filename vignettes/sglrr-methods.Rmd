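---
title: "sgLRR: model, solver and design notes"
author: "sglrr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sgLRR: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sglrr)
```

## The model

sgLRR clusters the columns (samples) of an expression matrix
`X ∈ R^(m×n)` under the union-of-subspaces assumption: samples from one
biological group lie near a shared low-dimensional linear subspace of
feature space. The representation Z solves

$$
\min_{Z,E}\ \|Z\|_* + \lambda\|Z\|_1 + \beta\,\mathrm{tr}(Z L Z^\top)
 + \gamma\|E\|_1
\quad \text{s.t.}\quad X = XZ + E,\ Z = Z^\top .
$$

Each penalty encodes one assumption about the data:

* **Low rank** (`||Z||_*`): with independent subspaces the ideal
  self-representation is block diagonal, one block per subspace, so its
  rank is the sum of subspace dimensions — far below n.
* **Sparsity** (`λ||Z||_1`): within-group affinities should be dense and
  between-group affinities zero; the elementwise penalty localizes the
  representation.
* **Manifold smoothness** (`β tr(ZLZᵀ)`): `L` is the unnormalized
  Laplacian of the k-nearest-neighbor graph of the sample columns. Since
  `tr(ZLZᵀ) = Σ_{ij} w_{ij} ||z_i − z_j||²` over representation rows, the
  term asks samples that are close in feature space to have similar
  representations, preserving local geometry that the global low-rank
  term ignores.
* **Symmetry** (`Z = Zᵀ`): similarity of i to j and of j to i are forced
  to agree inside the optimization, rather than repaired afterwards by
  `(|Z| + |Zᵀ|)/2`, which discards information.
* **Sparse gross errors** (`γ||E||_1`): isolated corrupted entries
  (dropouts, artifacts) are absorbed by E instead of distorting Z.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda` | sparsity weight on Z | 0.1 | unitless; 0 disables |
| `beta` | graph-penalty weight | 1.0 | unitless; 0 disables |
| `gamma` | L1 weight on E | 0.5 | lower it when entries carry gross corruption (see below) |
| `k_neighbors` | k-NN graph size | 5 | the conventional choice for expression data |
| `mu0`, `rho`, `mu_max` | ADMM penalty schedule | 1e-2, 1.1, 1e6 | see solver notes |
| `tol_primal`, `tol_change` | stopping tolerances | 1e-4 | relative / absolute, see below |
| `max_iter` | iteration cap | 500 | non-convergence warns, never errors |

No canonical `(λ, β, γ)` exists for expression data; the defaults are
sensible starting points for data on a roughly unit scale and should be
tuned per dataset (all three are mandatory-visible flags in the CLI). On
clean, low-noise subspace data results are insensitive to them over an
order of magnitude.

## Graph construction

The neighbor graph uses plain Euclidean distance between raw sample
columns (a config option allows other `stats::dist` metrics), with the
mutual-OR rule `w_ij = 1` iff i is among the k nearest neighbors of j or
vice versa — this forces symmetry without any post-processing. Decisions
that the graph definition itself leaves open:

* a sample is never its own neighbor and `diag(W) = 0`, which keeps the
  degree matrix interpretable;
* distance ties break toward the lower sample index, so the graph is
  deterministic;
* duplicate columns are at distance 0 and therefore always neighbor each
  other.

`L = D − W` is symmetric positive semi-definite with exact zero row sums;
the test suite asserts both on every run.

## Solver

The constrained problem is split with an auxiliary `J = Z` carrying the
L1 penalty (and, as a side effect of its shrinkage step, a nonnegativity
clip, so J is an affinity-like companion of Z), then minimized on the
augmented Lagrangian by LADMAP — linearized ADMM with an adaptive,
nondecreasing penalty:

1. **Z-step.** The smooth part `q(Z)` of the Lagrangian is linearized at
   `Z_k` with proximal weight
   `η₁ = 2β‖L‖₂ + μ(1 + ‖X‖₂²)` (spectral norms, computed once; η₁ is
   refreshed whenever μ changes). The resulting subproblem
   `min ‖Z‖_* + ⟨∇q, Z−Z_k⟩ + (η₁/2)‖Z−Z_k‖²_F` over symmetric Z has the
   closed form `Z_{k+1} = Θ_{1/η₁}((Q+Qᵀ)/2)` with `Q = Z_k − ∇q/η₁`,
   where Θ soft-thresholds the singular values of the symmetrized point.
   The operator returns the exact minimizer of
   `ε‖P‖_* + ½‖P−Q‖²_F` over symmetric P; the suite verifies this against
   an independent numerical minimizer (BFGS with smoothing continuation on
   the singular values) to 1e-4 in Frobenius norm.
2. **E-step.** Elementwise shrinkage of `X − XZ_{k+1} + Y₁/μ` at `γ/μ`.
3. **J-step.** Elementwise shrinkage of `Z_{k+1} + Y₂/μ` at `λ/μ`,
   clipped at zero (J is exactly nonnegative at every iterate).
4. **Multipliers** ascend on both constraint residuals; then
   `μ ← min(ρμ, μ_max)`.

All variables start at zero, the standard LADMAP initialization; the whole
iteration is deterministic, so identical inputs give bit-identical
solutions. The run stops when *both* the relative primal residual
`‖X − XZ − E‖_F / ‖X‖_F ≤ tol_primal` and
`max(‖Z − J‖_∞, ‖ΔZ‖_∞) ≤ tol_change`. For all-zero X the relative
residual is replaced by the absolute one and the solver converges to the
zero solution in one iteration. A NaN/Inf iterate (possible only with
extreme penalty settings) raises an error naming the iteration;
exhausting `max_iter` warns and returns `converged = FALSE`, and the
pipeline proceeds to clustering with the last iterate.

Numerical details: skinny SVDs keep singular values above
`1e-10 × σ_max`; the Z-step output is re-symmetrized to kill roundoff
asymmetry; `‖X‖₂`, `‖L‖₂` are computed once per fit.

## Affinity and spectral clustering

The affinity is the squared cosine between rows of `M = U√Σ` from the
skinny SVD of Z\*. Squaring removes the sign ambiguity of singular
vectors, and cosines make H invariant to positive rescaling of Z — both
properties are tested. For symmetric Z the alternative factor
`N = √Σ Vᵀ` produces the same H (also tested; M is used in production).
A sample with a zero row of M gets `H_ii = 1`, `H_ij = 0`, so normalized
cuts always sees positive degrees.

Normalized cuts is realized in the Ng–Jordan–Weiss form: symmetric
normalized Laplacian `I − D^{-1/2} H D^{-1/2}`, k smallest-eigenvalue
eigenvectors, row-normalized embedding, k-means with squared Euclidean
distance and k-means++ seeding, 20 restarts by default keeping the lowest
within-cluster sum of squares. (The classic formulation leaves the
spectral realization open; NJW is the standard choice for a dense
similarity matrix.) Because k-means++ is random, evaluation uses the
repeat-and-average protocol: `repeated_cluster_metrics()` reruns the
clustering (default 50 times) with per-repeat seeds derived
deterministically from one master seed, and reports per-metric means and
standard deviations.

## Evaluation metrics

* **Accuracy** maximizes label agreement over one-to-one cluster-to-class
  mappings (Kuhn–Munkres via weighted bipartite matching on the
  contingency table). The suite checks it against exhaustive enumeration
  of all mappings.
* **Pairwise MCC and Rand index** use standard pair-counting semantics:
  over all unordered pairs, TP = same class & same cluster, TN =
  different & different, FP = different class & same cluster, FN = same
  class & different cluster, with `RI = (TP+TN) / (n(n−1)/2)`. Verbal
  definitions of the pair classes vary in the literature and are easy to
  state inconsistently; this package fixes the convention above, the one
  under which both scores attain 1 exactly at perfect agreement. MCC
  returns the no-association value 0 whenever a denominator factor
  vanishes.
* **NMI** is `2I/(H₁+H₂)` with base-2 logarithms. Two single-cluster
  partitions are identical and score 1; if exactly one entropy is zero
  the normalization is degenerate and the score is 0.

All four are invariant to relabeling; internal values are on the 0–1
scale and the CLI/pipeline multiply by 100 for display.

## Synthetic data: what it does and does not emulate

`subspace_data()` generates exactly the structure the model assumes:
orthonormal bases with disjoint spans (when total intrinsic dimension
fits in the ambient dimension), standard-normal subspace coefficients,
i.i.d. Gaussian noise, and elementwise corruption hitting each entry with
a fixed probability and uniform `±scale` magnitude. An optional
shift-and-clip mimics nonnegative intensity scales but is off by default.
The reference fixture used throughout the tests is 3 subspaces of
dimension 4 in 50 ambient dimensions with 40 samples each
(n = 120, σ = 0.01) — small enough that a full fit takes about a second,
large enough that the spectral geometry is non-trivial.

The generator deliberately does **not** emulate count statistics
(negative binomial mean–variance), library-size variation, batch effects,
or correlated (column-wise) corruption. Passing tests on these fixtures
therefore demonstrate correctness of the algorithm under its own
assumptions, not performance on real RNA-seq data, where preprocessing
and parameter tuning matter.

## Robustness to gross corruption: a known limitation

The `γ‖E‖₁` term recovers individual corrupted entries well when γ is
matched to the corruption level (for the reference fixture with 5% of
entries corrupted at scale 5, γ ≈ 0.02 is suitable — the default 0.5
essentially disables E). However, the k-NN graph is built on the
*corrupted* columns upstream of the solver, and at that corruption energy
(several times the column norm) Euclidean neighborhoods become largely
random. The graph penalty then propagates noise into Z: on the reference
fixture, mean accuracy drops from ~0.99 (clean) to ~0.70 (corrupted, best
γ, default β = 1), and even with the graph term disabled the best
achievable is ~0.89. Substituting the clean-data graph restores perfect
recovery, isolating the graph as the failure point. Users applying the
method to data with suspected gross corruption should lower γ *and*
either lower β or build the graph on robustly preprocessed data.

## Problem sizes in the test suite

Unit tests run on 2-subspace fixtures with 16–40 samples; the
integration and end-to-end checks use the 120-sample reference fixture
(10 generator seeds) and 50-repeat clustering averages; oracle
comparisons use 4×4 prox problems (50 random instances) and partitions of
up to 12 samples (100 random pairs, exhaustively enumerated). These sizes
were chosen so the whole suite exercises every code path at full
tolerance in a few minutes on one CPU.

## Limitations

* Dense matrices only; complexity is `O(r·mn + n²m)` per fit with an
  `O(n³)` eigendecomposition in the spectral step, practical to a few
  thousand samples.
* The number of clusters is an input; no model selection is provided.
* Exact ALM/ADM solver variants, weighted (heat-kernel) graphs and
  column-wise (L2,1) error models are out of scope.
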