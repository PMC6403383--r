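# fisim — alignment-free phylogenetics with Markov chains and fuzzy integrals

`fisim` compares DNA sequences without aligning them. It is aimed at
phylogenetic and comparative studies where alignment is impractical — whole
genomes, large marker-gene collections, or sequence sets too diverged for
reliable positional homology.

## The method

Every sequence is summarised by the transition probability matrix of a
first-order Markov chain on the nucleotide states **S** = (A, T, G, C):

```
p_ij = N(s_i s_j) / sum_j N(s_i s_j)
```

where `N(s_i s_j)` counts adjacent nucleotide pairs. The k-step matrix
`P^k` (the k-th matrix power, by the Chapman–Kolmogorov relation) captures
longer-range composition structure.

Two sequences are compared through their k-step matrices `P1^k`, `P2^k`
with a Sugeno fuzzy integral:

* evidence of agreement per cell: `h_ij = 1 − |P1_ij − P2_ij|`;
* fuzzy densities per cell: `mu_ij = max(P1_ij, P2_ij)` — the conservation
  level of each nucleotide-pair position;
* per matrix row, a λ-fuzzy measure is built from the densities
  (`mu(X ∪ Y) = mu(X) + mu(Y) + λ mu(X) mu(Y)`, with λ solved from
  `1 + λ = Π_j (1 + λ mu_ij)`), and the Sugeno integral
  `S_i = max_j min(h_(j), mu(A_ij))` is taken with the evidence sorted in
  decreasing order;
* the similarity is `I = max_i S_i` and the distance `D = 1 − I ∈ [0, 1]`.

The step k is chosen automatically: k grows until the all-pairs distance
matrix stops changing (root-mean-square difference between consecutive-step
matrices below a tolerance). The distance matrix feeds UPGMA (default) or
neighbor-joining tree building, with PHYLIP square-matrix and Newick
interchange, Robinson–Foulds comparison against reference trees, and
ROC/AUC evaluation against group labels. A seeded Markov-chain simulator
(`simulate_sequence()`, `evolve_family()`) generates test data with known
truth.

## Worked example

Simulate a four-leaf family along a known guide tree, pick the optimal
step, and rebuild the tree:

```r
library(fisim)

gt <- guide_tree_balanced(depth = 2, branch_length = c(0.01, 0.3))
ds <- evolve_family(chain_spec(length = 10000), gt, seed = 42)
fit <- find_optimal_k(ds)
print(fit)
#> optimal step k = 8 (converged, tol = 1e-06, max_k = 30)
#> rmsd trace (D_k vs D_{k+1}):
#>  k         rmsd
#>  1 4.650686e-03
#>  ...
#>  8 3.879685e-07

print(fit$distance)
#> fuzzy-integral distance matrix: 4 taxa, step k = 8
#>        t1     t2     t3     t4
#> t1 0.0000 0.0024 0.0046 0.0037
#> t2 0.0024 0.0000 0.0054 0.0045
#> t3 0.0046 0.0054 0.0000 0.0012
#> t4 0.0037 0.0045 0.0012 0.0000

tree <- upgma(fit$distance)
cat(to_newick(tree))
#> ((t3:0.000600,t4:0.000600):0.001669,(t1:0.001200,t2:0.001200):0.001069);
rf_distance(tree, gt)
#> [1] 0
```

The distance matrix converged at step k = 8; the two simulated cherries
(t1, t2) and (t3, t4) are recovered exactly (Robinson–Foulds distance 0),
and within-cherry distances (0.0024, 0.0012) are clearly below cross-cherry
ones (0.0037–0.0054). `roc_auc(fit$distance, groups)` with the cherry
labels scores this separation at AUC = 1.

A shell front-end covering the same pipeline is installed as
`inst/scripts/fisim` (`fisim dist | tree | eval | simulate`).

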