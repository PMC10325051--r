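---
title: "Methods: community detection in kinase networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community detection in kinase networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinasecomm)
```

This vignette is the package's own account of its methods: the model behind
each stage, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the
known limitations.

## From z-scores to networks

The input is a table of unordered kinase pairs with one real z-score per
treatment, quantifying how strongly the interaction (defined by shared
putative downstream phosphorylation targets) responded to a kinase
inhibitor. The working hypothesis is that inhibiting a pathway's kinase
depresses the downstream kinase–kinase interactions *within* that pathway,
so the inhibited (strictly negative) tail of one treatment carries the
pathway signal.

`build_network()` therefore keeps the pairs whose z-score is strictly
negative (or strictly positive, for the complementary analysis of
upregulated interactions), weights each edge by |z|, and takes as nodes
exactly the kinases incident to a retained edge. Key conventions:

* **Zeros are excluded from both tails.** The negative tail is defined as
  strictly negative; the same strictness is applied symmetrically to the
  positive tail, so the two tails partition the non-zero entries.
* **Missing cells are missing**, never imputed as zero: absence of a
  measurement is not evidence of absence of inhibition.
* **Undirected**: nothing in the edge definition says which kinase acts
  upstream, so the adjacency matrix is symmetric and no direction is ever
  assigned by this package.
* Pairs are canonicalised (members sorted lexicographically) and nodes are
  ordered lexicographically, making every downstream matrix computation
  invariant to input row order.
* `merge_aliases()` handles kinases measured as one entity (isoforms with
  identical substrate assignments, e.g. AKT1 and AKT2): renaming is
  config-driven, collapsing duplicates must agree within an absolute
  tolerance of 1e-9 (they are identical copies in the motivating case, so
  the tolerance only absorbs formatting noise), and self-pairs created by
  the merge are dropped.
* `summarise_zscores()` reports both the sample (n−1) and population (n)
  standard deviation, with the sample convention as the headline `sd`
  field; empirical summary tables of this kind rarely state which
  convention they use, so both are exposed rather than hard-coding one.

## Modularity and its null models

Communities maximise the unnormalised modularity

$$Q(C) = \sum_{i,j=1}^{n} (A_{ij} - P_{ij})\,\delta(c_i, c_j),$$

a sum over *ordered* node pairs, including $i = j$. Two null models define
the expected adjacency $P$, both scaled by a resolution parameter
$\gamma > 0$:

* **Newman–Girvan**: $P_{ij} = \gamma\, s_i s_j / (2m)$ for all ordered
  pairs, with $s_i$ the strength of node $i$ and $2m$ the total weight.
  The diagonal term $\gamma s_i^2/(2m)$ is deliberately kept: since
  $\delta(c_i,c_i) = 1$ under every partition it is a partition-independent
  offset, and keeping it makes the one-community partition score exactly
  $2m - (2m)^2/(2m) = 0$ at $\gamma = 1$ — the strength-preservation
  property that motivates this null. Dropping it would shift every
  partition's score by the same constant but break that closed form.
* **uniform**: constant expected weight
  $P_{ij} = \gamma \cdot 2m / (n(n-1))$ between distinct nodes, zero
  diagonal. This is the standard constant-expected-weight null; with it,
  any partition of a constant-weight complete network scores exactly 0 at
  $\gamma = 1$. The uniform null is the package's default because it is the
  variant preferred for empirical kinase networks (better alignment of the
  selected communities with canonical pathways), with Newman–Girvan
  available everywhere via `null_model("newman-girvan")`.

$\gamma$ defaults to 1 — a single natural scale — and is exposed for
multi-scale exploration, but none of the package's validation sweeps it.

## Louvain with a pluggable null

`louvain_partition()` implements the locally greedy heuristic directly on
the modularity matrix $B = A - \gamma P$:

1. start from singleton communities;
2. sweep the nodes in a random order, freshly drawn at the start of *every*
   sweep, moving each node to the community with the largest strictly
   positive modularity gain (computed against all current communities, so
   the choice is exact for any null);
3. when a full sweep makes no move, aggregate **B itself** by the current
   communities and repeat on the aggregated matrix.

Aggregating $B$ (rather than the weights alone, with the null recomputed)
is essential for the uniform null, whose $P$ is not a function of the
aggregated weights; for Newman–Girvan the two are equivalent. Numerical
choices: a move must improve the gain by more than 1e-12 (guarding against
cycling on floating-point noise); gain ties go to the lowest community
index, which together with the seeded node order makes a run
bit-reproducible — the same seed, network and null always return the same
partition, while different seeds may return different local optima.

`brute_force_partition()` is the independent oracle: it enumerates every
set partition (restricted growth strings, feasible to n = 12; Bell(12) ≈
4.2 million), scores them all against $B$, and breaks ties (within 1e-10)
towards fewer communities, then the lexicographically smallest canonical
labelling. The test suite verifies that Louvain never exceeds the
exhaustive optimum and attains it on well-separated planted instances.

## Consensus clustering

Because Louvain is nondeterministic, `consensus_partition()` runs an
ensemble (default 100 runs; the per-run seeds are derived deterministically
from one master seed and recorded in the result for replay) and summarises
it as a co-classification matrix: entry $(i,j)$ is the fraction of runs
placing $i$ and $j$ together. While that matrix is not binary it is treated
as a weighted network over the same nodes (diagonal zeroed) and the
ensemble is re-run on it under the same null-model family and resolution —
an assumption the package documents rather than a prescribed choice, since
the iteration needs *some* null and reusing the base one keeps the
procedure parameter-free. Iteration stops when the matrix is exactly
binary; since entries are counts over an integer ensemble, binarity is
tested exactly, with no epsilon. The consensus partition is the connected
block structure of the binary matrix.

Two deliberate deviations from fancier consensus schemes: there is no
thresholding of weak co-classification entries by default (`tau = 0`
zeroes nothing; a positive `tau` is available for users who want the
thresholded variant), and non-convergence within `max_iterations` (default
20, a pure safety valve — planted and empirical-scale networks converge in
1–2 iterations) is an explicit error carrying the last matrix, never a
silent result.

Partition similarity (`compare_partitions()`) reports both the adjusted
Rand index and normalised mutual information (symmetric
$2I/(H_1 + H_2)$ normalisation), computed from the contingency table.
Both are reported because robustness summaries of this kind are not tied
to a single canonical metric; `consensus_robustness()` repeats the whole
consensus procedure under distinct master seeds and reports all pairwise
similarities.

## Pathway analysis

For each treatment the community containing the inhibitor's main target
(after alias merging) is selected. Per-member **community strength** is
$\mathrm{CS}(v) = \sum_{u \in C,\, u \neq v} A_{vu}$ — edges leaving the
community never contribute. Since weights are absolute z-scores, CS is
non-negative and ranking by |CS| (ties share the smaller rank) equals
ranking by CS.

The **anchor-edge filter** keeps the community members (anchors excluded)
that have a direct positive-weight edge to *every* anchor kinase — looked
up in the full treatment network, not the community subgraph: the community
only scopes the candidate list, while adjacency is a property of the
network. Adding anchors can only shrink the survivor set. Known pathway
members can be excluded from the final ranking via the pipeline config
(`excluded_known_members`) rather than inside the filter, since published
analyses list them separately from the novel candidates.

Cross-treatment ranking (`rank_candidates()`) orders candidates by their
best (minimum) CS rank across the selected communities, breaking ties by
mean CS and then name — an explicit package convention, since narrative
descriptions of "highest CS in both communities" do not define a total
order.

`run_pipeline()` composes all stages from one config (list or YAML) and one
master seed; per-treatment seeds are derived from it, embedded in the
report, and `write_report()` serialises the result to JSON such that two
runs of the same config are byte-identical.

## The synthetic generator

`generate_planted_zscores()` draws one treatment column over all unordered
pairs of `n_kinases` kinases partitioned into planted communities:

| parameter | default | role |
|---|---|---|
| `community_sizes` | 20/20/20 | planted partition |
| `p_within`, `p_between` | 0.6, 0.1 | probability a within-/between-community pair gets a negative z |
| `mu_within`, `sigma_within` | −1.5, 0.5 | bulk within-community component (truncated normal, z < 0) |
| `mu_between`, `sigma_between` | −0.2, 0.2 | between-community component |
| `heavy_tail_fraction` | 0.05 | share of within draws redrawn from the heavy tail |
| `mu_heavy`, `sigma_heavy` | −8, 4 | heavy-tail component |
| `positive_noise_fraction` | 0.1 | share of absent pairs given z = \|N(0.3, 0.2)\| |

The defaults are the package's reference study conditions: a clearly
recoverable three-community instance whose negative tail has bulk mean and
spread on the scale of empirical per-treatment summaries (means of a few
tenths to ≈ −1.5, sd below 1–2) and whose heavy-tail component produces
minima of magnitude ≈ 10–17, far beyond the bulk, as observed for
AKT-inhibitor treatments. Negative draws use truncation-by-redraw rather
than sign-flipping so the component means remain interpretable;
`negative_tail_moments()` returns the exact truncated-normal mixture mean
and sd implied by a spec, which the tests compare against generated tables
(within three standard errors over replicates).

What the generator does **not** emulate: the biochemical dependence between
treatments (each generated column is independent), the degree
heterogeneity and hub structure of real kinase networks, shared-substrate
correlations between overlapping pairs, and any notion of directionality.
Passing the planted-recovery tests therefore shows the machinery is
correct and well-calibrated at realistic signal strengths — not that real
kinase communities are as cleanly separated as planted ones.

The first member of the designated pathway community is recorded as the
ground-truth target and the first three members as anchors, mirroring a
pathway with one inhibited main target and a small canonical core.

## Validation problem sizes

The shipped validation uses sizes chosen to exercise every contract while
keeping a full run fast: exhaustive-oracle comparisons on 200 random
networks of 3–8 nodes (both nulls); consensus contract and recovery on the
default 60-kinase planted spec with ensembles of 50–100 over 20–50
replicate seeds; law-of-large-numbers calibration on 120-kinase tables.
The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from a single master seed.

## Known limitations

* Modularity maximisation inherits the resolution limit and the
  near-degeneracy of its optimum landscape; consensus clustering addresses
  run-to-run variability, not the choice of scale. Multi-scale sweeps of
  $\gamma$ and alternative optimisers (e.g. Leiden) are out of scope.
* Exhaustive search is limited to 12 nodes; beyond that, optimality is
  only ever verified statistically (Louvain ≤ oracle on subsampled cases).
* The pipeline nominates candidates; it cannot establish whether a
  candidate acts upstream or downstream — that requires perturbation
  experiments outside the scope of network analysis.
* Communities are evaluated per treatment; merged multi-treatment networks
  and directed or temporal extensions of modularity are not implemented.
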