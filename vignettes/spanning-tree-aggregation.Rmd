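---
title: "Aggregating nodal scores over unbalanced signed graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating nodal scores over unbalanced signed graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstree)
```

## The problem

Causal network models describe biological systems as signed graphs: nodes are
molecular entities or activities, and each edge carries a sign, +1 ("->", an
increase in the source causes an increase in the target) or -1 ("-|", an
increase causes a decrease). Omics experiments attach a real-valued score
$X_n$ to each node — a log fold-change, a node-level perturbation amplitude —
and a network-level readout is obtained by *aggregation*: summing the nodal
scores with their signs taken relative to one designated *reference node*
whose activity is, by convention, positively related to the activity of the
network as a whole,

$$X_G = \sum_n s_{n \to REF}(G)\, X_n, \qquad
  s_{n \to REF}(G) \in \{-1, +1\}.$$

The nodal sign $s_{n \to REF}$ is the product of edge signs along a
(non-oriented) path from $n$ to the reference. This is well defined only when
every path gives the same answer — when the graph is *balanced* in the
signed-graph sense, equivalently *causally consistent*: every cycle has
positive sign product. Realistic network models are frequently unbalanced,
because real biology contains negative feedback and contradictory regulation.
The incoherent feed-forward loop shipped as `iffl()` is the minimal example:
A activates both B and C while B inhibits C, so the two paths from A to B
(direct, and through C) disagree in sign and no consistent assignment exists.

## The spanning-tree relaxation

Every spanning tree $t$ of a connected graph is balanced, because trees have
no cycles; each node then has a unique path to the reference and an
unambiguous sign $s_{n \to REF}(t)$. Averaging over *all* $N(G)$ spanning
trees defines the **effective nodal weight**

$$S_{n \to REF}(G) = \frac{1}{N(G)} \sum_{i=1}^{N(G)} s_{n \to REF}(t_i)
  \in [-1, +1],$$

a structural average that degenerates to the rigid sign on balanced graphs
and interpolates smoothly when paths disagree. The aggregate becomes
$X_G = \sum_n S_{n \to REF}(G) X_n$, which (swapping the two summations)
equals the mean over spanning trees of the per-tree aggregates
$X(t) = \sum_n s_{n \to REF}(t) X_n$. On the incoherent loop the three trees
give per-tree scores $(3, 1, 1)$ for unit nodal values, weights
$(1, \tfrac13, \tfrac13)$, and $X_G = \tfrac53$: the aggregate is discounted
relative to the naive sum of 3 exactly because the unit scores are
inconsistent with the inhibiting edge.

Two engines compute $S$:

* **Exact enumeration** (`exact_effective_weights()`), for graphs whose tree
  count — obtained from the matrix-tree determinant,
  `count_spanning_trees()` — is below a cap (default $10^6$). Enumeration is
  a contraction–deletion recursion that is multigraph-aware: parallel
  contradictory edges are distinct tree members. Tree-sign tallies are kept
  as exact integer counts, so balanced graphs come out at bit-exact $\pm 1$.
* **Monte-Carlo sampling** (`estimate_effective_weights()`), the scalable
  path. Signed random walkers implement first-entrance (Aldous) uniform
  spanning-tree sampling: a walker starts at the reference with sign +1,
  repeatedly picks an incident edge with probability proportional to its
  traversal weight ignoring direction and sign, flips its sign on negative
  edges, stamps each node with its sign at first entrance (that edge joins
  the tree), adopts the node's stored sign on re-entry, and stops when all
  nodes are visited. The estimator is
  $S_n \approx (N_+(n) - N_-(n)) / (N_+(n) + N_-(n))$ from the walkers' visit
  counts, with the binomial standard error
  $\sqrt{(1 - S_n^2)/n_{\text{trees}}}$ reported per node.

A subtlety worth stating: on re-entering a visited node the walker *adopts*
the node's stored sign and continues from there. This is the only reading of
the re-entry rule under which the stamped signs coincide exactly with the
path signs of the reconstructed first-entrance tree — an invariant the test
suite checks walker by walker.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 1000 | sampled trees (= walkers); SE scales as $1/\sqrt{n_{\text{trees}}}$ |
| `seed` | 1 | base of the per-walker counter-derived RNG substreams |
| `profile` | `"uniform"` | `"bel"` switches on edge-class traversal weights |
| class weights | 1, 1/2, 1/3, 1/4 | intramolecular, direct, indirect, expression edges |
| `cap` | $10^6$ | enumeration refuses graphs with more trees |
| `max_steps` | $500 \cdot |V| \cdot |E|$ | per-walker cover-time budget |

The class weights encode the semantics of BEL-encoded models: intramolecular
edges (a molecule and its activity) are the most likely to be retained in a
tree, expression edges the least, since they act on slower timescales and
often close feedback loops. Under weighted traversal the sampled trees follow
the first-entrance distribution of the weighted walk rather than the uniform
distribution; every spanning tree retains positive probability, and the
weighting is deliberately mild. `sst()` front-ends both engines and, given
scores, also reports the per-tree score distribution and the *most
representative tree* $t^\ast = \arg\min_t |X(t) - X_G|$ (ties broken by
collection order, for reproducibility). We extend $t^\ast$ to the subgraph
$G^\ast$ consisting of $t^\ast$ plus every non-tree edge whose endpoint signs
under $t^\ast$ match its edge sign — the maximal balanced subgraph containing
$t^\ast$. That construction is our interpretation of "the subgraph
corresponding to $t^\ast$"; the tree alone is the conservative reading.

Determinism: the sampler never touches R's RNG. Each walker draws from a
splitmix64 substream keyed by (seed, walker index), so a fixed seed gives
bit-identical weights and enlarging `n_trees` does not correlate runs. A
walker exceeding `max_steps` is retried on a fresh substream up to 3 times
and then raises an error — never a silent truncation — since a blown cover
time signals near-disconnection or pathological weights.

## Degenerate inputs and numerical choices

Self-loops are dropped at load (they cannot join a tree; a negative one
would unbalance every graph trivially). Exact duplicate edges collapse with
a warning; contradictory parallels are kept — curated models do assert both
activation and inhibition between the same pair. Disconnected input is a
hard error because balance relative to a single reference is ambiguous
across components; `reference_component()` extracts the reference's
component when that is what is wanted. Missing nodal scores are an error
unless `impute_zero = TRUE` is requested explicitly: silent zero-imputation
is a classic silent-failure mode. The matrix-tree determinant uses
fraction-free Bareiss elimination, so all intermediates are integers and the
count is exact far beyond the enumeration cap. An exactly-zero effective
weight is treated as carrying no direction and counts as a mislabel in
`compare_to_reference_signs()`, whose ROC sweep uses $s = +1$ as the
positive class and reports AUROC as undefined (not 0 or 1) when the
reference contains a single class.

## What the synthetic generator emulates — and what it does not

`random_signed_graph()` draws a uniform random labelled tree backbone
(connectivity guaranteed at any density, no rejection loop), adds the
remaining edges uniformly among unjoined pairs (so generated graphs are
simple; parallel-edge behaviour is exercised by hand-built fixtures),
assigns signs i.i.d. negative with probability `p_negative`, and optionally
resamples signs until the graph is unbalanced. Scores come from
`random_scores()`: unit scores (the typical-differential-expression
convention of the worked example) or i.i.d. gaussians.

This emulates the *scale and connectivity* of curated causal network models,
not their content. In particular, i.i.d. edge signs produce far more
frustration than curation does: with $E - V + 1 \approx 98$ independent
cycles of typical length ~15, roughly half of all cycles are negative at any
plausible `p_negative`, so a large fraction of nodes carry genuinely
ambiguous signs. A curated model of comparable size is typically *nearly*
consistent — a handful of edge deletions suffices to balance it — so most of
its nodes have near-deterministic signs and the sampled weights converge
visibly faster there than on our synthetic graphs. Convergence summaries
measured on the generator (e.g. the 1,000-vs-20,000-tree comparison in
`convergence_check()`, which we run at 144 nodes / 241 edges) are therefore
conservative upper bounds on what the same protocol yields on a real curated
network, and passing tests on synthetic graphs say nothing about the
biological adequacy of any particular model. The per-node difference between
a 1,000- and a 20,000-tree run is pure binomial noise with
$\mathrm{sd} = \sqrt{(1 - S_n^2)(1/1000 + 1/20000)}$, up to $\approx 0.033$
at $S_n = 0$; its median over nodes falls below 0.01 only when most nodes
have $|S_n| \gtrsim 0.95$ — true for nearly-consistent curated models, false
for i.i.d.-signed random graphs.

## Problem sizes used by the tests

The suite validates the sampler against exhaustive enumeration on graphs of
up to 8 nodes (where brute force over edge subsets is an independent
oracle), checks tree-sampling uniformity by chi-square on 4–6-node graphs at
5,000 walkers, runs the convergence protocol at 144 nodes / 241 edges with
1,000 vs 20,000 trees over three seeds, and exercises the balanced limit on
switched all-positive random graphs, where both engines must reproduce the
propagated signs exactly and with zero variance. These sizes keep every
statistical check well-powered at desk scale.

## Known limitations

* Enumeration (and the line-index-of-balance brute force) are oracles for
  small graphs; there is no polynomial-time frustration solver here.
* Wilson's loop-erased-walk sampler would also produce uniform spanning
  trees and can be faster on some graphs; the first-entrance walk is the
  method this package implements, and the one whose signed variant yields
  the visit-count estimator directly.
* The weighted ("bel") tree distribution is defined operationally by the
  weighted walk; it is not a Gibbs measure over trees with per-edge
  multiplicative weights.
* Effective weights depend only on graph structure, never on the scores;
  data-dependent summaries ($t^\ast$, $G^\ast$) can change between score
  vectors, which is a feature for dose- or time-course analyses but means
  they should not be interpreted as fixed network prunings.
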