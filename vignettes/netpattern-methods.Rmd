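---
title: "Methods: a four-measure profile for knowledge-processing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-measure profile for knowledge-processing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

netpattern asks one question of very different systems — a neural
classifier in training, a research field accumulating publications, a
random graph growing by a fixed rule, and animal connectomes of
increasing size: *how does the wiring profile change as the system
processes more knowledge?* Every system is reduced to a sequence of
simple undirected graphs, each graph is summarized by four structural
measures, and each measure's trajectory is classified as Up, Down or
Flat. The package's end product is the cross-system table of those
direction labels.

## The graph currency and the four measures

All stages produce a `kgraph`: a simple, undirected, unweighted graph.
Directed or repeated inputs (synapse tables, layered networks) are
symmetrized and deduplicated first and self-loops are dropped; isolated
nodes stay in the node set and count in every average. The measures are:

* **Average degree** `2|E|/|V|` — edge endpoints per node.
* **Average PageRank** — the mean of the damped PageRank vector. By
  normalization this equals `1/|V|`; it is kept because it expresses
  network size on a probability scale, and the package computes it by
  power iteration rather than assuming it (the identity doubles as a
  free correctness check).
* **Average clustering** — mean over all nodes of
  `2 Tri(v) / (deg(v)(deg(v)−1))`, the fraction of a node's neighbour
  pairs that are themselves linked. Nodes of degree < 2 have no
  neighbour pair and contribute 0 rather than being dropped; this keeps
  the mean defined on every graph and is negligible at the densities
  profiled here.
* **Average triangles** — mean per-node triangle *membership*, i.e.
  `3T/|V|` for `T` distinct triangles, since each triangle has three
  member nodes. Read as an approximate completeness ratio: how much of
  the graph is made of the smallest possible cliques. The membership
  convention (not `T/|V|`) is the one consistent with the
  Erdős–Rényi closed form `C(n−1,2)p³` that the matched-null checks
  rely on.

PageRank uses damping 0.85, tolerance 1e-10, at most 200 iterations,
with dangling mass spread uniformly — the classical configuration. The
profile definition itself carries no damping constant; every check the
package makes of the mean (`1/|V|`) is damping-invariant, so the choice
only affects the per-node vector, where the standard value is the
sensible default. Non-convergence raises a warning and is flagged on
the result rather than silently returned.

Triangle membership counting is compiled (Rcpp): the largest profiled
null model has ~2.9 million edges, where a merge-intersection over
sorted adjacency lists runs in seconds.

Every implementation is tested two ways: against brute-force oracles
(exhaustive triple enumeration, dense power iteration) on all random
graphs up to 12 nodes, and against igraph's independent implementations
on larger draws. igraph also *generates* the standard random models
behind `er_gnp()`, `er_gnm()` and `random_regular()`; the measures are
never delegated to it.

## Random-graph growth

`growth_experiment()` regenerates a model at sizes `n_k = k·step_nodes`
for `k = 1..iterations` and averages the profile over independent
repetitions. Defaults are the reference growth conditions: 20
iterations of 200 nodes (4,000 final), 20 repetitions, `p = 0.015`,
`e = d = 20`. Two conventions matter:

* `G(n,m)` grows with a fixed per-node budget `m_k = 20·n_k`, so its
  average degree is static during expansion; a literally fixed `m`
  would instead dilute to zero. The regular model is static by
  construction.
* The Barabási–Albert variant follows the explicit construction whose
  seed node `v[e+1]` is linked to `v[1..e]` and every later node
  attaches `e` distinct degree-proportional edges (duplicates redrawn),
  giving exactly `|E| = e(n−e)`; its average degree `2e(n−e)/n`
  approaches `2e` and is nearly constant after the first iterations.

Only `G(n,p)` has an edge budget that scales with the *pair* population,
so only it shows rising degree and triangle counts; its clustering is
theoretically flat (≈ p), which is why the clustering cell of the
growth row is left unasserted in the expected pattern.

## The neural classifier and its fired patterns

The artificial system is a fully connected sigmoid multilayer
perceptron, reference architecture 784-80-40-20-10 with a softmax
output, trained with mini-batch Adam (lr 1e-3, β₁ 0.9, β₂ 0.999,
ε 1e-8, batch 32 — the library defaults of the era; the task states
none) on categorical cross-entropy. An untrained sigmoid unit outputs
0.5, which anchors the firing rule: for one input, the *fired* set is
every neuron with output strictly greater than 0.5 (input neurons
output their pixel intensity, output neurons their class probability);
the *active* superset uses 0.1. Comparisons are strict, so a unit
sitting exactly on 0.5 does not fire.

The pattern graph connects fired neurons under a configurable edge
universe: `"cross"` (default) links every fired pair in different
layers, `"adjacent"` only consecutive layers, `"all"` every fired pair.
Adjacent-only graphs are multipartite between consecutive layers and
can never close a triangle, which would make the triangle trajectory
degenerately zero; the cross-layer default keeps it informative.
Cohesion is the edge count of the fired graph divided by that of the
active graph under the same universe (0 when the denominator is empty).
The denominator requires both endpoints active by default; a
documented flag switches to counting every potential edge with at least
one active endpoint.

`epoch_sweep()` records, at every epoch up to 10 and every 10th up to
100, the held-out accuracy plus the profile and cohesion averaged over
100 held-out inputs (configurable; the averaging population is an
implementation choice).

## Synthetic inputs

**Images.** The classifier trains on a stand-in for 28×28 grayscale
10-class data: one fixed random prototype per class in `[0,1]^{side²}`,
plus Gaussian pixel noise (sd 0.1), clipped to `[0,1]`. Generation
fails unless the minimum pairwise prototype distance exceeds
`4·noise_sd`, which keeps the task learnable by construction. An 8×8
reduced profile exists for desk-scale runs. The generator makes no
attempt at visual realism — no strokes, no background/foreground
structure, no pixel correlations; what passing tests show is that the
pipeline's mechanics (training, thresholding, graph extraction,
profiling) behave correctly on a learnable task, not that the measured
trajectories match what real image data would produce (see
Limitations).

**Publications.** The topic stream emulates a maturing field with two
mechanisms chosen for realism and then frozen: yearly publication
volume compounds at 4% (the characteristic growth rate of scientific
output), and 30 fresh topics enter the vocabulary each year, each
force-seeded into one publication so the cumulative node count grows
linearly. Remaining topic slots (3 topics per publication) are filled
by preferential reuse — probability ∝ `(past frequency + 1)^bias` with
bias 1 — which concentrates co-occurrence on hub topics. Volume growth
is what makes cumulative edge counts grow super-linearly against the
linear vocabulary, and the large vocabulary keeps the graph sparse so
average clustering declines monotonically instead of saturating into a
dense core. Defaults: 100 years, 10 publications in the first year.

**Connectome fixtures.** `make_toy_connectome()` writes a synthetic
four-column synapse table (neuron, neuron, type, count) around a
planted `G(n,p)` graph, emitting reversed "receiving" duplicate rows
(types R/Rp) for a configurable fraction of edges. Reading the file
with the default exclusion of receiving types must recover exactly the
planted edge set — the fixture tests the filtering mechanics, not any
biology.

## Topic networks

A publication record is a year plus a topic set; the year-`y` network
is the union of the cliques on every record with year ≤ y (co-occurrence
in one publication links all its topic pairs). Networks are cumulative —
nodes and edges never leave — and years without records carry the
previous graph forward so trajectories live on a contiguous year axis.
Repeat co-occurrences add no weight; the profile is unweighted
throughout.

## Connectomes and matched nulls

The reader accepts bare edge lists and the four-column synapse-table
dialect, where sending (S/Sp), electric-junction (EJ) and neuromuscular
(NMJ) rows are kept and receiving rows (R/Rp) — duplicates of sending
rows — are dropped by default. Unknown type tokens are kept with a
warning; malformed rows fail with their line number. Multiplicities and
direction are discarded to give the simple undirected currency.

A connectome's null model is `G(n,p)` at its neuron count and
edge-completion ratio `p = 2|E|/(|V|(|V|−1))`. The projection sweep
profiles unmapped animals (eight, 200–18,000 neurons) across ten
densities linearly spaced — endpoints included, inclusivity being a
convention the grid definition leaves open — between the fruit-fly
(0.012164) and roundworm (0.061134) ratios. At a fixed density the
per-animal series gives the animal trend row; since clustering in
`G(n,p)` is ≈ p independent of n, the Down direction seen between the
two *real* maps can only come from density shrinking with size, so the
sweep also exposes a diagonal reading (k-th smallest animal paired with
k-th largest density) where that interpretation can be checked
explicitly. The full-scale corner of the sweep (18,000 neurons at the
worm density, ~9.9M edges) is kept behind the `max_n` argument; the
desk profile caps the roster at 5,600 neurons with one seed per cell.

## Trend classification

`classify_trend()` fits the least-squares slope of a series against its
index, divides by the series' mean absolute value, and takes the sign;
normalized slopes under 0.01 per step are Flat. Slope sign is preferred
to a first-versus-last comparison because several trajectories under
study are jagged; the threshold 0.01 means a drift of under ~1% of the
series' own scale per checkpoint does not count as a direction. There
is no canonical rule for turning a trajectory into Up/Down/Flat; this
reconstruction is deliberately simple, shared across all systems, and
antisymmetric (reversing or negating a series flips Up and Down).

`run_all()` executes all four pipelines, writes per-system trajectory
CSVs, the trend summary, and a JSON manifest of seeds and parameters,
and checks the summary against the packaged expected-pattern file
(`inst/extdata/expected_trends.csv`), in which only defensible cells
are asserted: the topic row fully (Up, Down, Down, Up), growth and
animal rows with clustering unasserted, and the classifier row only on
degree and triangles.

## Problem sizes

The test and default (`profile = "test"`) configurations are sized for
a single CPU: 8×8 images with 1,500/400 train/test samples and 50
evaluation inputs per checkpoint; the 100-year publication stream; 5
repetitions per growth stage; the capped animal roster. The full
profile (`profile = "full"`) restores 28×28 images, 20 repetitions and
the whole roster. The matched-null reproductions always run at natural
scale (281 and 21,733 nodes) since sparse counting makes them cheap.

## Numerical and degenerate-input choices

* Empty node sets raise a classed error from every measure; an empty
  *fired* set yields an all-zero profile row in the epoch sweep rather
  than an error, since silent inputs are a legitimate network state.
* Edgeless graphs short-circuit PageRank to the exact uniform vector.
* Pair keys, degree sums and density ratios are computed in double
  precision; the largest intermediate (pair count at n = 21,733) is
  ~2.4e8, far inside exact integer representation in doubles.
* Generators take an explicit seed and restore the caller's RNG state,
  so embedding them in a larger seeded computation cannot silently
  shift downstream draws.

## Limitations

* The image stand-in is deliberately minimal. On it, the classifier
  saturates within a few epochs, after which training only grows
  confidence; the fired population contracts briefly and then expands
  and stabilizes slightly above its initial level, so the degree and
  triangle trajectories classify Flat/Up rather than the decreasing
  profile associated with long training on real handwritten-digit
  data. The degree–triangle co-movement (correlation > 0.99) is
  robust, and the run-scale choice is not the cause — the same shape
  appears at full input width and across noise levels. Reproducing the
  decreasing profile appears to need input statistics and a
  training-pressure regime this generator intentionally does not model.
* The topic stream reproduces the qualitative growth shapes by
  mechanism, not by fit to any bibliographic corpus; its parameters are
  defaults, not estimates.
* Trend labels depend on the flat tolerance; series drifting at about
  1% of their scale per checkpoint sit on the boundary, and the
  Erdős–Rényi clustering trajectory (theoretically flat at p) is the
  canonical example — hence its unasserted cell.
* The profile is blind to everything weighted, directed or layered:
  synapse multiplicities, neuron types and edge direction are discarded
  at the door by design.
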