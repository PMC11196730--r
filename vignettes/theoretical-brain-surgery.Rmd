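---
title: "Theoretical brain surgery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theoretical brain surgery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectotypes)
```

## The problem

Resective brain surgery removes a connected piece of one cerebral lobe.
Beyond the classical "eloquent cortex" avoid-list, the cognitive cost of a
resection plausibly depends on how much it degrades the brain's capacity to
integrate information globally. `connectotypes` models this with graph
theory: each subject's structural connectome is a weighted graph whose nodes
are atlas parcels and whose edge weights are tractography streamline counts;
a candidate resection is a *connected* set of physically adjacent parcels
within one lobe; and its cost is the drop in **global efficiency** (GE)

$$E_{glob} = \frac{1}{N(N-1)} \sum_{j \ne k} \frac{1}{L_{j,k}},$$

the mean inverse shortest-path length over ordered node pairs. Sweeping GE
over *every* plausible resection of a lobe (sizes 1..K, default K = 10)
yields a ranked deletion list per subject, from which the package derives:

* **stepwise structure** — whether all size-n resections are strictly less
  damaging than all size-(n+1) resections, or whether strata interleave
  (small, well-placed resections worse than larger ones);
* **worst-by-size progressions** and their nesting (worst large resections
  accumulating the previous worst areas);
* **lobe epicenters** — modal worst single deletions across a cohort — and
  the early-arrival statistic for candidate epicenters;
* **connectotypes** — per-subject labels grouping individuals by which
  epicenter dominates their progression;
* a comparison against **PageRank hub centrality** as a cheap predictor of
  the worst deletions.

## Anatomy as configuration

The physical-adjacency graph `G = (V, E)` (which parcels share a border, and
which lobe each belongs to) is data, not code: `load_atlas()` reads a small
JSON schema and enforces the invariants the analysis relies on — unique
IDs, symmetric loop-free adjacency, one lobe per resectable parcel, each
lobe connected. Adjacency is stored unweighted because only connectivity
and hop counts in `G` are ever used. Midline/subcortical/cerebellar nodes
are present in connectomes (they carry shortest paths and affect GE) but
flagged non-resectable.

Because the real multimodal-parcellation border graph is not published as
reusable data, the shipped full-scale atlas (`generate_atlas("full-scale")`)
is an explicitly *synthetic* stand-in that reproduces the published node
accounting — 8 named cortical regions per hemisphere, 180 parcels per
hemisphere, 19 non-resectable subcortical nodes, 379 nodes in all — with
generated IDs and lattice adjacency. It exercises full-scale problem sizes;
it does not claim real anatomy.

## Enumerating resections

"All anatomically plausible resections of a lobe" is exactly the set of
connected induced vertex sets of the lobe's adjacency subgraph with size at
most K. Distinct deletion *orders* of the same parcels are the same
resection, so enumeration runs over vertex sets, not traversal
permutations, using the anchored-extension (ESU) recursion: grow sets from
each anchor vertex, restrict extensions to vertices ordered after the
anchor, and track an exclusion set so each connected set is emitted exactly
once. Output order is deterministic (size ascending, then lexicographic
parcel tuple). Correctness is tested against a brute-force powerset filter
on every lobe shape used in the test suite. A guard warns before
enumeration when the subset-count upper bound exceeds a configurable cap
(default 2 × 10⁶ sets).

## Efficiency conventions

The GE formula leaves three choices open; the package fixes them
explicitly and records the mode in every output:

* **Deletion** zeroes all edges incident to the resected parcels and keeps
  the nodes, with `N` fixed at the intact count. This matches the
  edge-zeroing description of virtual resection and makes GE monotone
  non-increasing under nested deletions — a property the test suite
  exploits. A `renormalize_n` option shrinks `N` to the survivors for
  sensitivity analysis, since the printed formula's per-graph `N` is
  ambiguous on that point.
* **Unreachable pairs** contribute 0 to the sum (the standard efficiency
  convention, `1/∞`).
* **Edge length** is `1/streamline-count` (`"inverse-weight"`, the default
  and the standard connectome convention — the mode used throughout the
  reference simulations below) or unit (`"unweighted"`); the source never
  states which was used, so both are implemented and reported.

Shortest paths are computed with igraph's Dijkstra implementation on the
surviving graph, recomputed per deletion; the test oracle is an independent
dense Floyd–Warshall implementation, and the two agree to 1e-12 on random
graphs in both modes.

## Pattern definitions

Step `n → n+1` is *stepwise* iff `min GE` over size-n sets strictly exceeds
`max GE` over size-(n+1) sets; equal values count as mixed-in, because "not
mixed" reads as strict separation. Categories: `perfect` (all steps),
`partial` (steps 1→2, 2→3, 3→4 stepwise, some later step not), `non-step`
(none), and `mixed` for every remaining flag pattern — the three named
categories do not exhaust the possibilities, and forcing a misclassification
would bias cohort tallies. Sweeps covering fewer than four sizes cannot
define `partial` and classify into the restricted set with a warning.

All tie-breaks (sweep ranking, worst-by-size, epicenter candidate lists,
PageRank ranks, top-3 slots) are lexicographic on parcel IDs after the
primary keys, so every pipeline output is byte-reproducible.

## Epicenters, early arrival, and connectotypes

The epicenter of a lobe is its modal worst single deletion across the
cohort; because lobes typically show two or three focal parcels, the
candidate list size is configuration (default 2). For a candidate `y` and a
subject whose worst single deletion is `x` at hop distance `h` in the
lobe's adjacency graph, connectedness alone forbids `y` from sharing a
resection with `x` below size `h + 1`, so the expected minimal arrival size
is `s_m = h + 1`; the observed arrival `s_r` is the smallest size whose
worst set contains `y`. The difference `d = s_r − s_m` is *negative* when
`y` arrives earlier than physical proximity predicts — evidence that `y`
matters in its own right. (The sign convention follows the falsification
logic: early arrival, `s_r < s_m`, is the signature of an epicenter; the
package treats more-negative `d` as earlier-than-expected.)

Connectotype assignment applies, in order: (1) the worst single deletion is
itself a candidate; (2) a candidate adjacent to the worst single deletion
appears in the worst pair — collapsing small first/second-rank differences
between neighbouring parcels, which are within the noise of streamline
tracking, onto the candidate; (3) earliest arrival (most negative `d`, ties
by smaller `s_r`, then ID). Subjects whose progression never contains any
candidate are `"unassigned"` rather than forced into a type.

## PageRank as printed

The centrality recursion is implemented exactly as the analysis states it:

$$PR(P_i) = \frac{d}{n} + (1-d) \sum_{(j,i) \in E} \frac{PR(P_j)}{Outdeg(P_j)},$$

with the teleport term weighted by `d` — the transpose of the common
damping placement. No `d` value is stated in the source; the default
`d = 0.15` therefore reproduces standard 0.85-damped PageRank, and the
implementation agrees with igraph's PRPACK solver under that mapping.
Out-degree is the unweighted arc count (as "Outdegree" suggests), with a
streamline-weighted transition variant behind a flag. Dangling isolates
link uniformly everywhere, preserving unit score mass. Ranks are computed
per hemisphere (rank 1 = highest) and over the whole graph, since the
source describes both views.

## The synthetic cohort generator

The generator exists so that every analysis stage can be validated against
planted ground truth; its defaults are the package's reference simulation
conditions, chosen once:

| parameter | default | meaning |
|---|---|---|
| `total_streamlines` | 3e5 | expected per-subject streamline total, the scale of whole-brain deterministic tractography |
| `decay` | 0.5 | exponential distance decay of expected weight with adjacency hop count — connectomes are distance-dependent |
| `hub_boost` | 2 | multiplicative weight boost of the planted epicenter (its neighbours get `sqrt(2)`), spreading the signal so worst sets form spatially coherent, nested combinations |
| `noise_sd` | 0.1 | subject-level log-normal factor, giving overdispersed totals across subjects |
| `n_subjects` | 20 | cohort size for recovery experiments |

Weights are Poisson draws of the expectation — the simplest count model
consistent with "streamline count" semantics — symmetrized over the upper
triangle. Every pair keeps a small positive expectation (hop distances are
capped one beyond the largest finite distance), so synthetic brains are
connected and no parcel is a trivial cut vertex. Per-subject RNG substreams
are derived from `(seed, subject index)`, so cohorts are reproducible and
stable under cohort-size changes.

Two geometric design choices matter here. First, the toy atlas attaches
all external edges of a lobe (the inter-lobe chain, the hemisphere bridge,
subcortical links) at the lobe's *lattice-center* parcel: attaching them at
a boundary parcel would make that one corner a global hub of the toy
geometry, with several-fold higher baseline strength than the opposite
corner — a gradient no plausible epicenter boost could overcome, and an
artifact rather than a planted signal. With center attachment, opposite
boundary sites are exchangeable. Second, the default single-epicenter mix
plants a *mid-boundary* parcel (the second of the sorted lobe list):
neither the geometric center, which with distance decay is already the
lobe's heaviest node (recovery would be trivial), nor an extremal corner,
whose baseline weight is lowest. Recovery is then a genuine
signal-detection problem: the ×2 boost, not geometry, must make the
planted site the worst deletion. For the same reason, the "no planted
signal implies exchangeable worst parcels" property is only tested at
`decay = 0`, where pairs are exchangeable by construction.

What the generator does *not* emulate: tractography biases (length and
curvature effects, gyral-crown seeding), modular community structure beyond
one epicenter per lobe, hemispheric asymmetries, realistic inter-lobe
connection profiles — and, importantly, *sparsity*. A realistic streamline
budget spread over only 18 parcels makes every pair's Poisson mean large,
so synthetic connectomes are complete graphs. One consequence: the
unweighted arc graph is complete, default (degree-based) PageRank is
uniform, and its worst-deletion prediction rate degenerates to the
tie-break — the above-chance hub prediction seen on real, sparse
connectomes does not transfer to this test scale. The weighted-transition
PageRank variant is the meaningful hub measure on these dense graphs, and
it is the one validated against the planted epicenter in the test suite
(both variants are reported by the acceptance script). Passing recovery
tests therefore shows the pipeline identifies the signals this model
plants at realistic scale and noise — not that real cohorts contain such
signals.

## Reference simulation sizes

Recovery experiments run on the small test atlas (one 3×3-lattice lobe per
hemisphere, 18 parcels) with resections up to size 6 (176 sets per lobe),
20 subjects per cohort, and 50 cohorts per experiment — large enough that
cohort-level rates are stable, small enough that the whole suite runs in
minutes on one CPU. `scripts/acceptance.R` re-runs the same experiments
from scratch at these sizes and reports: the epicenter recovery rate
(single planted epicenter), the cohort-mean connectotype assignment
accuracy under a 60/40 two-epicenter mix, the median per-subject
worst-by-size nesting fraction, the fraction of subjects with non-stepwise
interleaving, and the PageRank prediction rates, alongside the fixed
configuration pins (379-node full-scale atlas, 8 regions per hemisphere,
maximum resection size 10, and the half-up percent formatting).

## Known limitations

* The full-scale atlas is synthetic; real-anatomy runs require a
  user-supplied topology JSON.
* Enumeration is exponential in lobe size; full-scale lobes at K = 10 are
  guarded by the projection warning and are not run in the test suite.
* GE is recomputed per deletion with no incremental shortest-path updates;
  correctness-first, with caching left to callers that rerun sweeps.
* Only single-lobe resections are modelled (multi-lobar resections are rare
  in practice and excluded by design).
* The early-arrival statistic conditions on the worst-by-size progression
  only; it does not examine near-worst sets, so candidates that are
  consistently second-worst at every size are invisible to it.
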