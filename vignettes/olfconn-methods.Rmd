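---
title: "Models and methods behind olfconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind olfconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfconn)
```

`olfconn` analyses neuron skeletons and polyadic synapses from the insect
olfactory system: the antennal lobe (AL), whose glomeruli are sampled by
uni- and multiglomerular projection neurons (uPNs, mPNs), and the
third-order neuropils their axons target. This vignette explains the models
the package implements, the parameters that matter, the numerical
conventions, and what the bundled synthetic brain does and does not
emulate.

## Coordinates and skeleton geometry

All coordinates are nanometres, the native unit of EM reconstructions;
lengths that the field reports per micron (cable lengths, synapse
densities, resampling steps) are converted at the reporting boundary only,
which avoids unit drift through the pipeline. A `skeleton` is a rooted tree
of 3D nodes; validity (single root, no cycles, no dangling parents) is
enforced at construction, so downstream algorithms can assume a tree.
`resample_points()` subdivides every parent–child edge so consecutive
points are at most one step apart (default 1 µm) while keeping all original
nodes; the inter-point gaps therefore sum exactly to the cable length.

Connectors model polyadic insect synapses: one presynaptic site with
several postsynaptic links. The connector position is the presynaptic-site
position, and polyadicity is the number of links. Several connectors may
share a presynaptic node — each synaptic cleft is counted once, however the
table was produced.

## The probabilistic glomerulus atlas

Glomerular boundaries are hard to draw by hand: dendrites leak across
them, and mPN dendrites often sit between glomeruli. The atlas therefore
represents each glomerulus as a 3D Gaussian kernel density estimate (KDE)
over a labelled point cloud (canonically, dendrite points of known uPNs).
Two parameters matter:

* **Bandwidth** (nm). Default: a Scott-style rule,
  `h = (mean within-glomerulus per-axis sd) * n^(-1/7)` with `n` the pooled
  point count — data-adaptive and standard for a 3-dimensional KDE. Kernels
  are isotropic in nm space: EM stacks have coarser z-resolution, but the
  reconstructed coordinates are already in physical units and no
  anisotropic treatment is attempted.
* **Probability threshold**. A point whose maximum glomerular density falls
  below the threshold is `unassigned`. Default: the 5% quantile of
  *leave-one-out* self-densities of the fitting clouds, i.e. the density
  above which 95% of fitting points lie. The leave-one-out correction
  matters: a fitting point's own kernel inflates its density, and without
  the correction roughly three times too many fresh points fall below the
  cut. The same threshold is used for assignment, innervation scoring and
  validation.

Innervation scoring normalizes each point's glomerular densities to
probabilities before summing, so every point contributes exactly one unit
of mass, split across glomeruli (or all in `unassigned`); innervation rows
therefore sum to 1 by construction. A deliberate consequence of the 5%
hold-out default is that about 5% of even perfectly in-distribution points
go unassigned, so "accuracy" on separable blobs is best read as correct
versus incorrect among assigned points; the test suite asserts ≥ 95% on
that measure (and ≥ 90% overall) at blob separations of ≥ 5 sd.

## PN classification

Each PN's innervation row (minus the unassigned column) is sorted in
descending order into a trace — ties broken by glomerulus name for
determinism — so that the shape, not the identity, of the innervation
pattern drives classification. Traces are averaged within externally
supplied morphology types (the package deliberately takes type labels as
input: any morphological clustering tool, or the synthetic ground truth,
can supply them), and type-average traces are clustered with average
linkage on Euclidean distances. The k = 2 cut defines superclasses; the
supercluster with the higher mean top-glomerulus score is uniglomerular.
The k = 5 cut defines subclasses named in order of decreasing sharpness
(uni, uni+ on the uniglomerular side; oligo, multi, pan on the other).
Because hierarchical cuts are nested, subclass and superclass labels are
automatically consistent; if a cut side yields more subclusters than
names, the last name is reused rather than inventing classes. Identical
traces make the distance matrix zero; the classification is then flagged
degenerate rather than cut arbitrarily. `k` is a parameter — five
subclasses is a convention, not a fact of the data.

## Anatomical transfer function

To attribute higher-brain synapses back to olfactory channels, each PN's
axonal presynapse count is split across glomeruli in proportion to its
innervation row: a uPN's synapses count fully toward its one glomerulus,
an mPN's fractionally. Mass in the unassigned column is not attributed, so
the budget total equals `sum(counts * (1 - unassigned))` — an identity the
tests check to 1e-9. Budgets can be split by any per-neuron category
(e.g. transmitter × uPN/mPN) and summarized per glomerulus, including a
Pearson correlation against glomerulus volumes when supplied (reported as
NA when either side has zero variance).

## Axon/dendrite compartmentalization

Most insect neurons have a soma fiber that splits into a dendrite and an
axon. The split is computed, never read from the SWC type column, using
centrifugal synapse flow centrality: with inputs = postsynaptic links and
outputs = presynapses (each polyadic presynapse counted once),

```
score(v) = (# inputs outside subtree(v)) * (# outputs inside subtree(v))
```

The maximizing node — ties resolved toward the root — is the split point;
its distal subtree is the axon, the remainder the dendrite. Synapse-free
segments on the root-to-split path are labelled `linker`, and the initial
run from the root `soma-fiber`; both are excluded from density
denominators, because the densities of interest describe arbors, not
fasciculated cable. A neuron with no inputs, no outputs, or a uniformly
zero score is flagged un-splittable rather than split arbitrarily.

The segregation index summarizes polarization: with `n_i` synapses and
binary input:output entropy `H_i` in compartment `i`,
`SI = 1 - (sum_i (n_i/N) H_i) / H_total`. It is 1 when inputs and outputs
separate perfectly, 0 when both compartments have the whole-cell mix, and
symmetric under relabelling axon and dendrite.

Lifetime sparseness of an input-weight vector across channels follows the
Rolls–Tovée/Willmore–Tolhurst form
`S = (1 - (Σr/n)²/(Σr²/n)) / (1 - 1/n)`: 1 for one-hot, 0 for uniform,
scale-invariant.

## Morphology-based connectivity prediction

Three predictors of increasing specificity share one length scale, delta —
the distance at which a synapse might plausibly occur. `calibrate_delta()`
estimates it as the 90% quantile of observed presynapse-to-nearest-target-
node distances; 1210 nm, the whole-brain EM value, is the shipped default.
Distances are measured to skeleton center-line nodes with no surface
offset, matching how the calibration quantity is defined.

* **Overlap score**: Gaussian kernel sum over all point pairs of the
  1-µm-resampled source axon and target dendrite.
* **Potential contacts**: source points with a target point within delta;
  qualifying points within one resampling step of each other are merged
  into a single contact site (single linkage, inclusive bound — consecutive
  resampled points sit at exactly the step). Both merged-site and raw point
  counts are returned, since the merge rule is a convention.
* **Near synapses**: presynapses within delta of the target skeleton; the
  most specific model, since it uses real output sites.

Predictions are evaluated by cosine similarity against observed
connectivity (per target-class group) and by the filling fraction:
observed count ÷ near-synapse count per pair, a proportion ≤ 1 because the
prediction is a geometric superset of the observation. Group summaries are
near-synapse-weighted means and SDs, compared across groups with a
weighted Welch t test using effective sample sizes; pairs with zero
predicted synapses are excluded and counted. The per-pair-then-weighted-
average order is a choice — pooling counts first is a defensible
alternative and would weight strong pairs even more.

## Network analysis

Synapse graphs are directed and weighted by link counts, filterable by
compartment on both ends (e.g. axo-axonic PN→PN). Conventions:

* **Weighted reciprocity**: per unordered pair, reciprocal weight
  `min(w_ij, w_ji)` over total `w_ij + w_ji`, summed across pairs. The
  canonical two-node example (5 and 2) gives 2/7 = 0.285 (truncated).
  Under this convention a perfectly symmetric graph scores 0.5 — the
  convention measures the reciprocated *fraction of pairwise weight*, and
  the package follows the published worked arithmetic rather than the
  ordered-sum variant (which would give 4/7 for the same example).
* **Local reaching centrality**: edge weights are normalized by the global
  mean weight so values are comparable with the plain reachable fraction;
  each reachable node contributes the mean normalized weight along a
  minimum-hop path (ties broken by maximum summed weight), divided by
  N − 1. On uniform weights this reduces exactly to the fraction of
  reachable nodes: a chain a→b→c gives 1, 0.5, 0. The path-choice rule is
  a documented convention; the exhaustive-path oracle in the test suite
  uses the same rule, so the contract is internally consistent.
* **Community detection**: Leiden modularity optimization under an
  explicit seed. igraph's Leiden requires an undirected graph, so
  reciprocal weights are summed before optimization; for modularity this
  symmetrization is the standard equivalent of the directed quality
  function. Isolated nodes stay unassigned (NA) rather than forming
  singleton communities.
* **Proximity null model**: the reciprocity expected from geometry alone,
  computed by building the near-synapse predicted graph and taking its
  weighted reciprocity. Observed reciprocity far below the null indicates
  genuinely directed wiring, not just spatial arrangement.
* **Input budgets**: upstream partners split at a fraction-of-input
  threshold (1% by default; 1.5% is the conventional cut when counting
  uPN partners), with budget composition by partner class.

## The synthetic brain

The generator exists so that every stage has ground truth. It emulates:
spatially clustered glomeruli (Gaussian blobs, default four on a 20-µm
grid with 3-µm sd); PNs as piecewise-linear trees with a soma-rooted
fiber, a dendritic arbor sampling glomeruli at planted fractional weights,
and an axonal arbor in a displaced target region; polyadic presynapses
placed by a Poisson process along cable (defaults 1.14/µm for cholinergic
uPN axons, 0.47/µm for GABAergic PNs, 0.19/µm axonal postsynapses) with
`1 + Poisson(mean - 1)` links per presynapse (default mean 12, matching
the stable observed mean with a wide spread); and an axo-axonic PN→PN
network with planted communities and a planted reciprocity level (default
0.074, the strongly hierarchical regime).

Two generation modes coexist deliberately. The geometric mode
(`generate_synapses`) drives the statistical targets: Poisson placement,
polyadicity, and link assignment to target nodes within a reach
`link_delta` (default 5 µm; presynapses with no target in reach are
flagged, never silently dropped — and links sample *distinct* target
nodes, since a presynapse cannot contact the same postsynaptic site
twice). The planted mode (`generate_network`) draws the axo-axonic graph
directly — Poisson pair weights, back-edges scaled by
`rho = t / (1 - t)` to hit reciprocity `t` exactly in expectation — and
then realizes it as connectors on axonal cable, so community and
hierarchy ground truth is exact rather than approximate. Community
members also share an axonal sub-region, making the planted partition
spatial as well as topological.

What the toy brain does **not** emulate: realistic branching statistics
or tortuosity (arbors are greedy nearest-neighbour trees over sampled
points), glomerular shape (real glomeruli are neither spherical nor
isotropic), extra-glomerular dendritic branches, left/right homologs,
sensory neurons, and any functional (activity) structure. Passing
recovery tests on it therefore demonstrates that the estimators are
correct and well-calibrated under their own assumptions — not that those
assumptions hold in real EM data, where the published validation numbers
(e.g. 82.4% correct atlas assignment on ~32,000 labelled sensory
synapses) are the relevant reference.

## Numerical choices and degenerate inputs

* Flow-centrality ties go to the node closest to the root; subdividing an
  edge can therefore move the compartment boundary by up to half an edge,
  and densities are invariant under subdivision only to that resolution.
* Sorting ties in traces break by glomerulus name; subclass naming reuses
  the last name when a cut side has more clusters than names.
* The contact-site merge bound is inclusive with a 1e-9 relative
  tolerance, so exactly-step-spaced resampled points merge.
* Zero-variance volumes, all-zero connectivity vectors, single-connector
  SEMs and un-splittable neurons are reported as NA/flagged, not errors;
  empty point clouds in `overlap_score` warn and return 0.
* Baker's gamma compares, for every leaf pair, the maximum number of
  clusters at which the pair still co-clusters, via Spearman correlation;
  the permutation null relabels the leaves of one tree (10,000
  permutations in the published setting; tests use fewer for speed).
* Problem sizes in the test suite (trees ≤ 50 nodes for exhaustive
  oracles, digraphs ≤ 7 nodes for path enumeration, point clouds ≤ 100
  for double loops, brains of 9–35 neurons for recovery) are chosen so
  that brute-force oracles remain exact and the whole suite runs in well
  under a minute per file.

## Known limitations

* KDE evaluation is O(points × kernel centers); atlases with very large
  fitting clouds should be thinned (the chunked evaluation bounds memory,
  not time).
* `local_reaching_centrality` uses dense adjacency and per-source BFS —
  fine for the few-hundred-node graphs it is meant for, not for
  whole-brain graphs.
* The LRC path convention and the community symmetrization are documented
  choices among defensible alternatives; numbers produced under other
  conventions will differ in detail.
* The generator's reciprocity control only spans [0, 0.5] because, under
  the pairwise min/total convention, 0.5 is full symmetry.
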