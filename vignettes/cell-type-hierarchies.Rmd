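---
title: "Learning and using cell-type hierarchies across single-cell datasets"
author: "scAtlasTree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and using cell-type hierarchies across single-cell datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

scAtlasTree operates strictly downstream of data integration. Its input
is, per dataset, a cells × d matrix of latent coordinates (d typically
10–30) produced by a reference-building model, plus one cell-type label
per cell. The package assumes the latent space is shared across
datasets — batch effects largely removed, biological variation
preserved — because that is the regime in which nearest-neighbour
relations between datasets are meaningful. Nothing in the package
normalizes counts, selects genes or fits the embedding model.

The central object is a rooted tree of cell types. A node houses one or
more `(dataset, label)` aliases: labels from different datasets judged
to denote the same population. An edge asserts that the child population
is wholly contained in the parent. The tree is also a classifier: every
internal node with two or more children carries a multiclass kNN
classifier over its children, trained on the latent coordinates of all
cells housed in each child's subtree. Cells whose alias sits at an
internal node (a coarse annotation) train that node's *parent*
classifier, not the node's own classifier among its children — a coarse
label carries no information about which subpopulation a cell belongs
to.

## The per-node classifier and its three rejection criteria

The classifier is deliberately simple: exact k-nearest-neighbour search
under the Euclidean metric. Latent spaces of variational integration
models are low-dimensional and not linearly separable, which is why a
neighbour method is used rather than a linear classifier; Euclidean
distance is the community default in such spaces, and the metric is a
config knob should that change. The posterior for class c is the
fraction of the k nearest training cells labeled c.

Parameters, defaults, and why:

* `k = 50` — the requested neighbourhood. With `dynamicNeighbors = TRUE`
  (default) k is reduced to the size of the smallest child class of the
  node, so a 20-cell population can still win its own neighbourhood;
  consequently different nodes of one tree may use different k. The
  trade-off: small k fits small populations, large k generalizes large
  ones.
* `tauPosterior = 0.5` — ambiguity rejection: a maximal posterior
  strictly below 0.5 means no class holds a majority, and the cell keeps
  the current node's (coarser) label rather than being forced into a
  child.
* distance rejection — novelty by location. For every training cell the
  mean distance to its k nearest training neighbours (self excluded) is
  computed; the threshold is the 99th percentile of those means. A query
  whose mean neighbour distance is strictly above it sits outside the
  training mass. By construction roughly 1% of cells drawn from the
  training distribution itself exceed this threshold; that background
  rejection rate is visible in resubstitution experiments and is
  intended.
* reconstruction rejection (`fnRate = 0.005`, `varianceKept = 0.9`,
  `nFolds = 5`) — novelty by shape. A PCA basis retaining 90% of the
  training variance is fitted; a query far from that subspace has a
  large squared reconstruction error. The threshold is calibrated by a
  nested loop: per outer fold (5 stratified folds), a basis is fitted on
  the training part and the `1 - fnRate` quantile of the test part's
  errors is recorded; the threshold is the median of the per-fold
  quantiles, so about 0.5% of held-out inliers are sacrificed. The
  variance fraction is a design choice: retaining everything would make
  the criterion vacuous (a full-rank basis reconstructs exactly, and the
  implementation then pins the errors to exact zero), while 90% keeps it
  sensitive to off-manifold queries in 10–30 dimensional spaces. Five
  folds is the smallest count giving a stable median of quantiles.

The three criteria are evaluated in the order distance, reconstruction,
posterior, and the first that fires is the reported reason; whether they
short-circuit is not observable in the accept/reject outcome, only in
the reported reason, and this ordering (novelty before ambiguity) is our
documented choice. Comparisons are strict — rejection requires being
strictly beyond the threshold, equality accepts — matching the wording
"lower than" / "above" for the criteria. All three criteria have
independent off switches.

Numerical conventions, pinned for reproducibility: percentiles use
linear interpolation between order statistics
(`stats::quantile(type = 7)`); neighbour ties at the k-th position break
by training-row index; posterior ties break by the smaller summed
neighbour distance, then lexicographically by class name; a training
cell is never its own neighbour during threshold fitting, but duplicated
cells are legitimate zero-distance neighbours.

## Matching cell types across datasets

Adding a labeled dataset to the tree produces two confusion matrices:
the tree's hierarchical classifier (with rejection) annotates the new
cells, and a flat kNN trained on the new dataset's labels (same
rejection machinery) annotates the tree's pooled training cells. Rows
are normalized to fractions and binarized at `matchThreshold = 0.25`;
the binarization rule and its threshold are a design choice of this
package — 0.25 tolerates a four-way split without losing majority
structure — and the threshold-sensitivity property (below) is its
guardrail. The reserved REJECTED column participates like any other.

Writing `to(L)` for the tree nodes matched by new label L and `to(N)`
for the labels matched by node N (REJECTED set aside):

* `to(L) = {N}` and `to(N) = {L}` — a reciprocal exclusive pair. The
  REJECTED fractions decide its character: if only N's row shows
  above-threshold rejection, the new-dataset classifier fails on part of
  N, so N is broader and L becomes N's child; if only L's row does, L is
  broader and is inserted between N and its parent; if neither (or
  both), the two are the same population and L merges into N as an
  alias. Rejection asymmetry as the perfect-vs-subpopulation
  discriminator is our reconstruction of behaviour documented only
  qualitatively (threshold changes flip matches between perfect and
  subpopulation); it is deliberately symmetric-case-conservative.
* `to(L) = {N}` and every label N matches is itself exclusive to N — N
  is being split: all labels exclusive to N become its children. Note L
  itself need not be matched back by N: a small or peripheral
  subpopulation can be adopted this way, which is exactly what makes
  the rejection options load-bearing (with them disabled, novel
  populations take this route into the wrong node).
* `to(L)` a set of sibling nodes, each exclusive to L — L is coarser
  than the tree: it is inserted as the siblings' new parent.
* `to(L) = {REJECTED}` and no node matches L — a population the
  reference does not contain; attached to the root. Attachment to the
  root rather than an intermediate node is a known coarseness: the
  method knows the population is new but not where it belongs.
* anything else — crossing many-to-many patterns, matches spanning
  non-siblings — is *unresolved*: the label is recorded as missing, its
  cells never enter training pools (they would contaminate
  neighbourhoods), and the user is pointed to it as a likely annotation
  inconsistency.

Datasets are added progressively, and because relations are judged
against the current tree, they should be added from low to high
annotation resolution when resolutions differ; at equal resolution the
result is order-invariant (tested over all six permutations of three
identically labeled datasets). After every update all node classifiers
are refit; training pools are subtree-cumulative, so refitting
everything is a superset of the strictly necessary path-to-root refit
and, with the fold seed fixed, identical on unchanged pools. Tree
updating never re-assigns reference cells: a subpopulation verdict adds
nodes, it does not split existing training pools. Manual curation is
supported as `deleteSubtree()` + `addNode()` + `fitClassifiers()` —
retraining after editing is the caller's duty.

## Annotating unlabeled queries

Prediction walks each cell from the root. Distance or reconstruction
rejection is terminal at any level (at the root it flags a potentially
novel cell type). Posterior rejection is not terminal in the same way:
it stops the descent and the cell keeps the current node's label — a
partial, coarse annotation that preserves the tree's value ("a T cell,
subtype unclear") — except at the root, where there is no informative
label and the cell is reported rejected with reason posterior; whether
root-level ambiguity should count as novelty is genuinely open, and the
flag leaves the interpretation to the caller. Single-child nodes are
pass-throughs.

Two prediction vectors over the same cells (for example, before and
after extending the reference) are compared by
`predictionAgreement()`: unchanged / refined (the new label is a strict
descendant of the old — annotation got deeper, not different) /
changed; the fractions are computed on integer counts and sum to
exactly 1.

## The synthetic test bed

`simulateDatasets()` emulates what a well-integrated latent space looks
like, not how it is made: leaf-cluster means are placed hierarchically
(child mean = parent mean + an isotropic offset of norm `separation`,
drawn on the unit sphere to avoid axis artifacts), cells are isotropic
unit-variance Gaussians, per-dataset resolution maps relabel leaves to
ancestors, novel clusters sit at a stated offset from the root mean,
and an optional per-dataset translation models residual batch effect.
Separations are in units of the within-cluster standard deviation, so
scenario difficulty is scale-free. Cell counts are apportioned across
leaves by largest remainder — exact, not multinomial — so class sizes
are reproducible.

Defaults of the shipped scenarios are the study conditions used
throughout the tests: 10 latent dimensions, separation 8σ, 1200 cells
per dataset for the resolution ladder (coarse/mid/fine references plus
a fine query with novel populations of 21 and 18 cells at 10σ), 450
cells for the three-leaf scenarios, novel clusters of 100 cells at 10σ
for the novelty-stress pair. These sizes keep a full build in seconds
while leaving every class far above the default k.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: non-Gaussian cluster shapes, density
gradients and doublets, partial mixing failures of the upstream
integration (clusters split by batch), label noise, and correlated
latent dimensions. Atlas-scale results on real tissues additionally
depend on the quality of the upstream neural integration, which is
outside this package entirely; the test suite instead pins the
properties such results rest on (exact oracle equivalence of the
classifier, threshold formulas, recovery/novelty/ablation behaviour on
the generator).

## Degenerate inputs and edge cases

Empty alias sets, unknown parents, duplicate aliases, non-finite
coordinates and dimension mismatches raise typed errors. A node with a
single child carries no classifier (pass-through); fitting a classifier
on one class is a degenerate-node error. `n <= k` is rejected when
fitting the distance threshold. Constant training data yields a zero
distance threshold and, at full PCA rank, exactly zero reconstruction
errors (rejection then never fires, by design). Labels are compared
exactly, case- and whitespace-sensitively, after trimming leading and
trailing whitespace at ingest — silent case-folding would hide exactly
the annotation inconsistencies the tool exists to surface.

## Evaluation conventions

For scoring, a tree is flattened by adding a directed edge from every
node to each of its descendants (transitively closed by construction).
The root is excluded by default: root edges exist for every method and
would inflate all counts equally. Edges are directed because direction
is the biological claim; an inverted relation costs one wrong plus one
missing edge. When comparing against a ground truth, learned nodes are
renamed through their aliases (a node housing aliases of several truth
populations expands to all of them); alias pairs that map into the same
truth node collapse to dropped self-edges, which makes the
perfect-vs-subpopulation distinction — the part of the verdict that is
threshold-sensitive — invisible to edge counts, exactly as intended.
Unmappable aliases are kept under an `UNMAPPED:` name and surface as
wrong edges with a reason instead of vanishing.

## Known limitations

* Novel populations attach to the root, never to an intermediate node;
  placing them deeper needs prior knowledge or manual editing.
* Labels smaller than a few dozen cells are hard to match: the
  extended rejection machinery fires on them easily, and dynamic k only
  mitigates this. (In the shipped ladder scenario the 21- and 18-cell
  novel types are *meant* to be rejected; a 20-cell population shared
  between datasets would be the hard case.)
* The matcher resolves one dataset against the current tree at a time;
  simultaneous multi-dataset matching and DAG-shaped (non-tree)
  hierarchies are out of scope, as is mapping labels onto ontology
  terms.
* The reconstruction criterion assumes an approximately linear
  low-dimensional training manifold per node; strongly curved manifolds
  inflate its false-negative calibration.
* Serialization stores tree structure only; classifiers are refit from
  the reference embeddings on restore (`restoreHierarchy()`), which
  requires keeping those embeddings.
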