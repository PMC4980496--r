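---
title: "Building rooted phylogenetic networks from incompatible cluster sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building rooted phylogenetic networks from incompatible cluster sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The problem

Gene trees estimated from different loci routinely disagree: hybridization,
horizontal transfer and recombination give some lineages more than one
parent, and no single rooted tree can display all of the clades (clusters)
observed across trees.  A rooted phylogenetic network — a rooted DAG whose
leaves are bijectively labelled by the taxa and whose *reticulate* nodes
have two or more parents — can.  `dcnet` builds such networks from a set of
clusters $\mathcal{C}$ over a taxon set $\mathcal{X}$, so that every input
cluster is represented in the *softwired* sense: for each cluster $C$ there
is a choice of one incoming edge per reticulate node (a *switching*) under
which some edge has exactly $C$ as its set of descendant leaves.

Two clusters are *compatible* when they are disjoint or nested; a set of
clusters is representable by a tree exactly when it is pairwise compatible.
The *incompatibility graph* $IG(\mathcal{C})$ joins incompatible pairs, and
its connected components are the irreducible units of conflict: the
construction is divide-and-conquer over these components, and the final
network satisfies the *decomposition property* — two clusters lie in the
same component of $IG(\mathcal{C})$ exactly when their representing edges
share a biconnected component of the network.

## ST-sets and the simplest form

An *ST-set* (strict tree set) is a taxon subset $S$, $|S| > 1$, compatible
with every cluster and whose restriction $\mathcal{C}|_S$ is compatible:
the taxa of $S$ behave like a clade and can be collapsed to a single
composite taxon without losing conflict structure.  Collapsing all maximal
ST-sets repeatedly (`to_simplest()`) yields the *simplest* form of a
cluster set, which has no ST-set at all.  Conversely, every composite taxon
decollapses into the subtree built from the clusters nested inside its
block (`subtree_for_block()`), and these blocks reappear as the maximal
subtrees of the final network.

Three boundary decisions are worth stating because the definitions do not
fix them:

* $S = \mathcal{X}$ is excluded as an ST-set candidate — collapsing the
  whole universe would destroy the instance.
* The collapse fixpoint is taken over states that still contain nontrivial
  clusters.  Once none remain, every pair of leftover taxa is vacuously an
  ST-set, the maximal ones overlap, and further collapsing is meaningless.
* Maximal ST-sets are assumed pairwise disjoint by the collapse semantics;
  this is asserted at run time and an overlap raises an error naming a
  witness pair rather than silently picking one.

Restrictions follow the definition literally: every cluster is intersected
with $S$ and only empty intersections are dropped.  An intersection equal
to $S$ itself is improper in the restricted universe but kept — it is
compatible with everything there, so ST-set tests are unaffected either
way.

## Isomorphism and the catalog

Two cluster sets are isomorphic when, after collapsing to their simplest
forms, a bijection between the universes maps one family of clusters onto
the other.  (The *weak* reading — the bijection need only preserve pairwise
co-membership — is available via `clustersets_isomorphic(strong = FALSE)`;
the strong reading is the default because network transfer relabels leaves
and requires the image to be represented cluster for cluster.)

Isomorphism classes are recognized through a canonical key: the
lexicographically minimal text encoding of the set over all taxon
relabelings.  The search is pruned by iteratively refined taxon signatures
(the multiset of containing-cluster sizes, folded with co-member
signatures), and only permutations within signature classes are
enumerated.  For the universes the catalog needs (at most 7 taxa) this is
exact and fast; universes above the configurable bound (default 10) are
rejected with a pointer to direct isomorphism testing.  Exhaustive
permutation search was chosen over a general graph-canonicalization
dependency deliberately: at these sizes exactness beats sophistication.

The catalog stores the canonical simplest sets whose incompatibility graph
is a single edge (1 class), a three-node path (4 stored classes) or a
triangle (12 classes), each with a verified network.  A component that
collapses onto a catalog entry is resolved by relabeling the stored
network through the bijection and decollapsing — no search.  The stored
networks were derived by the package's own bounded search (below) and are
re-verified by `verify_catalog()`: simplest, correct topology, softwired
representation, decomposition property, pairwise distinct keys.  The pair
and path entries use the smallest reticulation number the search space
contains (1 for the first four, 2 for the path set with the extra middle
taxon); for four of the triangle entries the bounded search is exhausted
and the constructive network below (3–5 reticulations) is stored instead,
so minimality is only reported, not asserted, for the triangle topology.
Any softwired-correct representative is sufficient: transfer is indifferent
to which network represents the class.

### The enumeration oracle — and a fifth linear class

`enumerate_simplest()` re-derives the classes from scratch: it enumerates
every set of two or three distinct proper clusters over universes of 3–7
taxa (bitmask encoding; every taxon must occur in at least one cluster,
otherwise class counts are unbounded), filters to the requested topology,
discards sets with an ST-set (a vectorized twin-taxon prefilter removes
most candidates cheaply), and merges the survivors under cluster-set
isomorphism.

For the triangle topology the oracle confirms exactly 12 classes over
universes of up to 7 taxa.  For the path topology, however, it finds
**five** classes over universes of up to 6 taxa, not four: the additional
class is

$$\{\{1,2\},\ \{1,3,4\},\ \{1,2,3,5\}\}$$

— the nested-ends path class with one private taxon in the *larger* end
cluster, exactly parallel to the way $\{\{1,2\},\{2,3,5\},\{3,4\}\}$
extends $\{\{1,2\},\{2,3\},\{3,4\}\}$ with a private middle taxon.  The
case analysis behind the four-class claim derives that the end clusters
must be nested but implicitly assumes the larger end adds no taxon of its
own.  The package keeps the classical 17-entry catalog and resolves the
fifth class through the fallback search; an independent brute-force check
of this set (all subsets tested against the ST-set definition, all
bijections against the four stored path classes) is part of the test
suite.

## Constructing a component without a catalog hit

Components whose simplest form has four or more clusters (and the fifth
path class) are resolved by `fallback_search()` in two phases.

**Bounded minimal search.**  For $r = 1, 2, \dots$ `max_r` (default 3):
removal sets of at most $r$ taxa are tried in order of increasing size,
then lexicographically.  When deleting the set leaves a compatible
restriction, its Hasse tree becomes the backbone (plus an auxiliary edge
above the root), and the removed taxa are re-attached below fresh
reticulate nodes whose parent edges are chosen exhaustively among all
current edges; multi-parent reticulations spend the remaining budget
($\sum(\mathrm{indeg}-1) = r$).  The first candidate passing the softwired
check wins, so within this space the result has minimal reticulation
number.  Each level is capped (default 1200 candidates) to keep worst-case
components predictable; caps, `max_r` and the switching cap are settable
via options (`dcnet.candidate_cap`, `dcnet.max_r`, `dcnet.switching_cap`).

**Constructive network.**  If the search is exhausted, an explicit network
is built along the Hasse diagram of cluster containment: one interior node
per cluster, hanging below the node(s) of its minimal proper supersets
(reticulate if there are several), with each taxon attached below its
minimal containing clusters (again reticulate if several).  Keeping, for a
cluster $C$, a parent inside $C$ for every cluster node below $C$ and a
minimal cluster inside $C$ for each of its taxa displays exactly $C$ at
the edge above $C$'s node, so the construction is softwired-correct for
*any* cluster set; its reticulation number
$\sum_{\text{nodes}}(\text{min-supersets}-1) +
\sum_{\text{taxa}}(\text{min-containing}-1)$ is an upper bound, not a
minimum.  This guarantees the pipeline never fails on a component, at the
price of possibly redundant reticulations — the per-component report marks
such components `fallback:constructive`.

Identically-shaped components are solved once per session: resolved
simplest forms are cached under their canonical key and reused through a
fresh bijection.

## Merging, nested components, and the maximal-subtree property

The flat divide-and-conquer narrative — build one subnetwork per component, decollapse,
hang everything off a common backbone — silently assumes that component
taxon spans do not nest.  They can: with
$\{\{1,2\},\{2,3\},\{4,5\},\{1,2,3,4\}\}$ the pair component
$\{\{1,2\},\{2,3\}\}$ lies strictly inside the span of
$\{\{4,5\},\{1,2,3,4\}\}$.  `build_network()` therefore recurses:

1. maximal ST-sets of the current instance are collapsed first (their
   interiors are compatible and decollapse into plain subtrees — this is
   what makes every maximal ST-set of the input reappear as a maximal
   subtree of the output);
2. the incompatibility graph is decomposed; only components with *maximal*
   spans are resolved at this level, and every cluster nested strictly
   inside a maximal span (other components and compatible clusters alike)
   is passed down into the recursive build of the corresponding block;
3. the maximal spans become composite leaves on the compatible Hasse
   backbone, which are then replaced by the subnetwork roots
   (`merge_subnetworks()`).

The decomposition assumptions that the flat narrative takes for granted —
spans pairwise disjoint at each level, every outside cluster compatible
with every span — are asserted at run time and raise descriptive errors
rather than being silently assumed.  Taxa declared in the universe but
absent from every cluster attach directly below the final root.

Unary nodes left by grafting are contracted in the final network.  The
result is verified end to end: every input cluster is checked softwired
(an internal error otherwise), the reticulation identity
$\sum(\mathrm{indeg}-1) = |E|-|V|+1$ is asserted, and
`check_decomposition()` searches witness mappings (bounded per-cluster
witness lists, default 32, then a backtracking assignment of distinct
biconnected components to incompatibility components) returning `TRUE`,
`FALSE`, or `NA` when the bounded search was truncated.

## What the generators emulate — and what they do not

The test fixtures are generated in code, under fixed seeds:

* *random trees* (recursive random splits, up to 12 leaves) exercise the
  tree-identity path: the clusters of a single tree rebuild that tree
  exactly;
* *expanded catalog sets* (each entry taxon replaced by a disjoint block
  of 1–3 fresh taxa — the inverse of collapsing) exercise the whole
  isomorphism-lookup-transfer-decollapse chain with known ground truth;
* *random cluster sets* (2–6 random subsets over 4–8 taxa, rejected until
  an incompatible pair exists) exercise decomposition, nested spans and
  the fallback paths.

The soundness suite runs 500 such fixtures end to end; enumeration runs at
the full catalog-relevant sizes (6 and 7 taxa).  These sizes keep the whole suite
within minutes on one core while still covering every dispatch path; they
are instance sizes the divide-and-conquer framework itself targets — real
gene-tree collections produce many small conflicting components rather
than one giant one.  What the generators do *not* emulate: estimation
error in the input trees (clusters are taken as given), components whose
simplest form exceeds ~8 taxa (the exponential ST-set and switching
machinery is capped, by design, at small component sizes), and any notion
of branch lengths or support values.  Passing tests therefore say the
construction is correct on the discrete cluster algebra, not that the
networks are biologically optimal — in particular, reticulation numbers
from the constructive fallback are upper bounds.

## Numerical and determinism choices

All orderings are locale-independent (C-collation radix sort): cluster
encodings, component order, removal sets, parent-edge combinations,
switching enumeration and canonical keys are identical across platforms,
so byte-identical outputs follow from identical inputs.  Composite taxa
are named from their sorted original blocks (`"1+2"`), which keeps
collapse results diffable.  When a catalog entry admits several bijections
onto a component (automorphisms), the lexicographically smallest is used.
eNewick output writes a hybrid node's children at its first occurrence and
bare `#Hk` references afterwards; reading goes through `ape::read.evonet`
and the two directions cross-validate each other in the tests.

## Known limitations

* Reticulation minimality is guaranteed only relative to the bounded
  search space; constructive-fallback components can be far from minimal.
* ST-set enumeration and canonicalization are exponential and bounded (16
  and 10 taxa); inputs whose *components* stay small are fine regardless
  of total taxon count, but a single large entangled component is out of
  scope, as are universes above 30 taxa for switching-based checks.
* `check_decomposition()` can return `NA` (inconclusive) when witness
  lists are truncated; the suite treats only `FALSE` as a failure.
* The decomposition-property assertions (disjoint spans, spans compatible
  with outside clusters) are conjectured to hold for every input under the
  union convention; the pipeline proves each instance at run time instead
  of relying on the conjecture.
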