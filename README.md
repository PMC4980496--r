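# dcnet — rooted phylogenetic networks from incompatible cluster sets

Rooted gene trees for the same taxa rarely agree: hybridization,
horizontal gene transfer and recombination give lineages more than one
parent, and the clades (clusters) extracted from different trees conflict.
`dcnet` builds a **rooted phylogenetic network** — a rooted DAG with
leaves bijectively labelled by the taxa and reticulate nodes of indegree
≥ 2 — that represents every input cluster in the *softwired* sense: for
each cluster *C* there is a switching (one retained incoming edge per
reticulate node) under which some edge has exactly *C* as its descendant
leaf set.

The construction is divide-and-conquer over the **incompatibility graph**
IG(𝒞) (edges join cluster pairs that are neither disjoint nor nested):

1. maximal **ST-sets** — taxon subsets that behave like clades — are
   collapsed into composite taxa (`to_simplest()`);
2. each connected component of IG(𝒞) is reduced to its *simplest* form and
   looked up, via a canonical key, in a **catalog of 17 canonical simplest
   cluster sets** (the unique 2-cluster class, 4 path classes, 12 triangle
   classes) with precomputed, verified networks; a hit is resolved by
   relabeling the stored network through the taxon bijection — no search;
3. components beyond the catalog fall back to a bounded
   minimal-reticulation search, then to an explicit constructive network;
4. composite taxa decollapse into subtrees/subnetworks and the components
   merge over the compatible Hasse backbone, so that the result satisfies
   the **decomposition property** (clusters share an IG component iff
   their representing edges share a biconnected component of the network).

The package also provides the verification machinery (softwired/hardwired
representation, reticulation numbers `∑(indeg−1) = |E|−|V|+1`, switchings,
decomposition checks, maximal subtrees), cluster-set isomorphism with
canonical keys, eNewick (`#H`) input/output, seeded fixture generators,
and an exhaustive enumeration oracle that re-derives the catalog's
isomorphism classes from scratch.

## Worked example

The cluster set 𝒞 = {{1,2}, {1,2,3}, {3,4}} is incompatible ({1,2,3} and
{3,4} overlap), so no tree represents it. {1,2} is its only maximal
ST-set:

```r
library(dcnet)
cs <- cluster_set(list(c("1","2"), c("1","2","3"), c("3","4")))
to_simplest(cs)
#> Collapse result
#> Cluster set: 2 cluster(s) over 3 taxa
#>   taxa: 1+2, 3, 4
#>   {1+2,3}
#>   {3,4}
#>   blocks:
#>     1+2 <- {1,2}
#>   dropped clusters: {1,2}
```

The collapsed set {{1+2,3},{3,4}} is isomorphic to the unique two-cluster
class {{1,2},{2,3}}, so the catalog resolves the whole instance with one
reticulation:

```r
b <- build_network(cs)
b
#> Rooted phylogenetic network: 9 nodes, 9 edges, 4 leaves, 1 reticulation(s)
#>   taxa: 1, 2, 3, 4
#> Components:
#>   [PAIR] 2 cluster(s) via catalog:pair_01, 1 reticulation(s); span {1+2,3,4}
write_enewick(b$network)
#> [1] "(((1,2))#H1,((#H1,3),4));"
sapply(maximal_subtrees(b$network), function(m) paste(m$leaves, collapse = ","))
#> [1] "3"   "4"   "1,2"
```

Reading the output: the hybrid node `#H1` carries the cherry `(1,2)` — the
decollapsed ST-set, which reappears as a maximal subtree — and its two
parents let a switching display either {1,2,3} (take the left parent) or
{1,2} alongside {3,4} (take the right), so all three input clusters are
represented with a single reticulation.

The same pipeline is available from the shell:

```sh
exec/dcnet build --clusters my.clusters        # eNewick on stdout
exec/dcnet simplify --clusters my.clusters
exec/dcnet catalog verify
exec/dcnet enumerate --topology triangle3
```

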