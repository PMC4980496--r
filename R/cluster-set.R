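#' Create a cluster set
#'
#' A cluster set is a collection of distinct clusters (proper, non-empty
#' subsets of a taxon set) together with its taxon universe.  By default the
#' universe is exactly the union of the clusters; a larger universe may be
#' declared explicitly, in which case the extra taxa take part in ST-set
#' analysis and network building but the set is rejected by the catalog and
#' canonicalization operations, which require the union convention.
#'
#' @param clusters list of character vectors, one vector of taxon labels per
#'   cluster.  Duplicate clusters are removed.
#' @param taxa optional character vector of taxon labels; must contain the
#'   union of the clusters.  Defaults to that union.
#' @param allow_improper keep clusters equal to the whole universe?  Only
#'   restrictions use this: the restriction of a superset of `s` to `s` is
#'   `s` itself, which is improper in the restricted universe but retained
#'   so that restrictions follow the definition literally.
#' @return an object of class `cluster_set` with fields `clusters` (list of
#'   sorted character vectors, deterministically ordered) and `taxa` (sorted
#'   character vector).
#' @examples
#' cluster_set(list(c("1", "2"), c("2", "3")))
#' @export
cluster_set <- function(clusters = list(), taxa = NULL, allow_improper = FALSE) {
  clusters <- lapply(clusters, function(m) sort_c(check_labels(m)))
  if (any(lengths(clusters) == 0L)) {
    stop_dcnet("clusters must be non-empty", "dcnet_invalid_cluster")
  }
  codes <- clusters_codes(clusters)
  clusters <- clusters[!duplicated(codes)]
  codes <- codes[!duplicated(codes)]
  clusters <- clusters[order_c(codes)]
  universe <- sort_c(unlist(clusters))
  if (!is.null(taxa)) {
    taxa <- sort_c(check_labels(taxa))
    if (!all(universe %in% taxa)) {
      stop_dcnet("declared taxa must contain every cluster member", "dcnet_domain_error")
    }
  } else {
    taxa <- universe
  }
  full <- vapply(clusters, function(m) length(m) == length(taxa), logical(1))
  if (any(full) && !allow_improper) {
    stop_dcnet("a cluster may not equal the whole taxon universe", "dcnet_invalid_cluster")
  }
  structure(list(clusters = clusters, taxa = taxa), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "Cluster set: %d cluster(s) over %d taxa\n",
    length(x$clusters), length(x$taxa)
  ))
  cat("  taxa: ", paste(x$taxa, collapse = ", "), "\n", sep = "")
  for (cl in x$clusters) cat("  {", paste(cl, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Is a cluster trivial?
#'
#' A cluster is trivial when it contains a single taxon.  Trivial clusters
#' are compatible with every other cluster, so they play no role in the
#' incompatibility analysis.
#'
#' @param members character vector of taxon labels.
#' @return `TRUE` iff the cluster has exactly one member.
#' @export
is_trivial_cluster <- function(members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) {
    stop_dcnet("empty cluster", "dcnet_invalid_cluster")
  }
  length(members) == 1L
}

#' Compatibility of two clusters
#'
#' Two clusters are compatible when they are disjoint or one contains the
#' other; only compatible clusters can coexist on a rooted tree.
#'
#' @param c1,c2 character vectors of taxon labels.
#' @return logical.
#' @export
are_compatible <- function(c1, c2) {
  c1 <- unique(as.character(c1))
  c2 <- unique(as.character(c2))
  ni <- sum(c1 %in% c2)
  ni == 0L || ni == length(c1) || ni == length(c2)
}

#' Incompatible taxa of two incompatible clusters
#'
#' For an incompatible pair the intersection is non-empty and neither
#' cluster contains the other; that intersection is called the incompatible
#' taxa of the pair.
#'
#' @inheritParams are_compatible
#' @return character vector, the (sorted) intersection.
#' @export
incompatible_taxa <- function(c1, c2) {
  if (are_compatible(c1, c2)) {
    stop_dcnet("clusters are compatible; incompatible taxa are undefined",
               "dcnet_precondition_error")
  }
  sort_c(intersect(c1, c2))
}

#' Is a cluster set pairwise compatible?
#'
#' @param cs a `cluster_set`.
#' @return `TRUE` iff every pair of clusters is compatible (vacuously true
#'   for fewer than two clusters).
#' @export
is_compatible_set <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  k <- length(cs$clusters)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (!are_compatible(cs$clusters[[i]], cs$clusters[[j]])) return(FALSE)
    }
  }
  TRUE
}

#' Restriction of a cluster set to a taxon subset
#'
#' Every cluster is intersected with `s`; empty intersections are dropped
#' and duplicates are merged.  An intersection equal to `s` itself is kept
#' (it is improper in the restricted universe, but the definition performs
#' no dropping and such clusters are compatible with everything).
#'
#' @param cs a `cluster_set`.
#' @param s character vector of taxa, a subset of `cs$taxa`.
#' @return a `cluster_set` over universe `s`.
#' @export
restrict_clusters <- function(cs, s) {
  stopifnot(inherits(cs, "cluster_set"))
  s <- sort_c(s)
  if (!all(s %in% cs$taxa)) {
    stop_dcnet("restriction set is not a subset of the universe", "dcnet_domain_error")
  }
  res <- lapply(cs$clusters, function(m) m[m %in% s])
  res <- res[lengths(res) > 0L]
  cluster_set(res, taxa = s, allow_improper = TRUE)
}

# Clusters with >= 2 members, as a cluster_set over the same universe.
nontrivial_clusters <- function(cs) {
  cluster_set(cs$clusters[lengths(cs$clusters) >= 2L], taxa = cs$taxa)
}

#' Clusters represented by a rooted tree
#'
#' Collects, for every non-root node `v`, the set of leaf labels descending
#' from `v`.  The full leaf set (the cluster of the root) is never included;
#' singletons are included only when `include_trivial` is `TRUE`.
#'
#' @param tree a `phylo_network` with no reticulate nodes, or an [ape]
#'   `phylo` object.
#' @param include_trivial keep singleton clusters?
#' @return a `cluster_set` whose universe is the leaf label set of the tree.
#' @export
clusters_of_tree <- function(tree, include_trivial = FALSE) {
  if (inherits(tree, "phylo")) tree <- as_phylo_network(tree)
  stopifnot(inherits(tree, "phylo_network"))
  if (reticulation_number(tree) != 0L) {
    stop_dcnet("input has reticulate nodes; expected a tree", "dcnet_precondition_error")
  }
  clusters_of_network(tree, include_trivial = include_trivial)
}

# Hardwired cluster extraction from any network: descendant leaf-label set of
# every non-root node.
clusters_of_network <- function(net, include_trivial = FALSE) {
  ix <- net_index(net)
  desc <- descendant_leafsets(ix)
  labs <- ix$taxa
  keep <- setdiff(seq_len(ix$n), ix$root)
  cl <- lapply(keep, function(v) labs[desc[v, ]])
  cl <- cl[lengths(cl) > 0L & lengths(cl) < length(labs)]
  if (!include_trivial) cl <- cl[lengths(cl) >= 2L]
  cluster_set(cl, taxa = labs)
}
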