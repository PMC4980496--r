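#' Create a rooted phylogenetic network
#'
#' A rooted phylogenetic network is a rooted DAG whose leaves (nodes of
#' outdegree 0) are bijectively labelled by taxa.  Nodes with indegree at
#' least 2 are reticulate nodes; all others are tree nodes.
#'
#' @param edges two-column character matrix of directed edges
#'   (parent, child), using arbitrary node identifiers.
#' @param leaves named character vector mapping leaf node identifiers to
#'   taxon labels.  If `NULL`, leaf identifiers are taken as their own
#'   labels.
#' @return an object of class `phylo_network` with fields `nodes`, `edges`,
#'   `root` and `leaves`.
#' @export
phylo_network <- function(edges, leaves = NULL) {
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges) == 0L) stop_dcnet("network needs at least one edge", "dcnet_invalid_network")
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    warning("parallel edges collapsed to single edges")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- sort_c(c(edges[, 1L], edges[, 2L]))
  indeg <- table(factor(edges[, 2L], levels = nodes))
  roots <- nodes[indeg == 0L]
  if (length(roots) != 1L) {
    stop_dcnet(sprintf("network must have exactly one root (found %d)", length(roots)),
               "dcnet_invalid_network")
  }
  outdeg <- table(factor(edges[, 1L], levels = nodes))
  leaf_nodes <- nodes[outdeg == 0L]
  if (is.null(leaves)) {
    leaves <- stats::setNames(leaf_nodes, leaf_nodes)
  }
  leaves <- stats::setNames(as.character(leaves), names(leaves))
  if (!vset_equal(names(leaves), leaf_nodes)) {
    stop_dcnet("`leaves` must name exactly the outdegree-0 nodes", "dcnet_invalid_network")
  }
  if (anyDuplicated(leaves)) {
    stop_dcnet("duplicate leaf labels", "dcnet_invalid_network")
  }
  check_labels(unname(leaves))
  net <- structure(
    list(nodes = nodes, edges = edges, root = roots, leaves = leaves[sort_c(names(leaves))]),
    class = "phylo_network"
  )
  ix <- net_index(net)
  if (is.null(ix$topo)) stop_dcnet("network contains a directed cycle", "dcnet_invalid_network")
  if (!all(reachable_nodes(ix, rep(TRUE, nrow(ix$edges))))) {
    stop_dcnet("network is not connected: some node unreachable from the root",
               "dcnet_invalid_network")
  }
  net
}

#' @export
print.phylo_network <- function(x, ...) {
  cat(sprintf(
    "Rooted phylogenetic network: %d nodes, %d edges, %d leaves, %d reticulation(s)\n",
    length(x$nodes), nrow(x$edges), length(x$leaves), reticulation_number(x)
  ))
  cat("  taxa: ", paste(sort_c(x$leaves), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- internal indexed form -------------------------------------------------

# Integer-indexed view of a network used by all algorithms.  Nodes are
# renumbered 1..n in C-collation order of their identifiers, which keeps
# every downstream enumeration deterministic.
net_index <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  id <- stats::setNames(seq_len(n), nodes)
  e <- cbind(id[net$edges[, 1L]], id[net$edges[, 2L]])
  dimnames(e) <- NULL
  indeg <- tabulate(e[, 2L], n)
  outdeg <- tabulate(e[, 1L], n)
  taxa <- sort_c(net$leaves)
  leaf_label <- rep(NA_character_, n)
  leaf_label[id[names(net$leaves)]] <- unname(net$leaves)
  # Kahn topological order; NULL if cyclic.
  topo <- integer(0)
  deg <- indeg
  queue <- which(deg == 0L)
  out_by <- split(seq_len(nrow(e)), factor(e[, 1L], levels = seq_len(n)))
  in_by <- split(seq_len(nrow(e)), factor(e[, 2L], levels = seq_len(n)))
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (ei in out_by[[v]]) {
      w <- e[ei, 2L]
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  list(
    n = n, nodes = nodes, edges = e, root = unname(id[net$root]),
    indeg = indeg, outdeg = outdeg, leaf_label = leaf_label, taxa = taxa,
    out_by = out_by, in_by = in_by,
    topo = if (length(topo) == n) topo else NULL
  )
}

# Nodes reachable from the root using only edges with keep == TRUE.
reachable_nodes <- function(ix, keep) {
  seen <- rep(FALSE, ix$n)
  seen[ix$root] <- TRUE
  stack <- ix$root
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (ei in ix$out_by[[v]]) {
      if (keep[ei]) {
        w <- ix$edges[ei, 2L]
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
  }
  seen
}

# Logical node x taxon matrix of descendant leaf labels, using kept edges.
descendant_leafsets <- function(ix, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, nrow(ix$edges))
  nt <- length(ix$taxa)
  m <- matrix(FALSE, ix$n, nt)
  pos <- match(ix$leaf_label, ix$taxa)
  for (v in rev(ix$topo)) {
    if (!is.na(pos[v])) m[v, pos[v]] <- TRUE
    for (ei in ix$out_by[[v]]) {
      if (keep[ei]) m[v, ] <- m[v, ] | m[ix$edges[ei, 2L], ]
    }
  }
  m
}

# ---- reticulation accounting ----------------------------------------------

#' Reticulation number of a network
#'
#' The reticulation number is the total excess indegree,
#' `sum(indeg(v) - 1)` over nodes with positive indegree, which for a
#' connected rooted DAG equals `|E| - |V| + 1`.  Both sides are computed and
#' asserted equal.
#'
#' @param net a `phylo_network`.
#' @return non-negative integer.
#' @export
reticulation_number <- function(net) {
  ix <- net_index(net)
  a <- sum(pmax(ix$indeg - 1L, 0L))
  b <- nrow(ix$edges) - ix$n + 1L
  if (a != b) {
    stop_dcnet("reticulation identity violated: network is not a connected rooted DAG",
               "dcnet_invalid_network")
  }
  as.integer(a)
}

reticulate_node_ids <- function(net) net$nodes[net_index(net)$indeg >= 2L]

#' Enumerate switchings of a network
#'
#' A switching keeps exactly one incoming edge per reticulate node and
#' removes the others; each switching displays a tree.  Switchings are
#' returned as logical keep-vectors over the rows of `net$edges`, in a
#' deterministic order.
#'
#' @param net a `phylo_network`.
#' @param cap maximum number of switchings to enumerate before raising a
#'   resource error (default 4096).
#' @return list of logical vectors.
#' @export
switchings <- function(net, cap = getOption("dcnet.switching_cap", 4096L)) {
  ix <- net_index(net)
  sw <- switchings_ix(ix, cap)
  lapply(seq_len(nrow(sw)), function(i) switching_keep(ix, sw[i, ]))
}

# Matrix of kept in-edge indices: one row per switching, one column per
# reticulate node (columns in node-index order).
switchings_ix <- function(ix, cap = 4096L) {
  retics <- which(ix$indeg >= 2L)
  if (length(retics) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  choices <- lapply(retics, function(v) sort(ix$in_by[[v]]))
  total <- prod(lengths(choices))
  if (total > cap) {
    stop_dcnet(sprintf("switching count %d exceeds cap %d", total, cap),
               "dcnet_resource_error")
  }
  as.matrix(rev(expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)))
}

# keep-vector over edges for one row of switchings_ix
switching_keep <- function(ix, sw_row) {
  keep <- rep(TRUE, nrow(ix$edges))
  retics <- which(ix$indeg >= 2L)
  for (j in seq_along(retics)) {
    drop <- setdiff(ix$in_by[[retics[j]]], sw_row[j])
    keep[drop] <- FALSE
  }
  keep
}

# ---- representation checks -------------------------------------------------

cluster_target <- function(ix, members) {
  members <- sort_c(members)
  if (!all(members %in% ix$taxa)) {
    stop_dcnet("cluster contains taxa not present among the leaves", "dcnet_domain_error")
  }
  ix$taxa %in% members
}

# Bitmask encodings (used when the universe has at most 30 taxa, which the
# switching-enumerating checks require anyway for tractability).
taxa_bitmask <- function(ix, members) {
  sum(bitwShiftL(1L, match(sort_c(members), ix$taxa) - 1L))
}

# Per-edge descendant leaf masks under one switching, filtered to leaves
# still reachable from the root; also returns node reachability.
edge_cluster_masks <- function(ix, keep) {
  reach <- reachable_nodes(ix, keep)
  pos <- match(ix$leaf_label, ix$taxa)
  desc <- integer(ix$n)
  own <- ifelse(is.na(pos), 0L, bitwShiftL(1L, pos - 1L))
  for (v in rev(ix$topo)) {
    d <- own[v]
    for (ei in ix$out_by[[v]]) {
      if (keep[ei]) d <- bitwOr(d, desc[ix$edges[ei, 2L]])
    }
    desc[v] <- d
  }
  live <- 0L
  for (v in which(reach)) live <- bitwOr(live, own[v])
  val <- bitwAnd(desc[ix$edges[, 2L]], live)
  val[!keep | !reach[ix$edges[, 2L]]] <- -1L
  list(val = val, reach = reach)
}

#' Softwired representation of a single cluster
#'
#' A network represents a cluster `C` in the softwired sense when some
#' switching contains an edge `(u, v)` such that the leaves reachable from
#' `v` — restricted to leaves still reachable from the root after the
#' switching — are exactly `C`.
#'
#' @param net a `phylo_network`.
#' @param members character vector of taxon labels (the cluster).
#' @param cap switching cap, see [switchings()].
#' @return logical.
#' @export
represents_softwired <- function(net, members,
                                 cap = getOption("dcnet.switching_cap", 131072L)) {
  ix <- net_index(net)
  if (length(ix$taxa) > 30L) {
    stop_dcnet("softwired checks are limited to at most 30 taxa", "dcnet_resource_error")
  }
  target <- taxa_bitmask(ix, members)
  sw <- switchings_ix(ix, cap)
  for (i in seq_len(nrow(sw))) {
    keep <- switching_keep(ix, sw[i, ])
    if (any(edge_cluster_masks(ix, keep)$val == target)) return(TRUE)
  }
  FALSE
}

#' Hardwired representation of a single cluster
#'
#' The network itself (no switching) must contain a tree edge `(u, v)` —
#' an edge whose head has indegree at most 1 — with descendant leaf set
#' exactly `C`.
#'
#' @inheritParams represents_softwired
#' @return logical.
#' @export
represents_hardwired <- function(net, members) {
  ix <- net_index(net)
  target <- cluster_target(ix, members)
  desc <- descendant_leafsets(ix)
  for (ei in seq_len(nrow(ix$edges))) {
    v <- ix$edges[ei, 2L]
    if (ix$indeg[v] > 1L) next
    if (identical(unname(desc[v, ]), unname(target))) return(TRUE)
  }
  FALSE
}

#' Softwired representation of a whole cluster set
#'
#' Searches, over all switchings, for witness edges for every cluster of
#' `cs`.  On success returns the witness mapping (the first witness per
#' cluster, plus all witnesses found up to `max_witnesses` for use by the
#' decomposition check); on failure reports the first unrepresented
#' cluster.
#'
#' @param net a `phylo_network` whose leaf labels include `cs`'s universe.
#' @param cs a `cluster_set`.
#' @param max_witnesses per-cluster cap on recorded witness edges.
#' @param cap switching cap.
#' @return a list with components `ok` (logical), `epsilon` (named list:
#'   cluster code -> witness edge as a length-2 character vector), `witnesses`
#'   (named list of integer edge indices), `capped` (logical: some witness
#'   list was truncated) and, when `ok` is `FALSE`, `missing` (the first
#'   unrepresented cluster).
#' @export
represents_all_softwired <- function(net, cs, max_witnesses = 32L,
                                     cap = getOption("dcnet.switching_cap", 131072L)) {
  stopifnot(inherits(cs, "cluster_set"))
  ix <- net_index(net)
  if (!all(cs$taxa %in% ix$taxa)) {
    stop_dcnet("cluster-set universe is not contained in the network's leaf set",
               "dcnet_domain_error")
  }
  if (length(ix$taxa) > 30L) {
    stop_dcnet("softwired checks are limited to at most 30 taxa", "dcnet_resource_error")
  }
  targets <- vapply(cs$clusters, function(m) taxa_bitmask(ix, m), integer(1))
  codes <- clusters_codes(cs$clusters)
  wit <- stats::setNames(vector("list", length(targets)), codes)
  capped <- FALSE
  sw <- switchings_ix(ix, cap)
  nfound <- 0L
  for (i in seq_len(nrow(sw))) {
    open <- which(lengths(wit) < max_witnesses)
    if (length(open) == 0L) break
    keep <- switching_keep(ix, sw[i, ])
    val <- edge_cluster_masks(ix, keep)$val
    for (tj in open) {
      hits <- which(val == targets[[tj]])
      if (length(hits)) {
        w <- unique(c(wit[[tj]], hits))
        if (length(w) > max_witnesses) {
          capped <- TRUE
          w <- w[seq_len(max_witnesses)]
        }
        wit[[tj]] <- w
      }
    }
  }
  found <- lengths(wit) > 0L
  if (!all(found)) {
    return(list(ok = FALSE, missing = cs$clusters[[which(!found)[1L]]],
                epsilon = NULL, witnesses = wit, capped = capped))
  }
  eps <- lapply(wit, function(w) {
    ei <- min(w)
    c(ix$nodes[ix$edges[ei, 1L]], ix$nodes[ix$edges[ei, 2L]])
  })
  list(ok = TRUE, epsilon = eps, witnesses = wit, capped = capped)
}

# ---- decomposition property ------------------------------------------------

# Biconnected component id for every edge of the underlying undirected graph.
edge_bicomp_ids <- function(net) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  bc <- igraph::biconnected_components(g)
  ids <- integer(nrow(net$edges))
  for (k in seq_along(bc$component_edges)) {
    ids[as.integer(bc$component_edges[[k]])] <- k
  }
  ids
}

#' Does a network satisfy the decomposition property for a cluster set?
#'
#' The decomposition property asks for a witness mapping `epsilon` (cluster
#' to representing tree edge) such that two clusters lie in the same
#' connected component of the incompatibility graph if and only if their
#' witness edges lie in the same biconnected component of the underlying
#' undirected network.  The property quantifies existentially over
#' `epsilon`, so alternative witness edges are searched (bounded by
#' `max_witnesses` per cluster).
#'
#' @inheritParams represents_all_softwired
#' @return `TRUE`, `FALSE`, or `NA` when the bounded witness search was
#'   truncated without finding a valid mapping (inconclusive).
#' @export
check_decomposition <- function(net, cs, max_witnesses = 32L,
                                cap = getOption("dcnet.switching_cap", 131072L)) {
  cs_nt <- nontrivial_clusters(cs)
  if (length(cs_nt$clusters) == 0L) return(TRUE)
  rep_res <- represents_all_softwired(net, cs_nt, max_witnesses = max_witnesses, cap = cap)
  if (!rep_res$ok) {
    stop_dcnet("network does not represent the cluster set; decomposition undefined",
               "dcnet_precondition_error")
  }
  bic <- edge_bicomp_ids(net)
  ig <- incompatibility_graph(cs_nt)
  comps <- ig_components(ig)
  codes <- clusters_codes(cs_nt$clusters)
  # candidate biconnected components per IG component: intersection over its
  # clusters of the bicomp ids of their witness edges
  cand <- lapply(comps, function(comp) {
    sets <- lapply(comp, function(code) unique(bic[rep_res$witnesses[[code]]]))
    Reduce(intersect, sets)
  })
  if (any(lengths(cand) == 0L)) {
    return(if (rep_res$capped) NA else FALSE)
  }
  # system of distinct representatives across components (backtracking)
  ord <- order(lengths(cand))
  chosen <- integer(0)
  ok <- sdr_backtrack(cand[ord], chosen)
  if (ok) TRUE else if (rep_res$capped) NA else FALSE
}

sdr_backtrack <- function(cand, used) {
  if (length(cand) == 0L) return(TRUE)
  for (b in cand[[1L]]) {
    if (!(b %in% used)) {
      if (sdr_backtrack(cand[-1L], c(used, b))) return(TRUE)
    }
  }
  FALSE
}

# ---- maximal subtrees ------------------------------------------------------

#' Maximal subtrees of a network
#'
#' A node `v` roots a subtree when every strict descendant of `v` has
#' indegree 1 (so the sub-DAG below `v` is a tree and no reticulate node
#' below `v` has a parent outside it).  A subtree is maximal when its root
#' is not a strict descendant of another subtree root.
#'
#' @param net a `phylo_network`.
#' @return list with one entry per maximal subtree: `node` (identifier) and
#'   `leaves` (sorted character vector of leaf labels).
#' @export
maximal_subtrees <- function(net) {
  ix <- net_index(net)
  desc <- vector("list", ix$n)
  for (v in rev(ix$topo)) {
    kids <- ix$edges[ix$out_by[[v]], 2L]
    desc[[v]] <- sort(unique(c(kids, unlist(desc[kids]))))
  }
  tree_rooted <- vapply(seq_len(ix$n), function(v) {
    below <- desc[[v]]
    length(below) == 0L || all(ix$indeg[below] == 1L)
  }, logical(1))
  maximal <- tree_rooted
  for (v in which(tree_rooted)) {
    maximal[desc[[v]]] <- FALSE
  }
  lapply(which(maximal), function(v) {
    below <- c(v, desc[[v]])
    list(node = ix$nodes[v],
         leaves = sort_c(ix$leaf_label[below][!is.na(ix$leaf_label[below])]))
  })
}
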