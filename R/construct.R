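# The divide-and-conquer construction pipeline: Hasse backbone for
# compatible sets, catalog transfer for 2- and 3-cluster components,
# bounded search (with an explicit constructive fallback) for anything
# larger, recursive decollapse, and the final merge.

# ---- Hasse tree ------------------------------------------------------------

#' Rooted tree of a compatible cluster set
#'
#' Builds the tree whose nontrivial clusters are exactly the nontrivial
#' clusters of `cs` (the Hasse diagram of the containment order): the
#' parent of every cluster is the smallest cluster properly containing it,
#' or the root; likewise for single taxa.
#'
#' @param cs a compatible `cluster_set`.
#' @return a `phylo_network` with zero reticulations over `cs$taxa`.
#' @export
hasse_tree <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!is_compatible_set(cs)) {
    stop_dcnet("cluster set is incompatible; no tree represents it", "dcnet_precondition_error")
  }
  taxa <- cs$taxa
  # trivial clusters are the leaves; a cluster equal to the universe (from a
  # restriction) is the root itself
  cl <- cs$clusters[lengths(cs$clusters) >= 2L & lengths(cs$clusters) < length(cs$taxa)]
  k <- length(cl)
  node_id <- function(i) sprintf("H%d", i)     # internal node per cluster
  root <- "H0"
  parent_of_set <- function(members, self) {
    # smallest cluster strictly containing `members`, excluding index `self`
    best <- 0L
    best_size <- length(taxa) + 1L
    for (j in seq_len(k)) {
      if (j == self) next
      cj <- cl[[j]]
      if (length(cj) > length(members) && all(members %in% cj) && length(cj) < best_size) {
        best <- j
        best_size <- length(cj)
      }
    }
    if (best == 0L) root else node_id(best)
  }
  edges <- NULL
  for (i in seq_len(k)) {
    edges <- rbind(edges, c(parent_of_set(cl[[i]], i), node_id(i)))
  }
  for (t in taxa) {
    edges <- rbind(edges, c(parent_of_set(t, 0L), paste0("L", t)))
  }
  if (is.null(edges)) stop_dcnet("empty universe", "dcnet_domain_error")
  leaves <- stats::setNames(taxa, paste0("L", taxa))
  phylo_network(edges, leaves)
}

# ---- grafting helpers ------------------------------------------------------

relabel_nodes <- function(net, prefix) {
  ren <- function(x) paste0(prefix, x)
  phylo_network(
    cbind(ren(net$edges[, 1L]), ren(net$edges[, 2L])),
    stats::setNames(unname(net$leaves), ren(names(net$leaves)))
  )
}

relabel_leaves <- function(net, map) {
  # map: named character, old label -> new label
  labs <- unname(net$leaves)
  hit <- labs %in% names(map)
  labs[hit] <- unname(map[labs[hit]])
  phylo_network(net$edges, stats::setNames(labs, names(net$leaves)))
}

# Replace the leaf labelled `label` in `host` by the root of `subnet`.
graft_leaf <- function(host, label, subnet, prefix) {
  leaf_node <- names(host$leaves)[host$leaves == label]
  stopifnot(length(leaf_node) == 1L)
  sub <- relabel_nodes(subnet, prefix)
  edges <- host$edges
  edges[edges[, 2L] == leaf_node, 2L] <- sub$root
  edges <- rbind(edges, sub$edges)
  leaves <- c(host$leaves[names(host$leaves) != leaf_node], sub$leaves)
  phylo_network(edges, leaves)
}

# Remove unary nodes (indegree <= 1, outdegree 1, not a leaf) including a
# root with a single child; harmless for representation semantics.
suppress_unary <- function(net) {
  repeat {
    ix <- net_index(net)
    un <- which(ix$indeg == 1L & ix$outdeg == 1L)
    if (length(un)) {
      v <- un[[1L]]
      ein <- ix$in_by[[v]][[1L]]
      eout <- ix$out_by[[v]][[1L]]
      edges <- net$edges
      edges[ein, 2L] <- net$nodes[ix$edges[eout, 2L]]
      edges <- edges[-eout, , drop = FALSE]
      net <- phylo_network(edges, net$leaves)
      next
    }
    if (ix$outdeg[ix$root] == 1L && nrow(ix$edges) > 1L) {
      edges <- net$edges[-ix$out_by[[ix$root]][[1L]], , drop = FALSE]
      net <- phylo_network(edges, net$leaves)
      next
    }
    break
  }
  net
}

# ---- network transfer between isomorphic cluster sets ----------------------

#' Transfer a catalog network to an isomorphic target
#'
#' Relabels the leaves of a stored network through the taxon bijection `g`
#' and then replaces every leaf labelled by a composite taxon (a collapsed
#' block) by the subtree associated with that block, yielding a network on
#' the target's original universe.
#'
#' @param entry_net the stored `phylo_network`.
#' @param g named character vector: entry taxa -> simplified target taxa.
#' @param blocks the `collapse_result` of the target set.
#' @param cs_target the original (uncollapsed) target `cluster_set`.
#' @return a `phylo_network` with leaf set `cs_target$taxa`.
#' @export
transfer_network <- function(entry_net, g, blocks, cs_target) {
  stopifnot(inherits(blocks, "collapse_result"), inherits(cs_target, "cluster_set"))
  if (!vset_equal(names(g), sort_c(entry_net$leaves)) ||
      !vset_equal(unname(g), blocks$collapsed$taxa)) {
    stop_dcnet("bijection does not match the entry leaves and the collapsed universe",
               "dcnet_contract_error")
  }
  net <- relabel_leaves(entry_net, g)
  comp <- blocks$block_map[lengths(blocks$block_map) > 1L]
  i <- 0L
  for (lab in names(comp)) {
    i <- i + 1L
    sub <- subtree_for_block(comp[[lab]], cs_target)
    net <- graft_leaf(net, lab, sub, prefix = sprintf("d%d_", i))
  }
  if (!vset_equal(sort_c(net$leaves), cs_target$taxa)) {
    stop_dcnet("transferred network does not cover the target universe",
               "dcnet_contract_error")
  }
  net
}

# ---- fallback search -------------------------------------------------------

#' Search for a network representing an incompatible simplest set
#'
#' For `r = 1..max_r`, removal sets of taxa are tried in order of
#' increasing size then lexicographically; when the restriction to the
#' remaining taxa is compatible, its Hasse tree becomes the backbone and
#' the removed taxa are re-attached below fresh reticulate nodes whose
#' parent edges are chosen exhaustively (subdividing existing edges,
#' including an auxiliary edge above the root).  The first candidate whose
#' softwired check passes is returned, so the reticulation number is
#' minimal over the searched space.  If the bounded search is exhausted, an
#' explicit constructive network is built instead (one interior node per
#' cluster, taxa shared between clusters attached through reticulate
#' nodes), unless `allow_star = FALSE`, in which case an error is raised.
#'
#' @param cs an incompatible, simplest `cluster_set`.
#' @param max_r maximum reticulation number for the search phase.
#' @param candidate_cap bound on attachment candidates tried per level.
#' @param allow_star fall back to the constructive network when the search
#'   fails?
#' @return a `phylo_network` representing every cluster of `cs` softwired.
#' @export
fallback_search <- function(cs, max_r = getOption("dcnet.max_r", 3L),
                            candidate_cap = getOption("dcnet.candidate_cap", 1200L),
                            allow_star = TRUE) {
  stopifnot(inherits(cs, "cluster_set"))
  if (is_compatible_set(cs)) {
    stop_dcnet("cluster set is compatible; build its Hasse tree instead",
               "dcnet_precondition_error")
  }
  taxa <- cs$taxa
  for (r in seq_len(max_r)) {
    budget <- candidate_cap
    for (m in seq_len(min(r, length(taxa) - 1L))) {
      # parent-count compositions: m removed taxa, sum(p_i - 1) = r
      comps <- parent_compositions(m, r)
      removals <- utils::combn(taxa, m, simplify = FALSE)
      for (R in removals) {
        keepx <- setdiff(taxa, R)
        restr <- restrict_clusters(cs, keepx)
        if (!is_compatible_set(restr)) next
        backbone <- hasse_tree(restr)
        base <- add_top_edge(backbone)
        for (pc in comps) {
          res <- attach_retics(base, R, pc, cs, budget)
          budget <- res$budget
          if (!is.null(res$net)) return(suppress_unary(res$net))
          if (budget <= 0L) break
        }
        if (budget <= 0L) break
      }
      if (budget <= 0L) break
    }
  }
  if (!allow_star) {
    stop_dcnet(sprintf("no network with at most %d reticulations found for component {%s}",
                       max_r, paste(clusters_codes(cs$clusters), collapse = " ")),
               "dcnet_unsupported_component")
  }
  star_network(cs)
}

# all assignments of parent counts >= 2 to m removed taxa with sum(p-1) == r
parent_compositions <- function(m, r) {
  if (m == 0L) return(if (r == 0L) list(integer(0)) else list())
  out <- list()
  for (p in seq.int(2L, r - m + 2L)) {
    for (rest in parent_compositions(m - 1L, r - (p - 1L))) {
      out <- c(out, list(c(p, rest)))
    }
  }
  out
}

add_top_edge <- function(net) {
  phylo_network(rbind(c("TOP", net$root), net$edges), net$leaves)
}

# Sequentially attach removed taxa below reticulate nodes, enumerating
# parent-edge subsets depth-first in deterministic edge order.
attach_retics <- function(base, removed, pcounts, cs, budget) {
  removed <- sort_c(removed)
  recurse <- function(net, i) {
    if (budget <= 0L) return(NULL)
    if (i > length(removed)) {
      budget <<- budget - 1L
      chk <- represents_all_softwired(net, cs, max_witnesses = 1L)
      return(if (chk$ok) net else NULL)
    }
    t <- removed[[i]]
    p <- pcounts[[i]]
    edges <- net$edges
    ord <- order_c(paste(edges[, 1L], edges[, 2L]))
    if (nrow(edges) < p) return(NULL)
    for (choice in utils::combn(ord, p, simplify = FALSE)) {
      if (budget <= 0L) return(NULL)
      new_edges <- edges
      hub <- sprintf("R%d", i)
      for (j in seq_along(choice)) {
        mid <- sprintf("S%d_%d", i, j)
        ei <- choice[[j]]
        new_edges <- rbind(new_edges, c(mid, new_edges[ei, 2L]), c(mid, hub))
        new_edges[ei, 2L] <- mid
      }
      new_edges <- rbind(new_edges, c(hub, paste0("L", t)))
      cand <- phylo_network(new_edges, c(net$leaves, stats::setNames(t, paste0("L", t))))
      res <- recurse(cand, i + 1L)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  net <- recurse(base, 1L)
  list(net = net, budget = budget)
}

# Constructive network along the Hasse diagram of cluster containment: one
# interior node per cluster, whose parents are the nodes of all MINIMAL
# proper supersets (the root when there is none; a reticulate node when
# there are several).  A taxon attaches below the node of each minimal
# cluster containing it (again reticulate when there are several), or
# below the root when it lies in no cluster.  For any cluster C, keeping
# for every cluster node D < C a parent inside C, and for every taxon of C
# a minimal cluster inside C, displays exactly C at the edge above C's
# node, so the network represents every cluster in the softwired sense.
star_network <- function(cs) {
  cl <- cs$clusters
  k <- length(cl)
  unode <- function(i) sprintf("U%d", i)
  minimal_supersets <- function(members, self) {
    sup <- which(vapply(seq_len(k), function(j) {
      j != self && length(cl[[j]]) > length(members) && all(members %in% cl[[j]])
    }, logical(1)))
    sup[vapply(sup, function(i) {
      !any(vapply(sup, function(j) {
        j != i && all(cl[[j]] %in% cl[[i]]) && length(cl[[j]]) < length(cl[[i]])
      }, logical(1)))
    }, logical(1))]
  }
  edges <- NULL
  for (i in seq_len(k)) {
    par <- minimal_supersets(cl[[i]], i)
    if (length(par) == 0L) {
      edges <- rbind(edges, c("TOP", unode(i)))
    } else {
      for (p in par) edges <- rbind(edges, c(unode(p), unode(i)))
    }
  }
  for (t in cs$taxa) {
    inn <- which(vapply(cl, function(x) t %in% x, logical(1)))
    inn <- inn[vapply(inn, function(i) {
      !any(vapply(inn, function(j) {
        j != i && all(cl[[j]] %in% cl[[i]]) && length(cl[[j]]) < length(cl[[i]])
      }, logical(1)))
    }, logical(1))]
    leaf <- paste0("L", t)
    if (length(inn) == 0L) {
      edges <- rbind(edges, c("TOP", leaf))
    } else if (length(inn) == 1L) {
      edges <- rbind(edges, c(unode(inn), leaf))
    } else {
      hub <- paste0("R", t)
      for (i in inn) edges <- rbind(edges, c(unode(i), hub))
      edges <- rbind(edges, c(hub, leaf))
    }
  }
  phylo_network(edges, stats::setNames(cs$taxa, paste0("L", cs$taxa)))
}

# ---- per-component construction -------------------------------------------

#' Build a subnetwork for one incompatibility-graph component
#'
#' Collapses the component to its simplest form, resolves it by catalog
#' lookup (transferring the stored network through the taxon bijection) or
#' by [fallback_search()], and decollapses the blocks back into subtrees.
#'
#' @param cs_comp `cluster_set` holding the clusters of one component (at
#'   least two clusters, pairwise connected through incompatibilities).
#' @param max_r passed to [fallback_search()].
#' @return a `phylo_network` representing `cs_comp` softwired.
#' @export
build_component <- function(cs_comp, max_r = getOption("dcnet.max_r", 3L)) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  net <- build_component_inner(cs_comp$clusters, list(), cs_comp$taxa, max_r, acc)
  chk <- represents_all_softwired(net, cs_comp, max_witnesses = 1L)
  if (!chk$ok) {
    stop_dcnet("internal error: component network fails the softwired check",
               "dcnet_internal_error")
  }
  net
}

# M: list of clusters of the component; inside: clusters of other components
# and singletons nested strictly inside the span; U: the span (universe).
build_component_inner <- function(M, inside, U, max_r, acc) {
  res <- to_simplest(cluster_set(M, taxa = U))
  S <- res$collapsed
  hit <- catalog_lookup(S)
  if (!is.null(hit)) {
    net0 <- relabel_leaves(hit$entry$network, hit$bijection)
    method <- paste0("catalog:", hit$entry$id)
    topo <- hit$entry$topology
  } else {
    got <- fallback_cached(S, max_r)
    net0 <- got$net
    method <- got$method
    topo <- classify_big(S)
  }
  acc$rows <- c(acc$rows, list(list(
    span = paste(U, collapse = ","),
    n_clusters = length(M),
    topology = topo,
    method = method,
    reticulations = reticulation_number(net0)
  )))
  # decollapse: composite leaves become recursively built subnetworks
  comp <- res$block_map[lengths(res$block_map) > 1L]
  all_inside <- c(M, inside)
  i <- 0L
  for (lab in names(comp)) {
    i <- i + 1L
    B <- comp[[lab]]
    inner <- all_inside[vapply(all_inside, function(cl) {
      all(cl %in% B) && length(cl) < length(B)
    }, logical(1))]
    sub <- build_rec(inner, B, max_r, acc)
    net0 <- graft_leaf(net0, lab, sub, prefix = sprintf("d%d_", i))
  }
  # anything nested inside the span must now be covered by a block or equal it
  left <- inside[vapply(inside, function(cl) {
    !any(vapply(comp, function(B) all(cl %in% B), logical(1)))
  }, logical(1))]
  if (length(left)) {
    stop_dcnet(sprintf("cluster {%s} is nested in a component span but in no block",
                       cluster_code(left[[1L]])), "dcnet_assumption_violated")
  }
  net0
}

classify_big <- function(S) {
  ig <- incompatibility_graph(S)
  comps <- ig_components(ig)
  if (length(comps) == 1L) classify_component(comps[[1L]], ig)$tag else "OTHER"
}

# Session cache: simplest components already solved by the search are reused
# through their canonical key and a fresh bijection.
.dcnet_cache <- new.env(parent = emptyenv())

fallback_cached <- function(S, max_r) {
  key <- tryCatch(canonical_key(S), error = function(e) NULL)
  if (!is.null(key) && !is.null(.dcnet_cache[[key]])) {
    hit <- .dcnet_cache[[key]]
    bij <- iso_simplest(hit$cs, S)
    return(list(net = relabel_leaves(hit$net, bij), method = hit$method))
  }
  net <- fallback_search(S, max_r = max_r)
  method <- if (any(grepl("^U\\d+$", net$nodes))) "fallback:constructive"
            else sprintf("fallback:search(r=%d)", reticulation_number(net))
  if (!is.null(key)) .dcnet_cache[[key]] <- list(cs = S, net = net, method = method)
  list(net = net, method = method)
}

# ---- merge -----------------------------------------------------------------

#' Merge component subnetworks and compatible clusters
#'
#' The span of each component (the union of its taxa) is treated as a
#' composite taxon; the compatible backbone over these spans, the remaining
#' clusters and the leftover taxa is the Hasse tree, and each span leaf is
#' then replaced by the root of its subnetwork.  The decomposition
#' assumption — every span is compatible with every cluster outside its
#' component — is asserted and violations raise an error naming a witness.
#'
#' @param subnets list of `phylo_network` objects, one per component.
#' @param singles list of clusters (character vectors) lying in singleton
#'   components, plus trivial clusters.
#' @param universe character vector, the full taxon set.
#' @return a `phylo_network` over `universe`.
#' @export
merge_subnetworks <- function(subnets, singles, universe) {
  spans <- lapply(subnets, function(nt) sort_c(nt$leaves))
  if (length(spans) >= 2L) {
    for (i in seq_len(length(spans) - 1L)) {
      for (j in seq.int(i + 1L, length(spans))) {
        if (length(intersect(spans[[i]], spans[[j]]))) {
          stop_dcnet("component spans overlap; decomposition assumption violated",
                     "dcnet_assumption_violated")
        }
      }
    }
  }
  singles <- lapply(singles, sort_c)
  backbone_cs <- tryCatch(
    relabel_by_blocks(cluster_set(singles, taxa = sort_c(universe)), spans),
    dcnet_assumption_violated = function(e) {
      stop_dcnet(paste0("a cluster is incompatible with a component span: ",
                        conditionMessage(e)), "dcnet_assumption_violated")
    }
  )
  for (d in backbone_cs$dropped) {
    if (!any(vapply(spans, function(s) vset_equal(s, d), logical(1)))) {
      stop_dcnet(sprintf("cluster {%s} lies strictly inside a component span at merge time",
                         cluster_code(d)), "dcnet_assumption_violated")
    }
  }
  host <- hasse_tree(backbone_cs$collapsed)
  labels <- vapply(spans, composite_label, character(1))
  for (i in seq_along(subnets)) {
    host <- graft_leaf(host, labels[[i]], subnets[[i]], prefix = sprintf("m%d_", i))
  }
  host
}

# ---- full pipeline ---------------------------------------------------------

build_rec <- function(K, X, max_r, acc) {
  K <- K[!duplicated(clusters_codes(K))]
  K <- K[lengths(K) >= 2L]
  if (length(K) == 0L) {
    return(hasse_tree(cluster_set(list(), taxa = X)))
  }
  csK <- cluster_set(K, taxa = X)
  if (is_compatible_set(csK)) {
    return(hasse_tree(csK))
  }
  # Collapse the instance's own maximal ST-sets first, so that they come
  # back as maximal subtrees of the result (blocks have compatible
  # interiors and decollapse into plain trees).
  if (length(X) <= 16L) {
    mst <- maximal_st_sets(csK)
    if (length(mst) > 0L) {
      res <- relabel_by_blocks(csK, mst)
      host <- build_rec(res$collapsed$clusters, res$collapsed$taxa, max_r, acc)
      comp <- res$block_map[lengths(res$block_map) > 1L]
      i <- 0L
      for (lab in names(comp)) {
        i <- i + 1L
        B <- comp[[lab]]
        inner <- K[vapply(K, function(cl) all(cl %in% B) && length(cl) < length(B),
                          logical(1))]
        host <- graft_leaf(host, lab, build_rec(inner, B, max_r, acc),
                           prefix = sprintf("s%d_", i))
      }
      return(host)
    }
  }
  ig <- incompatibility_graph(csK)
  comps <- ig_components(ig)
  multi <- comps[lengths(comps) >= 2L]
  if (length(multi) == 0L) {
    return(hasse_tree(csK))
  }
  codes <- clusters_codes(K)
  comp_clusters <- lapply(multi, function(cm) K[match(cm, codes)])
  spans <- lapply(comp_clusters, function(cls) sort_c(unlist(cls)))
  # maximal spans; nested components are resolved inside their enclosing span
  is_max <- vapply(seq_along(spans), function(i) {
    !any(vapply(seq_along(spans), function(j) {
      i != j && all(spans[[i]] %in% spans[[j]]) && length(spans[[j]]) > length(spans[[i]])
    }, logical(1)))
  }, logical(1))
  if (anyDuplicated(vapply(spans[is_max], paste, character(1), collapse = ","))) {
    stop_dcnet("two components share the same taxon span", "dcnet_assumption_violated")
  }
  keep <- which(is_max)
  used <- unlist(comp_clusters[keep], recursive = FALSE)
  used_codes <- clusters_codes(used)
  subnets <- vector("list", length(keep))
  inside_codes <- character(0)
  for (kidx in seq_along(keep)) {
    i <- keep[[kidx]]
    U <- spans[[i]]
    inside <- K[vapply(seq_along(K), function(j) {
      !(codes[j] %in% used_codes) && all(K[[j]] %in% U) && length(K[[j]]) < length(U)
    }, logical(1))]
    inside_codes <- c(inside_codes, clusters_codes(inside))
    subnets[[kidx]] <- build_component_inner(comp_clusters[[i]], inside, U, max_r, acc)
  }
  singles <- K[!(codes %in% c(used_codes, inside_codes))]
  merge_subnetworks(subnets, singles, X)
}

#' Build a rooted phylogenetic network from clusters or trees
#'
#' The full divide-and-conquer pipeline: extract nontrivial clusters (when
#' trees are given), split the incompatibility graph into connected
#' components, collapse each component to its simplest form, resolve it by
#' catalog lookup or bounded search, decollapse, and merge the subnetworks
#' over the compatible backbone.  The result is verified to represent every
#' input cluster in the softwired sense.
#'
#' @param input a `cluster_set`, or a list of rooted trees
#'   (`phylo_network` or ape `phylo` objects) whose nontrivial clusters are
#'   pooled.
#' @param max_r passed to [fallback_search()].
#' @return an object of class `dc_build`: `network` (the `phylo_network`),
#'   `per_component` (one row per resolved component: span, topology,
#'   method, reticulations), and `witness` (the softwired witness mapping).
#' @examples
#' b <- build_network(cluster_set(list(c("1", "2"), c("2", "3"))))
#' reticulation_number(b$network)
#' @export
build_network <- function(input, max_r = getOption("dcnet.max_r", 3L)) {
  if (inherits(input, "cluster_set")) {
    cs <- input
  } else if (is.list(input) && length(input) > 0L &&
             all(vapply(input, inherits, logical(1), what = c("phylo_network", "phylo")))) {
    parts <- lapply(input, clusters_of_tree, include_trivial = FALSE)
    cs <- cluster_set(
      unlist(lapply(parts, `[[`, "clusters"), recursive = FALSE),
      taxa = sort_c(unlist(lapply(parts, `[[`, "taxa")))
    )
  } else {
    stop_dcnet("input must be a cluster_set or a non-empty list of rooted trees",
               "dcnet_domain_error")
  }
  if (length(cs$taxa) == 0L) stop_dcnet("empty taxon universe", "dcnet_domain_error")
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  K <- cs$clusters[lengths(cs$clusters) >= 2L]
  net <- suppress_unary(build_rec(K, cs$taxa, max_r, acc))
  chk <- represents_all_softwired(net, cs, max_witnesses = 1L)
  if (!chk$ok) {
    stop_dcnet(sprintf("internal error: built network misses cluster {%s}",
                       cluster_code(chk$missing)), "dcnet_internal_error")
  }
  structure(list(network = net, per_component = acc$rows, witness = chk$epsilon),
            class = "dc_build")
}

#' @export
print.dc_build <- function(x, ...) {
  print(x$network)
  if (length(x$per_component)) {
    cat("Components:\n")
    for (row in x$per_component) {
      cat(sprintf("  [%s] %d cluster(s) via %s, %d reticulation(s); span {%s}\n",
                  row$topology, row$n_clusters, row$method, row$reticulations, row$span))
    }
  } else {
    cat("No incompatible components: plain Hasse tree.\n")
  }
  invisible(x)
}
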