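# ST-sets, Collapse, and the simplest form of a cluster set.

#' Is a taxon subset an ST-set?
#'
#' An ST-set (strict tree set) of a cluster set is a subset `s` of the
#' universe with more than one taxon that is compatible with every cluster
#' and whose restriction `cs|_s` is itself a compatible set.  The whole
#' universe is excluded as a candidate (collapsing it would destroy the
#' instance).
#'
#' @param s character vector of taxa.
#' @param cs a `cluster_set`.
#' @return logical.
#' @export
is_st_set <- function(s, cs) {
  stopifnot(inherits(cs, "cluster_set"))
  s <- sort_c(s)
  if (!all(s %in% cs$taxa)) {
    stop_dcnet("candidate set is not a subset of the universe", "dcnet_domain_error")
  }
  if (length(s) < 2L || length(s) == length(cs$taxa)) return(FALSE)
  for (cl in cs$clusters) {
    if (!are_compatible(s, cl)) return(FALSE)
  }
  is_compatible_set(restrict_clusters(cs, s))
}

# All ST-sets as bitmasks over the sorted universe (vectorized).  Bound at
# 16 taxa: the enumeration is exponential and every pipeline use operates on
# small collapsed components.
st_set_masks <- function(cs) {
  n <- length(cs$taxa)
  if (n > 16L) {
    stop_dcnet("ST-set enumeration is limited to universes of at most 16 taxa",
               "dcnet_resource_error")
  }
  if (n < 3L) return(integer(0))
  full <- bitwShiftL(1L, n) - 1L
  masks <- seq_len(full - 1L)
  pc <- popcount16(masks)
  masks <- masks[pc >= 2L & pc < n]
  if (length(masks) == 0L) return(integer(0))
  cm <- cluster_masks(cs$clusters, cs$taxa)
  ok <- rep(TRUE, length(masks))
  for (m in cm) {
    a <- bitwAnd(masks, m)
    ok <- ok & (a == 0L | a == masks | a == m)
    if (!any(ok)) return(integer(0))
  }
  k <- length(cm)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (are_compatible(cs$clusters[[i]], cs$clusters[[j]])) next
        ri <- bitwAnd(cm[[i]], masks)
        rj <- bitwAnd(cm[[j]], masks)
        a <- bitwAnd(ri, rj)
        ok <- ok & (a == 0L | a == ri | a == rj)
        if (!any(ok)) return(integer(0))
      }
    }
  }
  masks[ok]
}

popcount16 <- function(x) {
  cnt <- integer(length(x))
  while (any(x > 0L)) {
    cnt <- cnt + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  cnt
}

cluster_masks <- function(clusters, taxa) {
  lapply(clusters, function(m) {
    sum(bitwShiftL(1L, match(m, taxa) - 1L))
  })
}

mask_to_taxa <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftR(mask, seq_along(taxa) - 1L), 1L) == 1L]
}

#' Maximal ST-sets of a cluster set
#'
#' All ST-sets not properly contained in another ST-set.  The collapse
#' semantics assume maximal ST-sets are pairwise disjoint; this is asserted
#' at run time and violated overlaps raise an error naming a witness pair.
#'
#' @param cs a `cluster_set` (at most 16 taxa).
#' @return list of sorted character vectors, deterministically ordered.
#' @export
maximal_st_sets <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  masks <- st_set_masks(cs)
  if (length(masks) == 0L) return(list())
  maximal <- vapply(masks, function(s) {
    !any(masks != s & bitwAnd(masks, s) == s)
  }, logical(1))
  mx <- masks[maximal]
  if (length(mx) >= 2L) {
    for (i in seq_len(length(mx) - 1L)) {
      for (j in seq.int(i + 1L, length(mx))) {
        if (bitwAnd(mx[i], mx[j]) != 0L) {
          stop_dcnet(sprintf(
            "maximal ST-sets overlap: {%s} and {%s}",
            paste(mask_to_taxa(mx[i], cs$taxa), collapse = ","),
            paste(mask_to_taxa(mx[j], cs$taxa), collapse = ",")
          ), "dcnet_assumption_violated")
        }
      }
    }
  }
  blocks <- lapply(mx, mask_to_taxa, taxa = cs$taxa)
  blocks[order_c(clusters_codes(blocks))]
}

#' Is a cluster set simplest?
#'
#' A cluster set is simplest when it has no ST-set at all (equivalently, no
#' maximal ST-set), so no collapse is possible.
#'
#' @param cs a `cluster_set` (at most 16 taxa).
#' @return logical.
#' @export
is_simplest <- function(cs) {
  length(st_set_masks(cs)) == 0L
}

#' Collapse all maximal ST-sets once
#'
#' Every maximal ST-set is replaced, in every cluster and in the universe,
#' by a single fresh composite taxon named from the sorted block
#' (`"1+2"` style).  Clusters that become trivial or duplicate are dropped
#' and recorded.
#'
#' @param cs a `cluster_set`.
#' @return an object of class `collapse_result`: `collapsed` (the new
#'   `cluster_set`), `block_map` (named list: taxon of the new universe ->
#'   character vector of input taxa it stands for; identity for untouched
#'   taxa) and `dropped` (list of input clusters that became trivial or
#'   duplicate).
#' @export
collapse_once <- function(cs) {
  blocks <- maximal_st_sets(cs)
  relabel_by_blocks(cs, blocks)
}

relabel_by_blocks <- function(cs, blocks) {
  labels <- vapply(blocks, composite_label, character(1))
  in_block <- unlist(blocks)
  new_taxa <- c(setdiff(cs$taxa, in_block), labels)
  new_clusters <- list()
  dropped <- list()
  seen <- character(0)
  for (cl in cs$clusters) {
    out <- setdiff(cl, in_block)
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      ni <- sum(bl %in% cl)
      if (ni == 0L) next
      if (ni == length(bl)) {
        out <- c(out, labels[b])        # block inside the cluster
      } else if (all(cl %in% bl)) {
        out <- labels[b]                # cluster inside the block -> trivial
        break
      } else {
        stop_dcnet("block is incompatible with a cluster; not an ST-set",
                   "dcnet_assumption_violated")
      }
    }
    code <- cluster_code(out)
    if (length(out) < 2L || code %in% seen) {
      dropped <- c(dropped, list(cl))
    } else {
      new_clusters <- c(new_clusters, list(sort_c(out)))
      seen <- c(seen, code)
    }
  }
  block_map <- c(
    stats::setNames(as.list(setdiff(cs$taxa, in_block)), setdiff(cs$taxa, in_block)),
    stats::setNames(blocks, labels)
  )
  structure(list(
    collapsed = cluster_set(new_clusters, taxa = new_taxa),
    block_map = block_map[sort_c(names(block_map))],
    dropped = dropped
  ), class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("Collapse result\n")
  print(x$collapsed)
  comp <- x$block_map[lengths(x$block_map) > 1L]
  if (length(comp)) {
    cat("  blocks:\n")
    for (nm in names(comp)) {
      cat("    ", nm, " <- {", paste(comp[[nm]], collapse = ","), "}\n", sep = "")
    }
  }
  if (length(x$dropped)) {
    cat("  dropped clusters:",
        paste(vapply(x$dropped, function(d) paste0("{", paste(d, collapse = ","), "}"),
                     character(1)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Collapse a cluster set to its simplest form
#'
#' Applies [collapse_once()] repeatedly until no ST-set remains.  The
#' block map is composed across rounds, so returned blocks always name
#' taxa of the original input.
#'
#' @param cs a `cluster_set`.
#' @return a `collapse_result`; `collapsed` satisfies [is_simplest()].
#' @export
to_simplest <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  map <- stats::setNames(as.list(cs$taxa), cs$taxa)
  dropped <- list()
  cur <- cs
  repeat {
    # once no nontrivial cluster remains there is nothing left to simplify
    # (and maximal ST-sets of an empty family are not well defined)
    if (all(lengths(cur$clusters) < 2L)) break
    if (length(cur$taxa) > 16L) {
      # the exhaustive enumeration is out of reach: shrink the universe by
      # collapsing two-taxon ST-sets first (any ST-set collapse preserves
      # the eventual fixpoint; maximality is re-established below 16 taxa)
      pair <- find_pair_st_set(cur)
      if (is.null(pair)) {
        stop_dcnet("universe above 16 taxa with no two-taxon ST-set; cannot simplify",
                   "dcnet_resource_error")
      }
      step <- relabel_by_blocks(cur, list(pair))
      changed <- TRUE
    } else {
      step <- collapse_once(cur)
      changed <- length(step$block_map[lengths(step$block_map) > 1L]) > 0L
    }
    # expand this round's blocks and dropped clusters to original taxa
    expand <- function(members) sort_c(unlist(map[members]))
    dropped <- c(dropped, lapply(step$dropped, expand))
    map <- stats::setNames(
      lapply(step$block_map, expand),
      names(step$block_map)
    )
    cur <- step$collapsed
    if (!changed) break
  }
  # composite labels already name sorted original blocks by construction
  structure(list(collapsed = cur, block_map = map[sort_c(names(map))], dropped = dropped),
            class = "collapse_result")
}

# first two-taxon ST-set in deterministic order, or NULL
find_pair_st_set <- function(cs) {
  n <- length(cs$taxa)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- c(cs$taxa[i], cs$taxa[j])
      if (is_st_set(s, cs)) return(s)
    }
  }
  NULL
}

#' Subtree associated with an ST-set
#'
#' The rooted tree on leaf set `s` whose nontrivial clusters are exactly
#' the clusters of `cs` strictly contained in `s` (Hasse construction);
#' its root corresponds to `s` itself.  Used to decollapse a composite
#' taxon back into the taxa it stands for.
#'
#' @param s an ST-set of `cs`.
#' @param cs a `cluster_set`.
#' @return a `phylo_network` with zero reticulations.
#' @export
subtree_for_block <- function(s, cs) {
  if (!is_st_set(s, cs)) {
    stop_dcnet("`s` is not an ST-set of the cluster set", "dcnet_precondition_error")
  }
  s <- sort_c(s)
  inside <- cs$clusters[vapply(cs$clusters, function(cl) {
    all(cl %in% s) && length(cl) < length(s)
  }, logical(1))]
  hasse_tree(cluster_set(inside, taxa = s))
}
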