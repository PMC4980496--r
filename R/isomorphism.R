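# Isomorphism of cluster sets and of networks, and canonical keys for
# catalog lookup.

# Iteratively refined taxon signatures (invariant under taxon renaming).
# Round 0: sorted sizes of the clusters containing the taxon.  Each further
# round folds in the signatures of co-members, cluster by cluster.
taxon_signatures <- function(cs, rounds = 2L) {
  taxa <- cs$taxa
  sig <- vapply(taxa, function(t) {
    paste(sort(vapply(cs$clusters, function(cl) if (t %in% cl) length(cl) else NA_integer_,
                      integer(1)), na.last = NA), collapse = ".")
  }, character(1))
  for (r in seq_len(rounds)) {
    sig <- vapply(taxa, function(t) {
      per_cluster <- vapply(cs$clusters, function(cl) {
        if (!(t %in% cl)) return(NA_character_)
        paste(sort_keep_dup(sig[setdiff(cl, t)]), collapse = "/")
      }, character(1))
      paste(sig[[t]], paste(sort_keep_dup(per_cluster[!is.na(per_cluster)]), collapse = ";"),
            sep = "|")
    }, character(1))
    names(sig) <- taxa
  }
  sig
}

#' Isomorphism of two cluster sets
#'
#' Both sets are first collapsed to their simplest forms; the sets are
#' isomorphic when a bijection between the simplified universes maps one
#' cluster family onto the other (the strong reading of cluster-set
#' isomorphism).  With `strong = FALSE` only pairwise co-membership is
#' required to be preserved, which is the literal reading; the strong form
#' is what network transfer needs, because the relabelled network must
#' represent the target set cluster for cluster.
#'
#' @param a,b `cluster_set` objects.
#' @param strong require the bijection to induce a bijection of cluster
#'   families (default) rather than only preserving co-membership.
#' @return a named character vector (names: simplified universe of `a`,
#'   values: simplified universe of `b`), or `NULL` when no bijection
#'   exists.
#' @export
clustersets_isomorphic <- function(a, b, strong = TRUE) {
  stopifnot(inherits(a, "cluster_set"), inherits(b, "cluster_set"))
  sa <- to_simplest(a)$collapsed
  sb <- to_simplest(b)$collapsed
  iso_simplest(sa, sb, strong = strong)
}

# Bijection search between two already-simplest cluster sets.
iso_simplest <- function(sa, sb, strong = TRUE, all_bijections = FALSE) {
  if (length(sa$taxa) != length(sb$taxa)) return(NULL)
  if (strong) {
    if (length(sa$clusters) != length(sb$clusters)) return(NULL)
    if (!identical(sort(lengths(sa$clusters)), sort(lengths(sb$clusters)))) return(NULL)
  }
  siga <- taxon_signatures(sa)
  sigb <- taxon_signatures(sb)
  if (!identical(sort_keep_dup(siga), sort_keep_dup(sigb))) return(NULL)
  bcodes <- clusters_codes(sb$clusters)
  check <- function(map) {
    if (strong) {
      img <- vapply(sa$clusters, function(cl) cluster_code(unname(map[cl])), character(1))
      all(img %in% bcodes) && !anyDuplicated(img)
    } else {
      co_member <- function(cs, x, y) {
        any(vapply(cs$clusters, function(cl) x %in% cl && y %in% cl, logical(1)))
      }
      tx <- sa$taxa
      for (i in seq_along(tx)) {
        for (j in seq_along(tx)) {
          if (i == j) next
          if (co_member(sa, tx[i], tx[j]) != co_member(sb, map[[tx[i]]], map[[tx[j]]])) {
            return(FALSE)
          }
        }
      }
      TRUE
    }
  }
  ta <- sa$taxa[order_c(paste(siga, sa$taxa))]
  found <- list()
  assign_next <- function(map, used) {
    if (length(map) == length(ta)) {
      m <- stats::setNames(unlist(map), names(map))
      if (check(m)) {
        found[[length(found) + 1L]] <<- m[sort_c(names(m))]
        return(!all_bijections)
      }
      return(FALSE)
    }
    t <- ta[[length(map) + 1L]]
    cands <- sb$taxa[sigb == siga[[t]] & !(sb$taxa %in% used)]
    for (cand in cands) {
      map2 <- map
      map2[[t]] <- cand
      if (assign_next(map2, c(used, cand))) return(TRUE)
    }
    FALSE
  }
  assign_next(stats::setNames(list(), character(0)), character(0))
  if (length(found) == 0L) return(NULL)
  if (all_bijections) found else found[[1L]]
}

# All bijections between two simplest sets (used to pick a deterministic,
# lexicographically smallest one at catalog lookup).
iso_simplest_all <- function(sa, sb, strong = TRUE) {
  res <- iso_simplest(sa, sb, strong = strong, all_bijections = TRUE)
  if (is.null(res)) return(list())
  res
}

#' Canonical key of a simplest cluster set
#'
#' The lexicographically minimal text encoding of the set over all taxon
#' relabelings compatible with the refined taxon signatures.  Two simplest
#' sets receive equal keys exactly when they are isomorphic (strong form).
#' The universe must equal the union of the clusters.
#'
#' @param cs a simplest `cluster_set`.
#' @param bound maximum universe size (default 10); beyond it, test
#'   isomorphism directly with [clustersets_isomorphic()].
#' @return character scalar.
#' @export
canonical_key <- function(cs, bound = getOption("dcnet.canonical_bound", 10L)) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!vset_equal(cs$taxa, sort_c(unlist(cs$clusters)))) {
    stop_dcnet("canonical keys require the universe to equal the union of clusters",
               "dcnet_domain_error")
  }
  if (length(cs$taxa) > bound) {
    stop_dcnet(sprintf(
      "universe larger than canonicalization bound (%d); use clustersets_isomorphic()",
      bound), "dcnet_resource_error")
  }
  if (!is_simplest(cs)) {
    stop_dcnet("canonical keys are defined for simplest cluster sets; collapse first",
               "dcnet_precondition_error")
  }
  n <- length(cs$taxa)
  if (n == 0L) return("")
  sig <- taxon_signatures(cs)
  classes <- split(cs$taxa, sig)
  classes <- classes[order_c(names(classes))]
  sizes <- lengths(classes)
  if (prod(factorial(sizes)) > 40320) {
    stop_dcnet("taxon signature classes too symmetric for exhaustive canonicalization",
               "dcnet_resource_error")
  }
  # rank slots are assigned class by class, in canonical class order
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  perms_by_class <- lapply(seq_along(classes), function(k) {
    perms(sizes[[k]])
  })
  best <- NULL
  idx <- lapply(perms_by_class, function(p) seq_len(nrow(p)))
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  for (g in seq_len(nrow(grid))) {
    rank <- integer(n)
    names(rank) <- cs$taxa
    for (k in seq_along(classes)) {
      p <- perms_by_class[[k]][grid[[k]][[g]], ]
      rank[classes[[k]]] <- offsets[[k]] + p
    }
    enc <- encode_ranked(cs$clusters, rank)
    if (is.null(best) || enc < best) best <- enc
  }
  best
}

perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

encode_ranked <- function(clusters, rank) {
  enc <- vapply(clusters, function(cl) {
    paste(sprintf("%02d", sort(unname(rank[cl]))), collapse = ",")
  }, character(1))
  paste(sort(enc, method = "radix"), collapse = "|")
}

#' Isomorphism of two networks
#'
#' Two networks are isomorphic when a node bijection preserves directed
#' edges and leaf labels.  Leaf labels anchor the search; internal nodes
#' are matched by backtracking within classes of equal invariants
#' (indegree, outdegree, descendant leaf set).
#'
#' @param n1,n2 `phylo_network` objects.
#' @return logical.
#' @export
networks_isomorphic <- function(n1, n2) {
  i1 <- net_index(n1)
  i2 <- net_index(n2)
  if (i1$n != i2$n || nrow(i1$edges) != nrow(i2$edges)) return(FALSE)
  if (!vset_equal(i1$taxa, i2$taxa)) return(FALSE)
  sig_of <- function(ix) {
    desc <- descendant_leafsets(ix)
    vapply(seq_len(ix$n), function(v) {
      paste(ix$indeg[v], ix$outdeg[v],
            paste(ix$taxa[desc[v, ]], collapse = ","), sep = "#")
    }, character(1))
  }
  s1 <- sig_of(i1)
  s2 <- sig_of(i2)
  if (!identical(sort_keep_dup(s1), sort_keep_dup(s2))) return(FALSE)
  adj1 <- matrix(FALSE, i1$n, i1$n); adj1[i1$edges] <- TRUE
  adj2 <- matrix(FALSE, i2$n, i2$n); adj2[i2$edges] <- TRUE
  # leaves are forced by their labels
  map <- rep(NA_integer_, i1$n)
  for (v in which(!is.na(i1$leaf_label))) {
    w <- which(i2$leaf_label == i1$leaf_label[v])
    map[v] <- w
  }
  internals <- order(vapply(s1, function(s) sum(s1 == s), numeric(1)))
  internals <- internals[is.na(map[internals])]
  consistent <- function(map, v, w) {
    done <- which(!is.na(map))
    for (u in done) {
      if (adj1[v, u] != adj2[w, map[u]]) return(FALSE)
      if (adj1[u, v] != adj2[map[u], w]) return(FALSE)
    }
    TRUE
  }
  solve <- function(map, pos) {
    if (pos > length(internals)) return(TRUE)
    v <- internals[[pos]]
    for (w in which(s2 == s1[v])) {
      if (w %in% map) next
      if (!consistent(map, v, w)) next
      map[v] <- w
      if (solve(map, pos + 1L)) return(TRUE)
      map[v] <- NA_integer_
    }
    FALSE
  }
  # verify forced leaf assignments are consistent before recursing
  leaves <- which(!is.na(i1$leaf_label))
  for (v in leaves) if (!consistent(replace(map, v, NA), v, map[v])) return(FALSE)
  solve(map, 1L)
}
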