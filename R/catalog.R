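# The catalog: canonical simplest cluster sets whose incompatibility graph
# is a single edge (1 set), a three-node path (4 sets) or a triangle
# (12 sets), together with verified network fixtures.  Any cluster set
# whose component collapses to one of these is resolved by relabeling the
# stored network instead of searching again.

catalog_definitions <- function() {
  cl <- function(...) lapply(list(...), as.character)
  list(
    list(id = "pair_01", topology = "PAIR",
         clusters = cl(c(1, 2), c(2, 3))),
    list(id = "path3_01", topology = "PATH3",
         clusters = cl(c(1, 3), c(1, 2), c(1, 3, 4))),
    list(id = "path3_02", topology = "PATH3",
         clusters = cl(c(1, 3), c(1, 2, 4), c(1, 2, 3))),
    list(id = "path3_03", topology = "PATH3",
         clusters = cl(c(1, 2), c(2, 3), c(3, 4))),
    list(id = "path3_04", topology = "PATH3",
         clusters = cl(c(1, 2), c(2, 3, 5), c(3, 4))),
    list(id = "tri_01", topology = "TRIANGLE3",
         clusters = cl(c(1, 3), c(1, 2, 4), c(1, 2, 5))),
    list(id = "tri_02", topology = "TRIANGLE3",
         clusters = cl(c(1, 2), c(1, 3), c(1, 4))),
    list(id = "tri_03", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 4), c(1, 3, 5), c(1, 2, 3))),
    list(id = "tri_04", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 4), c(1, 3, 5), c(1, 2, 3, 6))),
    list(id = "tri_05", topology = "TRIANGLE3",
         clusters = cl(c(1, 2), c(2, 3), c(1, 3))),
    list(id = "tri_06", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 4), c(1, 3), c(2, 3))),
    list(id = "tri_07", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 4), c(1, 3, 5), c(2, 3))),
    list(id = "tri_08", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 4), c(1, 3, 5), c(2, 3, 6))),
    list(id = "tri_09", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4))),
    list(id = "tri_10", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 3, 5), c(1, 2, 4), c(1, 3, 4))),
    list(id = "tri_11", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 3, 5), c(1, 2, 4, 6), c(1, 3, 4))),
    list(id = "tri_12", topology = "TRIANGLE3",
         clusters = cl(c(1, 2, 3, 5), c(1, 2, 4, 6), c(1, 3, 4, 7)))
  )
}

.dcnet_catalog <- new.env(parent = emptyenv())

#' The catalog of canonical simplest cluster sets
#'
#' Returns the 17 catalog entries: the unique two-cluster class, the four
#' path classes and the twelve triangle classes, each with its cluster set,
#' its stored network (read from the package's eNewick fixtures) and its
#' canonical key.
#'
#' @return list of entries; each entry has `id`, `topology`, `clusters`
#'   (a `cluster_set`), `network` (a `phylo_network`) and `key`.
#' @export
catalog_entries <- function() {
  if (!is.null(.dcnet_catalog$entries)) return(.dcnet_catalog$entries)
  defs <- catalog_definitions()
  entries <- lapply(defs, function(d) {
    cs <- cluster_set(d$clusters)
    path <- system.file("extdata", "catalog", paste0(d$id, ".enewick"),
                        package = "dcnet")
    net <- if (nzchar(path)) read_enewick(path) else NULL
    list(id = d$id, topology = d$topology, clusters = cs,
         network = net, key = canonical_key(cs))
  })
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  .dcnet_catalog$entries <- entries
  entries
}

#' Catalog lookup for a simplest cluster set
#'
#' Matches the canonical key of `cs_simplest` against the catalog and, on a
#' hit, returns the entry together with the taxon bijection from the entry
#' universe onto `cs_simplest`'s universe (the lexicographically smallest
#' one when the entry has automorphisms).
#'
#' @param cs_simplest a simplest `cluster_set` (universe = union of
#'   clusters).
#' @return `NULL` when no entry matches (any component with more than three
#'   clusters), else a list with `entry` and `bijection`.
#' @export
catalog_lookup <- function(cs_simplest) {
  stopifnot(inherits(cs_simplest, "cluster_set"))
  if (!(length(cs_simplest$clusters) %in% c(2L, 3L))) return(NULL)
  key <- tryCatch(canonical_key(cs_simplest), error = function(e) NULL)
  if (is.null(key)) return(NULL)
  entries <- catalog_entries()
  hit <- Filter(function(e) identical(e$key, key), entries)
  if (length(hit) == 0L) return(NULL)
  entry <- hit[[1L]]
  bijs <- iso_simplest_all(entry$clusters, cs_simplest)
  if (length(bijs) == 0L) {
    stop_dcnet("canonical keys matched but no bijection found (internal error)",
               "dcnet_internal_error")
  }
  enc <- vapply(bijs, function(b) paste(b[sort_c(names(b))], collapse = ","), character(1))
  list(entry = entry, bijection = bijs[[which.min(rank(enc, ties.method = "first"))]])
}

#' Exhaustively enumerate simplest cluster sets for a component topology
#'
#' Enumerates every set of exactly two (`PAIR`) or three (`PATH3`,
#' `TRIANGLE3`) distinct proper non-empty clusters over taxon universes of
#' size 3 to `max_taxa` in which every taxon occurs in at least one cluster,
#' keeps the sets whose incompatibility graph matches the requested topology
#' and which have no ST-set, and partitions the survivors into cluster-set
#' isomorphism classes.
#'
#' @param topology `"PAIR"`, `"PATH3"` or `"TRIANGLE3"`.
#' @param max_taxa largest universe size (at most 8).
#' @return list of classes; each class has `n` (universe size),
#'   `representative` (a `cluster_set`), and `count` (number of labelled
#'   sets over a fixed universe of that size in the class).
#' @export
enumerate_simplest <- function(topology = c("PAIR", "PATH3", "TRIANGLE3"),
                               max_taxa = NULL) {
  topology <- match.arg(topology)
  if (is.null(max_taxa)) {
    max_taxa <- c(PAIR = 4L, PATH3 = 6L, TRIANGLE3 = 7L)[[topology]]
  }
  if (max_taxa > 8L) {
    stop_dcnet("enumeration is limited to universes of at most 8 taxa",
               "dcnet_resource_error")
  }
  reps <- list()
  for (n in 3L:max_taxa) {
    surv <- enumerate_survivors(topology, n)
    for (s in seq_len(ncol(surv))) {
      cs <- cluster_set(lapply(surv[, s], mask_to_taxa, taxa = as.character(seq_len(n))))
      matched <- FALSE
      for (ri in seq_along(reps)) {
        if (reps[[ri]]$n != n) next
        if (!identical(reps[[ri]]$invariant, set_invariant(cs))) next
        if (!is.null(iso_simplest(reps[[ri]]$representative, cs))) {
          reps[[ri]]$count <- reps[[ri]]$count + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        reps[[length(reps) + 1L]] <- list(
          n = n, representative = cs, count = 1L, invariant = set_invariant(cs)
        )
      }
    }
  }
  reps
}

# cheap isomorphism invariant used to avoid most bijection searches
set_invariant <- function(cs) {
  k <- length(cs$clusters)
  inter <- character(0)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        inter <- c(inter, length(intersect(cs$clusters[[i]], cs$clusters[[j]])))
      }
    }
  }
  paste(length(cs$taxa),
        paste(sort(lengths(cs$clusters)), collapse = "."),
        paste(sort(inter), collapse = "."),
        length(Reduce(intersect, cs$clusters)),
        sep = "|")
}

# Vectorized bitmask enumeration of covering, topology-matching, simplest
# sets over a universe of size n.  Returns a k x N matrix of cluster masks.
enumerate_survivors <- function(topology, n) {
  full <- bitwShiftL(1L, n) - 1L
  masks <- seq_len(full - 1L)
  pc <- popcount16(masks)
  masks <- masks[pc >= 2L]           # trivial clusters give isolated IG nodes
  nm <- length(masks)
  k <- if (topology == "PAIR") 2L else 3L
  empty <- matrix(integer(0), nrow = k, ncol = 0L)
  if (nm < k) return(empty)
  compat <- function(a, b) {
    x <- bitwAnd(a, b)
    x == 0L | x == a | x == b
  }
  if (topology == "PAIR") {
    pr <- utils::combn(nm, 2L)
    a <- masks[pr[1L, ]]; b <- masks[pr[2L, ]]
    keep <- !compat(a, b) & bitwOr(a, b) == full
    trip <- rbind(a[keep], b[keep])
  } else {
    # incompatibility matrix for fast pair lookup
    M <- outer(masks, masks, function(x, y) !compat(x, y))
    tr <- utils::combn(nm, 3L)
    e12 <- M[cbind(tr[1L, ], tr[2L, ])]
    e13 <- M[cbind(tr[1L, ], tr[3L, ])]
    e23 <- M[cbind(tr[2L, ], tr[3L, ])]
    ne <- e12 + e13 + e23
    want <- if (topology == "TRIANGLE3") ne == 3L else ne == 2L
    a <- masks[tr[1L, want]]; b <- masks[tr[2L, want]]; cc <- masks[tr[3L, want]]
    keep <- bitwOr(bitwOr(a, b), cc) == full
    trip <- rbind(a[keep], b[keep], cc[keep])
  }
  if (ncol(trip) == 0L) return(empty)
  # twin prefilter: two taxa lying in exactly the same clusters form an
  # ST-set, so such sets are never simplest
  pat <- matrix(0L, n, ncol(trip))
  for (r in seq_len(k)) {
    for (b in seq_len(n)) {
      pat[b, ] <- pat[b, ] + bitwShiftL((bitwAnd(trip[r, ], bitwShiftL(1L, b - 1L)) > 0L) * 1L,
                                        r - 1L)
    }
  }
  has_twin <- rep(FALSE, ncol(trip))
  if (n >= 2L) {
    for (b1 in seq_len(n - 1L)) {
      for (b2 in seq.int(b1 + 1L, n)) {
        has_twin <- has_twin | (pat[b1, ] == pat[b2, ])
      }
    }
  }
  trip <- trip[, !has_twin, drop = FALSE]
  if (ncol(trip) == 0L) return(empty)
  # full ST-set check on the remainder
  sub <- seq_len(full - 1L)
  spc <- popcount16(sub)
  sub <- sub[spc >= 2L & spc < n]
  simplest <- vapply(seq_len(ncol(trip)), function(s) {
    cms <- trip[, s]
    ok <- rep(TRUE, length(sub))
    for (m in cms) {
      x <- bitwAnd(sub, m)
      ok <- ok & (x == 0L | x == sub | x == m)
    }
    if (!any(ok)) return(TRUE)
    cand <- sub[ok]
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        ri <- bitwAnd(cms[i], cand)
        rj <- bitwAnd(cms[j], cand)
        x <- bitwAnd(ri, rj)
        good <- (x == 0L | x == ri | x == rj)
        cand <- cand[good]
        if (length(cand) == 0L) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  trip[, simplest, drop = FALSE]
}

#' Verify the catalog
#'
#' Re-checks every entry: the cluster set is simplest, its incompatibility
#' graph matches the declared topology, the stored network represents it in
#' the softwired sense and satisfies the decomposition property, its
#' reticulation number is at least 1, and all canonical keys are pairwise
#' distinct.
#'
#' @param entries catalog entries, by default [catalog_entries()].
#' @return a data.frame with one row per entry and logical check columns,
#'   plus an attribute `keys_distinct`.
#' @export
verify_catalog <- function(entries = catalog_entries()) {
  rows <- lapply(entries, function(e) {
    ig <- incompatibility_graph(e$clusters)
    comps <- ig_components(ig)
    topo_ok <- length(comps) == 1L &&
      classify_component(comps[[1L]], ig)$tag == e$topology
    has_net <- !is.null(e$network)
    rep_ok <- has_net && isTRUE(tryCatch(
      represents_all_softwired(e$network, e$clusters)$ok,
      dcnet_error = function(err) FALSE))
    dec_ok <- has_net && isTRUE(tryCatch(
      check_decomposition(e$network, e$clusters),
      dcnet_error = function(err) FALSE))
    data.frame(
      id = e$id,
      simplest = is_simplest(e$clusters),
      topology_ok = topo_ok,
      leaves_ok = has_net && vset_equal(sort_c(e$network$leaves), e$clusters$taxa),
      represents = rep_ok,
      decomposition = dec_ok,
      reticulations = if (has_net) reticulation_number(e$network) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    out <- data.frame(id = character(0), simplest = logical(0),
                      topology_ok = logical(0), leaves_ok = logical(0),
                      represents = logical(0), decomposition = logical(0),
                      reticulations = integer(0), stringsAsFactors = FALSE)
    attr(out, "keys_distinct") <- TRUE
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "keys_distinct") <-
    !anyDuplicated(vapply(entries, `[[`, character(1), "key"))
  out
}
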