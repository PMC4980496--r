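# Seeded fixture generators.  All randomness comes from R's RNG, so
# wrapping calls in set.seed() (or using generate_fixtures(seed = ...))
# makes outputs fully reproducible.

#' Random rooted binary tree
#'
#' Recursive random splits of the (shuffled) label set.
#'
#' @param n_taxa number of leaves (>= 1).
#' @param labels optional labels; default `t1..tn`.
#' @return a `phylo_network` with zero reticulations.
#' @export
random_rooted_tree <- function(n_taxa, labels = paste0("t", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 1L, length(labels) == n_taxa)
  labels <- sample(labels)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  edges <- NULL
  grow <- function(labs) {
    if (length(labs) == 1L) return(paste0("L", labs))
    counter$i <- counter$i + 1L
    me <- sprintf("H%d", counter$i)
    cut <- if (length(labs) == 2L) 1L else sample(length(labs) - 1L, 1L)
    left <- grow(labs[seq_len(cut)])
    right <- grow(labs[-seq_len(cut)])
    edges <<- rbind(edges, c(me, left), c(me, right))
    me
  }
  if (n_taxa == 1L) {
    return(phylo_network(rbind(c("H0", paste0("L", labels))),
                         stats::setNames(labels, paste0("L", labels))))
  }
  grow(labels)
  phylo_network(edges, stats::setNames(labels, paste0("L", labels)))
}

#' Random cluster set with at least one incompatible pair
#'
#' Random proper subsets (sizes 2 to `n_taxa - 1`) are drawn and
#' deduplicated, with rejection until the set contains an incompatible
#' pair.
#'
#' @param n_taxa universe size (>= 3).
#' @param n_clusters number of clusters to draw.
#' @return a `cluster_set`.
#' @export
random_cluster_set <- function(n_taxa, n_clusters) {
  stopifnot(n_taxa >= 3L, n_clusters >= 2L)
  taxa <- paste0("t", seq_len(n_taxa))
  for (try in seq_len(1000L)) {
    cl <- lapply(seq_len(n_clusters), function(i) {
      sz <- sample(2L:(n_taxa - 1L), 1L)
      sample(taxa, sz)
    })
    cl <- cl[!duplicated(clusters_codes(lapply(cl, sort_c)))]
    cs <- cluster_set(cl, taxa = taxa)
    if (!is_compatible_set(cs)) return(cs)
  }
  stop_dcnet("failed to draw an incompatible cluster set", "dcnet_internal_error")
}

#' Expanded-catalog fixture (inverse collapse of a catalog entry)
#'
#' Each taxon of a catalog entry is replaced by a disjoint block of fresh
#' taxa (block sizes drawn from `block_size_range`), i.e. the inverse of
#' the collapse step; feeding the result through [to_simplest()] and
#' [catalog_lookup()] must recover the entry.
#'
#' @param entry_id catalog entry identifier (see [catalog_entries()]).
#' @param block_size_range integer length-2 vector, inclusive block sizes.
#' @return list with `clusters` (a `cluster_set`), `entry_id` (ground
#'   truth) and `blocks` (named list: entry taxon -> block).
#' @export
expanded_catalog_fixture <- function(entry_id, block_size_range = c(1L, 3L)) {
  entry <- catalog_entries()[[entry_id]]
  if (is.null(entry)) stop_dcnet("unknown catalog entry", "dcnet_domain_error")
  cs <- entry$clusters
  blocks <- list()
  for (t in cs$taxa) {
    k <- sample(seq.int(block_size_range[1L], block_size_range[2L]), 1L)
    blocks[[t]] <- paste0("x", t, letters[seq_len(k)])
  }
  expanded <- lapply(cs$clusters, function(cl) unlist(blocks[cl], use.names = FALSE))
  list(clusters = cluster_set(expanded), entry_id = entry_id, blocks = blocks)
}

#' Generate a batch of seeded fixtures
#'
#' @param kind `"random-trees"`, `"expanded-catalog"` or
#'   `"random-clusters"`.
#' @param n_items number of fixtures.
#' @param seed integer seed; identical specifications produce identical
#'   fixtures.
#' @param n_taxa universe/leaf-count bound (trees and random clusters).
#' @param n_clusters cluster count for `"random-clusters"`.
#' @param block_size_range passed to [expanded_catalog_fixture()].
#' @param dir optional directory; when given, fixtures are also written as
#'   `.clusters` / `.newick` files.
#' @return list of fixtures; trees are `phylo_network`s, the other kinds
#'   are lists with a `clusters` element.
#' @export
generate_fixtures <- function(kind = c("random-trees", "expanded-catalog", "random-clusters"),
                              n_items, seed, n_taxa = 8L, n_clusters = 6L,
                              block_size_range = c(1L, 3L), dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  ids <- names(catalog_entries())
  out <- lapply(seq_len(n_items), function(i) {
    switch(kind,
      "random-trees" = random_rooted_tree(sample(seq.int(2L, n_taxa), 1L)),
      "expanded-catalog" = expanded_catalog_fixture(sample(ids, 1L), block_size_range),
      "random-clusters" = list(
        clusters = random_cluster_set(sample(seq.int(4L, n_taxa), 1L),
                                      sample(seq.int(2L, n_clusters), 1L))
      )
    )
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(out)) {
      stem <- file.path(dir, sprintf("%s_%03d", gsub("-", "_", kind), i))
      if (kind == "random-trees") {
        writeLines(write_enewick(out[[i]]), paste0(stem, ".newick"))
      } else {
        write_clusters(out[[i]]$clusters, paste0(stem, ".clusters"))
      }
    }
  }
  out
}
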