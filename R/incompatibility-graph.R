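#' Incompatibility graph of a cluster set
#'
#' Undirected graph with one node per cluster and an edge between every
#' incompatible pair.  Trivial clusters are compatible with everything and
#' must be stripped beforehand (an error is raised otherwise).
#'
#' @param cs a `cluster_set` without trivial clusters.
#' @return an [igraph] graph whose vertex names are the canonical cluster
#'   encodings (comma-separated sorted members).
#' @export
incompatibility_graph <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (any(lengths(cs$clusters) < 2L)) {
    stop_dcnet("strip trivial clusters before building the incompatibility graph",
               "dcnet_precondition_error")
  }
  codes <- clusters_codes(cs$clusters)
  k <- length(codes)
  ends <- character(0)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (!are_compatible(cs$clusters[[i]], cs$clusters[[j]])) {
          ends <- c(ends, codes[i], codes[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, k, name = codes)
  if (length(ends)) g <- igraph::add_edges(g, ends)
  g
}

#' Connected components of an incompatibility graph
#'
#' @param ig graph from [incompatibility_graph()].
#' @return list of character vectors (cluster encodings), one per connected
#'   component, ordered by each component's smallest encoding.
#' @export
ig_components <- function(ig) {
  memb <- igraph::components(ig)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort_c)
  names(comps) <- NULL
  comps[order_c(vapply(comps, function(x) x[[1L]], character(1)))]
}

#' Classify the topology of an incompatibility-graph component
#'
#' Components drive the catalog dispatch: an isolated node (`SINGLETON`),
#' two nodes joined by an edge (`PAIR`), a path on three nodes (`PATH3`),
#' a triangle (`TRIANGLE3`), or anything larger (`OTHER`).
#'
#' @param component character vector of cluster encodings, one connected
#'   component of `ig`.
#' @param ig graph from [incompatibility_graph()].
#' @return list with `tag` (one of `"SINGLETON"`, `"PAIR"`, `"PATH3"`,
#'   `"TRIANGLE3"`, `"OTHER"`) and, for `PATH3`, `middle` (the encoding of
#'   the degree-2 cluster).
#' @export
classify_component <- function(component, ig) {
  sub <- igraph::induced_subgraph(ig, component)
  nn <- igraph::vcount(sub)
  ne <- igraph::ecount(sub)
  tag <- if (nn == 1L) "SINGLETON"
    else if (nn == 2L && ne == 1L) "PAIR"
    else if (nn == 3L && ne == 2L) "PATH3"
    else if (nn == 3L && ne == 3L) "TRIANGLE3"
    else "OTHER"
  out <- list(tag = tag)
  if (tag == "PATH3") {
    deg <- igraph::degree(sub)
    out$middle <- names(deg)[deg == 2L]
  }
  out
}

#' DOT export of an incompatibility graph
#'
#' @param ig graph from [incompatibility_graph()].
#' @param path file to write, or `""` for stdout.
#' @return invisibly, the DOT text.
#' @export
ig_to_dot <- function(ig, path = "") {
  nodes <- sort_c(igraph::V(ig)$name)
  el <- igraph::as_edgelist(ig)
  lines <- c(
    "graph IG {",
    sprintf("  \"%s\";", nodes),
    if (nrow(el)) sprintf("  \"%s\" -- \"%s\";", el[, 1L], el[, 2L]),
    "}"
  )
  txt <- paste(lines, collapse = "\n")
  if (nzchar(path)) writeLines(txt, path) else cat(txt, "\n")
  invisible(txt)
}
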