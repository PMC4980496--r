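# Newick / extended Newick input and output.  Plain rooted trees are read
# with ape; eNewick (the #H hybrid-label dialect) is read through
# ape::read.evonet and converted, while writing uses a deterministic DFS of
# the DAG (a hybrid node's children are written at its first occurrence,
# later occurrences are bare #Hk references).

#' Convert an ape tree or network to a `phylo_network`
#'
#' @param x a `phylo` or `evonet` object.
#' @return a `phylo_network`.  Branch lengths and internal node labels are
#'   dropped.
#' @export
as_phylo_network <- function(x) {
  stopifnot(inherits(x, "phylo"))
  edges <- x$edge
  if (inherits(x, "evonet")) edges <- rbind(edges, x$reticulation)
  ntip <- length(x$tip.label)
  nall <- ntip + x$Nnode
  width <- nchar(as.character(nall))
  ids <- sprintf("n%0*d", width, seq_len(nall))
  em <- cbind(ids[edges[, 1L]], ids[edges[, 2L]])
  # ape may classify an internal node whose children are all hybrid
  # references as a tip; only outdegree-0 tips are leaves
  outdeg <- tabulate(edges[, 1L], nall)
  tip_is_leaf <- outdeg[seq_len(ntip)] == 0L
  leaves <- stats::setNames(x$tip.label[tip_is_leaf], ids[seq_len(ntip)][tip_is_leaf])
  phylo_network(em, leaves)
}

#' Read rooted trees from a Newick file
#'
#' One tree per line; internal node labels and branch lengths are ignored.
#'
#' @param path file path, or use `text`.
#' @param text Newick text (overrides `path`).
#' @return list of `phylo_network` objects with zero reticulations.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  lapply(tr, as_phylo_network)
}

#' Read a network from an eNewick string or file
#'
#' @inheritParams read_newick
#' @return a `phylo_network`.
#' @export
read_enewick <- function(path = NULL, text = NULL) {
  ev <- if (!is.null(text)) ape::read.evonet(text = text) else ape::read.evonet(path)
  as_phylo_network(ev)
}

#' Write a network as eNewick
#'
#' @param net a `phylo_network`.
#' @param path optional file to write to.
#' @return the eNewick string, invisibly when writing to a file.
#' @export
write_enewick <- function(net, path = NULL) {
  ix <- net_index(net)
  desc <- descendant_leafsets(ix)
  # deterministic child order: by descendant leaf-label encoding
  node_key <- vapply(seq_len(ix$n), function(v) {
    paste(ix$taxa[desc[v, ]], collapse = ",")
  }, character(1))
  hybrids <- which(ix$indeg >= 2L)
  hyb_no <- stats::setNames(seq_along(hybrids), hybrids)
  written <- rep(FALSE, ix$n)
  emit <- function(v) {
    h <- as.character(v)
    lab <- if (!is.na(ix$leaf_label[v])) ix$leaf_label[v] else ""
    if (v %in% hybrids) {
      if (written[v]) return(sprintf("#H%d", hyb_no[[h]]))
      written[v] <<- TRUE
      lab <- sprintf("%s#H%d", lab, hyb_no[[h]])
    }
    kids <- ix$edges[ix$out_by[[v]], 2L]
    if (length(kids) == 0L) return(lab)
    kids <- kids[order_c(paste(node_key[kids], kids))]
    sprintf("(%s)%s", paste(vapply(kids, emit, character(1)), collapse = ","), lab)
  }
  txt <- paste0(emit(ix$root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
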