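# Plain-text cluster files: UTF-8, '#'-prefixed comment lines ignored, an
# optional first data line "taxa: a,b,c" declaring the universe, and one
# cluster per non-blank line as comma-separated taxon labels.

#' Read a cluster set from a file
#'
#' @param path file path.
#' @return a `cluster_set`.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  taxa <- NULL
  clusters <- list()
  seen <- character(0)
  first_data <- TRUE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (first_data && grepl("^taxa:", line)) {
      taxa <- trimws(strsplit(sub("^taxa:", "", line), ",", fixed = TRUE)[[1L]])
      first_data <- FALSE
      next
    }
    first_data <- FALSE
    toks <- trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
    if (any(!nzchar(toks))) {
      stop_dcnet(sprintf("%s:%d: empty taxon label in cluster line", path, i),
                 "dcnet_parse_error")
    }
    code <- cluster_code(toks)
    if (code %in% seen) {
      warning(sprintf("%s:%d: duplicate cluster {%s} ignored", path, i, code))
      next
    }
    seen <- c(seen, code)
    clusters <- c(clusters, list(toks))
  }
  cluster_set(clusters, taxa = taxa)
}

#' Write a cluster set to a file
#'
#' @param cs a `cluster_set`.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_clusters <- function(cs, path) {
  stopifnot(inherits(cs, "cluster_set"))
  lines <- c(
    paste0("taxa: ", paste(cs$taxa, collapse = ",")),
    vapply(cs$clusters, function(cl) paste(cl, collapse = ","), character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' DOT export of a network
#'
#' Reticulate nodes are drawn as boxes, tree nodes as points, leaves with
#' their labels.
#'
#' @param net a `phylo_network`.
#' @param path file to write, or `""` for stdout.
#' @return invisibly, the DOT text.
#' @export
network_to_dot <- function(net, path = "") {
  ix <- net_index(net)
  decl <- vapply(seq_len(ix$n), function(v) {
    if (!is.na(ix$leaf_label[v])) {
      sprintf("  \"%s\" [shape=plaintext,label=\"%s\"];", ix$nodes[v], ix$leaf_label[v])
    } else if (ix$indeg[v] >= 2L) {
      sprintf("  \"%s\" [shape=box,label=\"\"];", ix$nodes[v])
    } else {
      sprintf("  \"%s\" [shape=point];", ix$nodes[v])
    }
  }, character(1))
  lines <- c("digraph N {",
             decl,
             sprintf("  \"%s\" -> \"%s\";", net$edges[, 1L], net$edges[, 2L]),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (nzchar(path)) writeLines(txt, path) else cat(txt, "\n")
  invisible(txt)
}
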