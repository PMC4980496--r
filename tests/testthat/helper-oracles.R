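# Naive reference implementations used as independent oracles.  They work
# on plain character vectors / lists and deliberately share no code with
# the package internals.

o_compat <- function(a, b) {
  i <- intersect(a, b)
  length(i) == 0 || setequal(i, a) || setequal(i, b)
}

o_pairwise_compat <- function(clusters) {
  k <- length(clusters)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      if (!o_compat(clusters[[i]], clusters[[j]])) return(FALSE)
    }
  }
  TRUE
}

o_is_st <- function(S, clusters, X) {
  if (length(S) < 2 || setequal(S, X)) return(FALSE)
  if (!all(sapply(clusters, function(cl) o_compat(S, cl)))) return(FALSE)
  restr <- lapply(clusters, function(cl) intersect(cl, S))
  restr <- restr[sapply(restr, length) > 0]
  o_pairwise_compat(restr)
}

# all ST-sets by exhaustive subset enumeration
o_st_sets <- function(clusters, X) {
  out <- list()
  for (k in 2:max(2, length(X) - 1)) {
    if (k > length(X)) break
    for (S in utils::combn(X, k, simplify = FALSE)) {
      if (o_is_st(S, clusters, X)) out <- c(out, list(sort(S)))
    }
  }
  out
}

o_maximal_st_sets <- function(clusters, X) {
  st <- o_st_sets(clusters, X)
  if (length(st) == 0) return(list())
  keep <- sapply(seq_along(st), function(i) {
    !any(sapply(seq_along(st), function(j) {
      j != i && all(st[[i]] %in% st[[j]]) && length(st[[j]]) > length(st[[i]])
    }))
  })
  st[keep]
}

# connected components of the incompatibility relation by brute-force
# closure; returns list of sorted vectors of cluster encodings
o_ig_components <- function(clusters) {
  k <- length(clusters)
  code <- sapply(clusters, function(cl) paste(sort(cl), collapse = ","))
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j && !o_compat(clusters[[i]], clusters[[j]]) && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  unname(lapply(split(code, comp), function(x) sort(x, method = "radix")))
}

# tiny deterministic helpers for building test networks
edgem <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2, byrow = TRUE)
}

# canonical single-reticulation network: root->a, root->b, a->1,
# a->h, b->h, b->3, h->2
net_1retic <- function() {
  phylo_network(
    edgem("r", "a", "r", "b", "a", "L1", "a", "h", "b", "h", "b", "L3", "h", "L2"),
    c(L1 = "1", L2 = "2", L3 = "3")
  )
}

cs_of <- function(...) cluster_set(lapply(list(...), as.character))

# restrict a cluster set to the union of its clusters (dropping clusters
# equal to that union), as the canonicalization operations require
union_wrap <- function(cs) {
  un <- sort(unique(unlist(cs$clusters)), method = "radix")
  cluster_set(cs$clusters[sapply(cs$clusters, length) < length(un)], taxa = un)
}

cl_codes <- function(clusters) {
  if (length(clusters) == 0) return(character(0))
  sort(sapply(clusters, function(cl) paste(sort(cl, method = "radix"), collapse = ",")),
       method = "radix")
}

c0_set <- function() cs_of(c(1, 2), c(2, 3))
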