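test_that("network validation enforces rooted-DAG structure", {
  expect_error(phylo_network(edgem("a", "b", "b", "a")), class = "dcnet_invalid_network")
  expect_error(phylo_network(edgem("a", "b", "c", "b")), class = "dcnet_invalid_network")
  expect_warning(phylo_network(edgem("a", "b", "a", "b", "a", "c")), "parallel")
  expect_error(phylo_network(edgem("r", "x", "r", "y"), c(x = "1", y = "1")),
               class = "dcnet_invalid_network")
})

test_that("reticulation number satisfies both formulas", {
  tr <- read_newick(text = "((1,2),(3,4));")[[1]]
  expect_equal(reticulation_number(tr), 0L)
  n1 <- net_1retic()
  expect_equal(reticulation_number(n1), 1L)
  expect_equal(nrow(n1$edges) - length(n1$nodes) + 1L, 1L)
  # a third parent of h adds one more
  n2 <- phylo_network(rbind(n1$edges, c("r", "c"), c("c", "h"), c("c", "L4")),
                      c(n1$leaves, L4 = "4"))
  expect_equal(reticulation_number(n2), 2L)
})

test_that("switchings multiply across reticulate nodes", {
  tr <- read_newick(text = "((1,2),3);")[[1]]
  expect_length(switchings(tr), 1L)
  expect_length(switchings(net_1retic()), 2L)
  two <- read_enewick(text = "(((1)#H1,(2)#H2),(#H1,#H2,3));")
  expect_length(switchings(two), 4L)
  expect_error(switchings(two, cap = 3), class = "dcnet_resource_error")
})

test_that("softwired representation enumerates switchings; hardwired does not", {
  tr <- read_newick(text = "((1,2),3);")[[1]]
  expect_true(represents_softwired(tr, c("1", "2")))
  n1 <- net_1retic()
  expect_true(represents_softwired(n1, c("1", "2")))
  expect_true(represents_softwired(n1, c("2", "3")))
  expect_false(represents_softwired(n1, c("1", "3")))
  expect_false(represents_hardwired(n1, c("1", "2", "3")))
  expect_true(represents_hardwired(n1, "2"))
  # on trees the two notions coincide for every cluster
  set.seed(79)
  for (i in 1:10) {
    tr <- random_rooted_tree(sample(3:7, 1))
    taxa <- sort(unname(tr$leaves))
    for (j in 1:10) {
      cl <- sample(taxa, sample(seq_len(length(taxa) - 1), 1))
      expect_identical(represents_softwired(tr, cl), represents_hardwired(tr, cl))
    }
  }
})

test_that("whole-set softwired check returns witnesses or the missing cluster", {
  tr <- read_newick(text = "((1,2),3);")[[1]]
  r <- represents_all_softwired(tr, clusters_of_tree(tr))
  expect_true(r$ok)
  expect_named(r$epsilon, "1,2")
  r2 <- represents_all_softwired(net_1retic(), c0_set())
  expect_true(r2$ok)
  expect_length(r2$epsilon, 2L)
  r3 <- represents_all_softwired(tr, cluster_set(list(c("2", "3")),
                                                 taxa = c("1", "2", "3")))
  expect_false(r3$ok)
  expect_identical(r3$missing, c("2", "3"))
})

test_that("the decomposition property holds for trees and the pair network", {
  tr <- read_newick(text = "(((1,2),3),(4,5));")[[1]]
  expect_true(check_decomposition(tr, clusters_of_tree(tr)))
  expect_true(check_decomposition(net_1retic(), c0_set()))
  cs <- cs_of(c(1, 2), c(2, 3), c(4, 5))
  b <- build_network(cs)
  expect_true(check_decomposition(b$network, cs))
})

test_that("maximal subtrees are the tree-rooted nodes not below another", {
  tr <- read_newick(text = "((1,2),3);")[[1]]
  ms <- maximal_subtrees(tr)
  expect_length(ms, 1L)
  expect_identical(ms[[1]]$leaves, c("1", "2", "3"))
  ms1 <- maximal_subtrees(net_1retic())
  expect_identical(sort(sapply(ms1, function(m) paste(m$leaves, collapse = ","))),
                   c("1", "2", "3"))
  # after decollapsing a block, the block subtree is maximal
  b <- build_network(cs_of(c(1, 2), c(1, 2, 3), c(3, 4)))
  got <- sapply(maximal_subtrees(b$network), function(m) paste(m$leaves, collapse = ","))
  expect_true("1,2" %in% got)
})

test_that("reticulation identity holds on randomly built networks", {
  set.seed(83)
  for (i in 1:10) {
    cs <- random_cluster_set(sample(4:7, 1), sample(2:5, 1))
    net <- build_network(cs)$network
    ind <- table(factor(net$edges[, 2], levels = net$nodes))
    expect_equal(sum(pmax(ind - 1L, 0L)), nrow(net$edges) - length(net$nodes) + 1L)
    expect_equal(reticulation_number(net), sum(pmax(ind - 1L, 0L)))
  }
})
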