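test_that("Hasse trees realize compatible cluster sets exactly", {
  h <- hasse_tree(cluster_set(list(c("1", "2"), c("1", "2", "3")), taxa = as.character(1:4)))
  expect_equal(reticulation_number(h), 0L)
  expect_identical(cl_codes(clusters_of_tree(h)$clusters), c("1,2", "1,2,3"))
  star <- hasse_tree(cluster_set(list(), taxa = c("1", "2")))
  expect_identical(sort(unname(star$leaves)), c("1", "2"))
  expect_error(hasse_tree(c0_set()), class = "dcnet_precondition_error")
  set.seed(97)
  for (i in 1:10) {
    tr <- random_rooted_tree(sample(3:9, 1))
    cs <- clusters_of_tree(tr)
    expect_identical(cl_codes(clusters_of_tree(hasse_tree(cs))$clusters),
                     cl_codes(cs$clusters))
  }
})

test_that("transfer relabels an entry network and decollapses blocks", {
  target <- cs_of(c(1, 2, 3), c(3, 4))
  res <- to_simplest(target)
  hit <- catalog_lookup(res$collapsed)
  net <- transfer_network(hit$entry$network, hit$bijection, res, target)
  expect_identical(sort(unname(net$leaves)), c("1", "2", "3", "4"))
  expect_true(represents_all_softwired(net, target)$ok)
  got <- sapply(maximal_subtrees(net), function(m) paste(m$leaves, collapse = ","))
  expect_true("1,2" %in% got)
  # identity bijection, no blocks: network unchanged
  res0 <- to_simplest(c0_set())
  hit0 <- catalog_lookup(res0$collapsed)
  net0 <- transfer_network(hit0$entry$network, hit0$bijection, res0, c0_set())
  expect_true(networks_isomorphic(net0, hit0$entry$network))
})

test_that("fallback search finds a single-reticulation pair network and respects preconditions", {
  net <- fallback_search(c0_set(), max_r = 1)
  expect_equal(reticulation_number(net), 1L)
  expect_true(represents_all_softwired(net, c0_set())$ok)
  compatible <- cluster_set(list(c("1", "2"), c("1", "2", "3")), taxa = as.character(1:4))
  expect_error(fallback_search(compatible), class = "dcnet_precondition_error")
  expect_error(fallback_search(c0_set(), max_r = 0, allow_star = FALSE),
               class = "dcnet_unsupported_component")
})

test_that("fallback agrees with the stored pair/path fixtures on reticulation number", {
  for (id in c("pair_01", "path3_01", "path3_02", "path3_03", "path3_04", "tri_05")) {
    e <- catalog_entries()[[id]]
    r_stored <- reticulation_number(e$network)
    net <- fallback_search(e$clusters, max_r = r_stored, candidate_cap = 20000L,
                           allow_star = FALSE)
    expect_equal(reticulation_number(net), r_stored)
    # and nothing with fewer reticulations exists in the searched space
    if (r_stored > 1) {
      expect_error(fallback_search(e$clusters, max_r = r_stored - 1L,
                                   candidate_cap = 20000L, allow_star = FALSE),
                   class = "dcnet_unsupported_component")
    }
  }
})

test_that("the constructive fallback covers components beyond the search bound", {
  cs <- cs_of(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6))
  net <- fallback_search(cs, max_r = 0)
  expect_true(represents_all_softwired(net, cs)$ok)
  expect_true(isTRUE(check_decomposition(net, cs)))
})

test_that("build_component resolves a component through the catalog and verifies it", {
  net <- build_component(cs_of(c(1, 2), c(2, 3, 5), c(3, 4)))
  expect_true(represents_all_softwired(net, cs_of(c(1, 2), c(2, 3, 5), c(3, 4)))$ok)
  net2 <- build_component(cs_of(c(1, 2, 3), c(3, 4)))
  expect_true(represents_all_softwired(net2, cs_of(c(1, 2, 3), c(3, 4)))$ok)
})

test_that("merge places subnetworks on the compatible backbone and guards its assumption", {
  sub <- build_component(c0_set())
  merged <- merge_subnetworks(list(sub), list(c("4", "5")), as.character(1:5))
  expect_identical(sort(unname(merged$leaves)), as.character(1:5))
  expect_true(represents_softwired(merged, c("4", "5")))
  expect_true(represents_softwired(merged, c("1", "2")))
  # a single lying strictly inside the span violates the assumption
  expect_error(merge_subnetworks(list(sub), list(c("1", "2", "4")), as.character(1:5)),
               class = "dcnet_assumption_violated")
})

test_that("build_network handles trees, cluster sets, and the worked example", {
  set.seed(101)
  tr <- random_rooted_tree(6)
  b <- build_network(list(tr))
  expect_equal(reticulation_number(b$network), 0L)
  expect_true(networks_isomorphic(tr, b$network))

  b0 <- build_network(c0_set())
  expect_equal(reticulation_number(b0$network), 1L)
  expect_true(represents_all_softwired(b0$network, c0_set())$ok)

  bw <- build_network(cs_of(c(1, 2), c(1, 2, 3), c(3, 4)))
  got <- sapply(maximal_subtrees(bw$network), function(m) paste(m$leaves, collapse = ","))
  expect_true("1,2" %in% got)
  expect_error(build_network(list()), class = "dcnet_domain_error")
})

test_that("per-component accounting sums to the network's reticulation number", {
  set.seed(103)
  for (i in 1:10) {
    cs <- random_cluster_set(sample(4:8, 1), sample(2:5, 1))
    b <- build_network(cs)
    rsum <- sum(vapply(b$per_component, function(x) x$reticulations, integer(1)))
    expect_equal(reticulation_number(b$network), rsum)
  }
})

test_that("two trees with conflicting clades yield a reticulate consensus network", {
  trees <- read_newick(text = "((1,2),3);\n(1,(2,3));")
  b <- build_network(trees)
  expect_gte(reticulation_number(b$network), 1L)
  expect_true(represents_softwired(b$network, c("1", "2")))
  expect_true(represents_softwired(b$network, c("2", "3")))
})
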