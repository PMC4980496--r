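test_that("cluster-set isomorphism collapses first and finds the printed bijection", {
  a <- cs_of(c(1, 2, 3), c(3, 4))
  g <- clustersets_isomorphic(a, c0_set())
  expect_false(is.null(g))
  expect_identical(unname(g[c("1+2", "3", "4")]), c("1", "2", "3"))
  # the weak (co-membership) reading is implied by the strong one
  expect_false(is.null(clustersets_isomorphic(a, c0_set(), strong = FALSE)))
})

test_that("renamed copies are isomorphic, structurally different sets are not", {
  set.seed(61)
  for (i in 1:15) {
    cs <- random_cluster_set(sample(4:7, 1), sample(2:5, 1))
    perm <- setNames(sample(LETTERS[1:9][seq_along(cs$taxa)]), cs$taxa)
    cs2 <- cluster_set(lapply(cs$clusters, function(cl) unname(perm[cl])),
                       taxa = unname(perm[cs$taxa]))
    expect_false(is.null(clustersets_isomorphic(cs, cs2)))
  }
  c5 <- cs_of(c(1, 2), c(2, 3), c(1, 3))
  expect_null(clustersets_isomorphic(c0_set(), c5))
})

test_that("isomorphism is an equivalence relation on random triples", {
  set.seed(67)
  pool <- replicate(6, random_cluster_set(sample(4:6, 1), sample(2:4, 1)), simplify = FALSE)
  for (a in pool) expect_false(is.null(clustersets_isomorphic(a, a)))
  for (i in 1:10) {
    ab <- sample(6, 2)
    g1 <- clustersets_isomorphic(pool[[ab[1]]], pool[[ab[2]]])
    g2 <- clustersets_isomorphic(pool[[ab[2]]], pool[[ab[1]]])
    expect_identical(is.null(g1), is.null(g2))
  }
})

test_that("canonical keys agree with isomorphism and are stable", {
  c0 <- c0_set()
  ab <- cluster_set(list(c("a", "b"), c("b", "c")))
  expect_identical(canonical_key(c0), canonical_key(ab))
  c3 <- cs_of(c(1, 2), c(2, 3), c(3, 4))
  c5 <- cs_of(c(1, 2), c(2, 3), c(1, 3))
  expect_false(identical(canonical_key(to_simplest(c3)$collapsed), canonical_key(c5)))
  set.seed(71)
  for (i in 1:20) {
    a <- to_simplest(union_wrap(random_cluster_set(sample(4:7, 1), sample(2:4, 1))))$collapsed
    b <- to_simplest(union_wrap(random_cluster_set(sample(4:7, 1), sample(2:4, 1))))$collapsed
    iso <- !is.null(clustersets_isomorphic(a, b))
    keys_equal <- identical(canonical_key(a), canonical_key(b))
    expect_identical(iso, keys_equal)
  }
})

test_that("canonical keys require simplest sets and the union convention", {
  expect_error(canonical_key(cs_of(c(1, 2), c(1, 2, 3), c(3, 4))),
               class = "dcnet_precondition_error")
  expect_error(canonical_key(cluster_set(list(c("1", "2"), c("2", "3")),
                                         taxa = as.character(1:4))),
               class = "dcnet_domain_error")
})

test_that("expanding taxa into disjoint blocks preserves the isomorphism class", {
  set.seed(73)
  for (id in c("pair_01", "path3_03", "tri_05", "tri_09")) {
    fx <- expanded_catalog_fixture(id, c(1, 3))
    entry <- catalog_entries()[[id]]
    expect_false(is.null(clustersets_isomorphic(fx$clusters, entry$clusters)))
  }
})

test_that("network isomorphism anchors on leaf labels", {
  n1 <- net_1retic()
  renamed <- phylo_network(
    matrix(c("R", "A", "R", "B", "A", "x1", "A", "H", "B", "H", "B", "x3", "H", "x2"),
           ncol = 2, byrow = TRUE),
    c(x1 = "1", x2 = "2", x3 = "3")
  )
  expect_true(networks_isomorphic(n1, renamed))
  t1 <- read_newick(text = "((1,2),3);")[[1]]
  t2 <- read_newick(text = "(1,(2,3));")[[1]]
  expect_false(networks_isomorphic(t1, t2))
  # same cluster set, different reticulation placement
  m1 <- read_enewick(text = "((1,(2)#H1),(#H1,3));")
  m2 <- read_enewick(text = "(((1)#H1,2),(#H1,3));")
  expect_false(networks_isomorphic(m1, m2))
})
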