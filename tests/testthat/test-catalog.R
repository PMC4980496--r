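test_that("the catalog holds the printed pair, path, and triangle sets", {
  entries <- catalog_entries()
  expect_length(entries, 17L)
  topo <- sapply(entries, `[[`, "topology")
  expect_equal(as.integer(table(topo)[c("PAIR", "PATH3", "TRIANGLE3")]), c(1L, 4L, 12L))
  expect_identical(cl_codes(entries$pair_01$clusters$clusters), c("1,2", "2,3"))
  expect_identical(cl_codes(entries$path3_04$clusters$clusters), c("1,2", "2,3,5", "3,4"))
  expect_identical(cl_codes(entries$tri_12$clusters$clusters),
                   c("1,2,3,5", "1,2,4,6", "1,3,4,7"))
})

test_that("every catalog entry passes its own verification", {
  v <- verify_catalog()
  expect_true(all(v$simplest))
  expect_true(all(v$topology_ok))
  expect_true(all(v$leaves_ok))
  expect_true(all(v$represents))
  expect_true(all(v$decomposition))
  expect_true(all(v$reticulations >= 1L))
  expect_true(attr(v, "keys_distinct"))
})

test_that("verification flags a corrupted entry (negative control)", {
  entries <- catalog_entries()
  bad <- entries["pair_01"]
  bad$pair_01$clusters <- cs_of(c(1, 2), c(3, 4))   # compatible: wrong topology
  v <- verify_catalog(bad)
  expect_false(v$topology_ok[1])
  expect_identical(nrow(verify_catalog(list())), 0L)
})

test_that("lookup matches collapsed sets to entries with a bijection", {
  s <- to_simplest(cs_of(c(1, 2), c(1, 2, 3), c(3, 4)))$collapsed
  hit <- catalog_lookup(s)
  expect_identical(hit$entry$id, "pair_01")
  expect_identical(unname(hit$bijection[c("1", "2", "3")]), c("1+2", "3", "4"))
  hit0 <- catalog_lookup(c0_set())
  expect_identical(hit0$entry$id, "pair_01")
  expect_identical(unname(hit0$bijection), c("1", "2", "3"))
  # no 4-cluster topology exists in the catalog
  four <- to_simplest(cs_of(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))$collapsed
  expect_null(catalog_lookup(four))
})

test_that("the pair topology has exactly one simplest class", {
  reps <- enumerate_simplest("PAIR", 4)
  expect_length(reps, 1L)
  expect_false(is.null(clustersets_isomorphic(reps[[1]]$representative, c0_set())))
})

test_that("the fifth linear class is simplest, path-shaped, and outside the catalog", {
  fifth <- list(c("1", "2"), c("1", "3", "4"), c("1", "2", "3", "5"))
  X <- as.character(1:5)
  # brute force, straight from the definitions (oracle code, no package internals)
  expect_length(Filter(function(x) TRUE, o_st_sets(fifth, X)), 0L)
  inc <- sum(!o_compat(fifth[[1]], fifth[[2]]), !o_compat(fifth[[1]], fifth[[3]]),
             !o_compat(fifth[[2]], fifth[[3]]))
  expect_equal(inc, 2L)   # two incompatible pairs: a path on three nodes
  # package view agrees, and no stored path class matches
  cs <- cluster_set(fifth)
  expect_true(is_simplest(cs))
  expect_null(catalog_lookup(cs))
  for (e in Filter(function(e) e$topology == "PATH3", catalog_entries())) {
    expect_null(clustersets_isomorphic(cs, e$clusters))
  }
  # the pipeline still resolves it, through the fallback
  b <- build_network(cs)
  expect_true(represents_all_softwired(b$network, cs)$ok)
  expect_match(b$per_component[[1]]$method, "^fallback")
})

test_that("enumeration agrees with the definition on a spot-checked survivor", {
  # every enumerated representative must itself be simplest with the right topology
  reps <- enumerate_simplest("PATH3", 4)
  for (r in reps) {
    expect_true(is_simplest(r$representative))
    g <- incompatibility_graph(r$representative)
    expect_identical(classify_component(ig_components(g)[[1]], g)$tag, "PATH3")
  }
})
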