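worked_example <- function() cs_of(c(1, 2), c(1, 2, 3), c(3, 4))

test_that("restriction intersects, drops empties, merges duplicates", {
  r <- restrict_clusters(worked_example(), c("1", "2"))
  expect_identical(cl_codes(r$clusters), "1,2")   # {1,2} and {1,2,3} merge; {3,4} vanishes
  expect_identical(r$taxa, c("1", "2"))
  # restriction to the full universe is the identity
  r2 <- restrict_clusters(worked_example(), c("1", "2", "3", "4"))
  expect_identical(cl_codes(r2$clusters), cl_codes(worked_example()$clusters))
  r3 <- restrict_clusters(c0_set(), "3")
  expect_identical(cl_codes(r3$clusters), "3")
  expect_error(restrict_clusters(c0_set(), c("1", "9")), class = "dcnet_domain_error")
})

test_that("ST-sets require size > 1, compatibility with all clusters, compatible restriction", {
  expect_true(is_st_set(c("1", "2"), worked_example()))
  expect_false(is_st_set(c("2", "3"), c0_set()))
  expect_false(is_st_set("1", worked_example()))
  expect_false(is_st_set(c("1", "2", "3"), cluster_set(list(c("1", "2")), taxa = c("1", "2", "3"))))
})

test_that("maximal ST-sets match the worked example and the degenerate cases", {
  expect_identical(maximal_st_sets(worked_example()), list(c("1", "2")))
  expect_identical(maximal_st_sets(c0_set()), list())
  two <- cs_of(c(1, 2), c(3, 4))
  expect_identical(maximal_st_sets(two), list(c("1", "2"), c("3", "4")))
})

test_that("maximal ST-sets agree with exhaustive enumeration on random inputs", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    cs <- random_cluster_set(n, sample(2:5, 1))
    got <- maximal_st_sets(cs)
    want <- o_maximal_st_sets(cs$clusters, cs$taxa)
    expect_identical(
      cl_codes(got),
      cl_codes(want)
    )
  }
})

test_that("one collapse round reproduces the printed Collapse example", {
  r <- collapse_once(worked_example())
  expect_s3_class(r, "collapse_result")
  expect_identical(cl_codes(r$collapsed$clusters), c("1+2,3", "3,4"))
  expect_identical(r$block_map[["1+2"]], c("1", "2"))
  expect_identical(r$dropped, list(c("1", "2")))
  # a set with no ST-set is left unchanged
  r0 <- collapse_once(c0_set())
  expect_identical(cl_codes(r0$collapsed$clusters), cl_codes(c0_set()$clusters))
  expect_true(all(lengths(r0$block_map) == 1L))
})

test_that("to_simplest reaches a fixpoint whose result is simplest, blocks name original taxa", {
  r <- to_simplest(worked_example())
  expect_true(is_simplest(r$collapsed))
  expect_identical(cl_codes(r$collapsed$clusters), c("1+2,3", "3,4"))
  expect_identical(r$block_map[["1+2"]], c("1", "2"))
  # the largest catalog triangle is already simplest
  c12 <- cs_of(c(1, 2, 3, 5), c(1, 2, 4, 6), c(1, 3, 4, 7))
  r12 <- to_simplest(c12)
  expect_identical(cl_codes(r12$collapsed$clusters), cl_codes(c12$clusters))
  # {{1,2,3},{3,4}} collapses the nested cherry
  r2 <- to_simplest(cs_of(c(1, 2, 3), c(3, 4)))
  expect_identical(cl_codes(r2$collapsed$clusters), c("1+2,3", "3,4"))
})

test_that("multi-round collapse composes block maps down to original taxa", {
  # {{1,2}} over {1,2,3} collapses {1,2}, then {(1+2),3}: two rounds
  cs <- cluster_set(list(c("1", "2")), taxa = c("1", "2", "3"))
  r <- to_simplest(cs)
  expect_true(is_simplest(r$collapsed))
  expect_length(r$collapsed$clusters, 0L)
  big <- r$block_map[lengths(r$block_map) > 1L]
  expect_identical(big, list(`1+2` = c("1", "2")))
  expect_identical(r$collapsed$taxa, c("1+2", "3"))
})

test_that("simplest detection matches the definitional cases", {
  expect_true(is_simplest(c0_set()))
  expect_false(is_simplest(worked_example()))
  expect_false(is_simplest(cluster_set(list(c("1", "2")), taxa = c("1", "2", "3"))))
})

test_that("to_simplest is idempotent and sound on random fixtures", {
  set.seed(37)
  for (i in 1:30) {
    cs <- random_cluster_set(sample(4:8, 1), sample(2:6, 1))
    r <- to_simplest(cs)
    expect_true(is_simplest(r$collapsed))
    r2 <- to_simplest(r$collapsed)
    expect_identical(cl_codes(r2$collapsed$clusters), cl_codes(r$collapsed$clusters))
    # blocks partition the universe
    expect_identical(sort(unname(unlist(r$block_map))), cs$taxa)
  }
})

test_that("collapse round-trips: expanding blocks through their subtrees recovers the clusters", {
  set.seed(41)
  for (i in 1:20) {
    cs <- random_cluster_set(sample(4:8, 1), sample(2:5, 1))
    r <- to_simplest(cs)
    blocks <- r$block_map[lengths(r$block_map) > 1L]
    recovered <- lapply(r$collapsed$clusters, function(cl) {
      sort(unname(unlist(r$block_map[cl])), method = "radix")
    })
    # clusters inside blocks come from the block subtrees
    for (b in blocks) {
      sub <- subtree_for_block(b, cs)
      inside <- clusters_of_tree(sub, include_trivial = FALSE)$clusters
      recovered <- c(recovered, inside, list(b))
    }
    nontrivial_orig <- cs$clusters[lengths(cs$clusters) >= 2L]
    expect_true(all(cl_codes(nontrivial_orig) %in% cl_codes(recovered)))
  }
})

test_that("collapsing a two-taxon ST-set first reaches the same fixpoint", {
  set.seed(43)
  expand_codes <- function(res, pmap) {
    sort(sapply(res$collapsed$clusters, function(cl) {
      paste(sort(unlist(lapply(cl, function(t) sort(unlist(pmap[res$block_map[[t]]])))),
                 method = "radix"), collapse = ",")
    }), method = "radix")
  }
  for (i in 1:30) {
    cs <- random_cluster_set(sample(4:8, 1), sample(2:6, 1))
    p <- dcnet:::find_pair_st_set(cs)
    if (is.null(p)) next
    pre <- dcnet:::relabel_by_blocks(cs, list(p))
    idmap <- setNames(as.list(cs$taxa), cs$taxa)
    expect_identical(expand_codes(to_simplest(pre$collapsed), pre$block_map),
                     expand_codes(to_simplest(cs), idmap))
  }
})

test_that("block subtrees have exactly the clusters nested in the block", {
  cs <- worked_example()
  sub <- subtree_for_block(c("1", "2"), cs)
  expect_identical(sort(unname(sub$leaves)), c("1", "2"))
  expect_equal(reticulation_number(sub), 0L)
  cs2 <- cs_of(c(1, 2), c(4, 5))
  sub2 <- subtree_for_block(c("1", "2", "3"), cluster_set(cs2$clusters, taxa = as.character(1:5)))
  expect_identical(cl_codes(clusters_of_tree(sub2)$clusters), "1,2")
  expect_error(subtree_for_block(c("2", "3"), c0_set()), class = "dcnet_precondition_error")
})
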