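two_sample <- function(tree_text, ...) {
  counts <- rbind(...)
  colnames(counts) <- c("s1", "s2")
  storage.mode(counts) <- "integer"
  bind_dataset(parse_newick(tree_text), counts)
}

test_that("branch partition matches brute-force descendant recount", {
  ds <- two_sample("(A:1,B:1);", A = c(1, 0), B = c(0, 1))
  bp <- branch_partition(ds)
  expect_equal(sort(bp$n[, "s1"]), c(0, 1))
  expect_equal(sort(bp$n[, "s2"]), c(0, 1))

  set.seed(31)
  for (i in 1:20) {
    ds <- random_test_dataset(ntip = 30, depth = 50)
    bp <- branch_partition(ds)
    sets <- brute_edge_sets(ds$tree)
    brute_n1 <- vapply(sets, function(e) sum(ds$counts[e$tips, 1]), numeric(1))
    # compare sorted multisets of (length, n1, n2) triples across branches
    pkg_tr <- paste(round(bp$length, 10), bp$n[, 1], bp$n[, 2])
    brute_n2 <- vapply(sets, function(e) sum(ds$counts[e$tips, 2]), numeric(1))
    brute_l <- vapply(sets, `[[`, numeric(1), "len")
    brute_tr <- paste(round(brute_l, 10), brute_n1, brute_n2)
    expect_identical(sort(pkg_tr), sort(brute_tr))
    # root-children sums recover sample totals
    root <- length(ds$tree$tip.label) + 1L
    at_root <- bp$parent == root
    expect_equal(colSums(bp$n[at_root, , drop = FALSE]), bp$totals)
    # monotone toward the root: child branch counts <= parent branch counts
    for (j in seq_along(bp$child)) {
      up <- which(bp$child == bp$parent[j])
      if (length(up)) expect_true(all(bp$n[j, ] <= bp$n[up, ]))
    }
  }
})

test_that("unweighted UniFrac hand cases", {
  disjoint <- two_sample("((A:1,B:1):1,(C:1,D:1):1);",
                         A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1))
  expect_equal(unweighted_unifrac(disjoint, "s1", "s2"), 1)

  same <- two_sample("((A:1,B:1):1,C:2);",
                     A = c(2, 7), B = c(1, 3), C = c(5, 2))
  expect_equal(unweighted_unifrac(same, "s1", "s2"), 0)

  # partial sharing, verified against the brute-force oracle
  mix <- two_sample("((A:1,B:1):1,(C:1,D:1):1);",
                    A = c(1, 1), B = c(1, 0), C = c(0, 1), D = c(0, 0))
  expect_equal(unweighted_unifrac(mix, "s1", "s2"),
               brute_unifrac(mix, "s1", "s2", "unweighted"))

  zero_total <- two_sample("(A:1,B:1);", A = c(0, 1), B = c(0, 1))
  expect_error(unweighted_unifrac(zero_total, "s1", "s2"), "zero total")
})

test_that("weighted UniFrac hand cases and normalization", {
  ds <- two_sample("(A:1,B:1);", A = c(2, 0), B = c(0, 3))
  expect_equal(weighted_unifrac(ds, "s1", "s2"), 2)
  expect_equal(weighted_unifrac(ds, "s1", "s2", normalized = TRUE), 1)

  same <- two_sample("((A:1,B:1):1,C:2);",
                     A = c(2, 2), B = c(1, 1), C = c(3, 3))
  expect_equal(weighted_unifrac(same, "s1", "s2"), 0)
  expect_equal(weighted_unifrac(same, "s1", "s2", normalized = TRUE), 0)
})

test_that("both metrics equal the brute-force oracle on small trees", {
  set.seed(32)
  for (i in 1:60) {
    ds <- random_test_dataset(ntip = sample(2:10, 1), depth = sample(5:25, 1))
    for (m in c("unweighted", "weighted_raw", "weighted_normalized")) {
      got <- switch(m,
                    unweighted = unweighted_unifrac(ds, "s1", "s2"),
                    weighted_raw = weighted_unifrac(ds, "s1", "s2"),
                    weighted_normalized = weighted_unifrac(ds, "s1", "s2",
                                                           normalized = TRUE))
      expect_equal(got, brute_unifrac(ds, "s1", "s2", m), tolerance = 1e-12)
    }
  }
})

test_that("unweighted is presence/absence; raw weighted scales with lengths", {
  set.seed(33)
  for (i in 1:25) {
    ds <- random_test_dataset(ntip = 8, depth = 30)
    u <- unweighted_unifrac(ds, "s1", "s2")
    # replacing positive counts by 1 changes nothing
    pa <- ds; pa$counts[pa$counts > 0L] <- 1L
    expect_equal(unweighted_unifrac(pa, "s1", "s2"), u, tolerance = 1e-12)
    # scaling one sample's counts by an integer changes nothing
    sc <- ds; sc$counts[, 1] <- sc$counts[, 1] * 5L
    expect_equal(unweighted_unifrac(sc, "s1", "s2"), u, tolerance = 1e-12)
    # tripling branch lengths triples W, leaves U unchanged
    w <- weighted_unifrac(ds, "s1", "s2")
    tr3 <- ds; tr3$tree$edge.length <- tr3$tree$edge.length * 3
    expect_equal(weighted_unifrac(tr3, "s1", "s2"), 3 * w, tolerance = 1e-12)
    expect_equal(unweighted_unifrac(tr3, "s1", "s2"), u, tolerance = 1e-12)
  }
})

test_that("pairwise matrix is symmetric, zero-diagonal, consistent, metric", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  counts <- matrix(c(2L,1L,0L,0L, 0L,0L,3L,1L, 1L,1L,1L,1L), 4, 3,
                   dimnames = list(c("A","B","C","D"), c("x","y","z")))
  ds <- bind_dataset(tr, counts)
  m <- pairwise_matrix(ds, "unweighted")
  expect_identical(m, t(m))
  expect_equal(diag(m), c(x = 0, y = 0, z = 0))
  expect_equal(m["x", "y"], unweighted_unifrac(ds, "x", "y"))

  ident <- bind_dataset(tr, matrix(rep(c(1L,2L,0L,1L), 3), 4, 3,
                        dimnames = list(c("A","B","C","D"), c("x","y","z"))))
  expect_true(all(pairwise_matrix(ident, "weighted_raw") == 0))

  # triangle inequality for unweighted UniFrac on random 3-sample data
  set.seed(34)
  for (i in 1:60) {
    tr <- random_test_tree(sample(3:9, 1))
    nt <- length(tr$tip.label)
    p <- rep(1 / nt, nt)
    cn <- sapply(1:3, function(k) stats::rmultinom(1, 12, p)[, 1])
    dimnames(cn) <- list(tr$tip.label, c("x", "y", "z"))
    m <- pairwise_matrix(bind_dataset(tr, cn), "unweighted")
    expect_lte(m["x", "z"], m["x", "y"] + m["y", "z"] + 1e-12)
    expect_lte(m["x", "y"], m["x", "z"] + m["z", "y"] + 1e-12)
    expect_lte(m["y", "z"], m["y", "x"] + m["x", "z"] + 1e-12)
  }
})
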