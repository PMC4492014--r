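two_sample <- function(tree_text, ...) {
  counts <- rbind(...)
  colnames(counts) <- c("s1", "s2")
  storage.mode(counts) <- "integer"
  bind_dataset(parse_newick(tree_text), counts)
}

test_that("permutation schemes preserve their invariants", {
  set.seed(41)
  ds <- random_test_dataset(ntip = 8, depth = 25)
  key <- function(m) sort(unname(apply(m, 1, paste, collapse = ",")))

  for (i in 1:50) {
    po <- permute_dataset(ds, "otu", seed = i)
    # count-vector multiset preserved, topology untouched
    expect_identical(key(po$counts), key(collapse_replicates(ds)$counts))
    expect_identical(bipartitions(po$tree),
                     bipartitions(collapse_replicates(ds)$tree))
    expect_identical(colSums(po$counts), colSums(ds$counts))

    ps <- permute_dataset(ds, "sequence", seed = i)
    expect_identical(colSums(ps$counts), colSums(ds$counts))
    expect_identical(key(ps$counts), key(expand_replicates(ds)$counts))

    pw <- permute_dataset(ds, "within_tip", seed = i)
    expect_identical(rowSums(pw$counts), rowSums(ds$counts))  # per-tip totals
    expect_identical(sum(pw$counts), sum(ds$counts))
  }
  # determinism
  expect_identical(permute_dataset(ds, "otu", seed = 7)$counts,
                   permute_dataset(ds, "otu", seed = 7)$counts)
})

test_that("monte_carlo_test p-value follows (k+1)/(N+1) and handles edges", {
  # observed = 0 for identical samples: p must be 1 under any scheme
  same <- two_sample("((A:1,B:1):1,C:2);", A = c(2, 2), B = c(1, 1), C = c(3, 3))
  for (sch in c("otu", "sequence", "within_tip")) {
    r <- monte_carlo_test(same, "s1", "s2", metric = "weighted_raw",
                          scheme = sch, n_permutations = 49, seed = 1)
    expect_equal(r$p_value, 1)
  }

  # maximally separated samples on a long-branch split: observed above all
  # nulls is the typical draw; p = (k+1)/(N+1) with k counted conservatively
  sep <- two_sample("((A:9,B:9):9,(C:9,D:9):9);",
                    A = c(5, 0), B = c(5, 0), C = c(0, 5), D = c(0, 5))
  r <- monte_carlo_test(sep, "s1", "s2", metric = "unweighted",
                        scheme = "otu", n_permutations = 99, seed = 2)
  k <- sum(r$null_values >= r$observed)
  expect_equal(r$p_value, (k + 1) / 100)
  expect_equal(r$p_naive, k / 99)
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)

  expect_error(monte_carlo_test(sep, "s1", "s2", n_permutations = 0),
               "n_permutations")
})

test_that("identical (dataset, scheme, seed, n) gives identical results", {
  set.seed(42)
  ds <- random_test_dataset(ntip = 7, depth = 20)
  for (sch in c("otu", "sequence", "within_tip")) {
    a <- monte_carlo_test(ds, "s1", "s2", metric = "weighted_raw",
                          scheme = sch, n_permutations = 59, seed = 11)
    b <- monte_carlo_test(ds, "s1", "s2", metric = "weighted_raw",
                          scheme = sch, n_permutations = 59, seed = 11)
    expect_identical(a$null_values, b$null_values)
    expect_identical(a$p_value, b$p_value)
    c_ <- monte_carlo_test(ds, "s1", "s2", metric = "weighted_raw",
                           scheme = sch, n_permutations = 59, seed = 12)
    expect_false(identical(a$null_values, c_$null_values))
  }
})

test_that("exact_test enumerates the full reference distribution", {
  # two permutable units -> two outcomes
  ds2 <- two_sample("(A:1,B:2);", A = c(1, 0), B = c(0, 1))
  ex <- exact_test(ds2, "s1", "s2", metric = "weighted_raw", scheme = "otu")
  expect_length(ex$null_values, 2L)
  expect_true(ex$exact)

  # enumeration refuses oversized problems
  set.seed(43)
  big <- random_test_dataset(ntip = 14, depth = 200)
  expect_error(exact_test(big, "s1", "s2", scheme = "sequence",
                          max_arrangements = 100), "infeasible")
})

test_that("Monte Carlo p converges to the exact p", {
  ds <- fixture_dataset("replicated_fixture")
  for (sch in c("otu", "sequence", "within_tip")) {
    ex <- exact_test(ds, "s1", "s2", metric = "weighted_raw", scheme = sch)
    mc <- monte_carlo_test(ds, "s1", "s2", metric = "weighted_raw",
                           scheme = sch, n_permutations = 10000, seed = 5)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 10000)
    expect_lt(abs(mc$p_naive - ex$p_value), 3 * se + 1e-9)
  }
})

test_that("sequence- and OTU-level nulls differ on replicated data only", {
  rep_ds <- fixture_dataset("replicated_fixture")
  obs_seq <- exact_test(rep_ds, "s1", "s2", metric = "weighted_raw",
                        scheme = "sequence")
  obs_otu <- exact_test(rep_ds, "s1", "s2", metric = "weighted_raw",
                        scheme = "otu")
  # identical observed statistic, different null distribution
  expect_equal(obs_seq$observed, obs_otu$observed, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sort(unique(round(obs_seq$null_values, 10))),
                                sort(unique(round(obs_otu$null_values, 10))))))

  # with no replication the two schemes have identical nulls and p-values
  single <- fixture_dataset("singleton_fixture")
  s_seq <- exact_test(single, "s1", "s2", metric = "weighted_raw",
                      scheme = "sequence")
  s_otu <- exact_test(single, "s1", "s2", metric = "weighted_raw",
                      scheme = "otu")
  expect_identical(sort(s_seq$null_values), sort(s_otu$null_values))
  expect_identical(s_seq$p_value, s_otu$p_value)
})

test_that("within_tip exact null enumerates all 2^n swap patterns", {
  ds <- two_sample("(A:1,B:2);", A = c(2, 1), B = c(1, 3))
  ex <- exact_test(ds, "s1", "s2", metric = "weighted_raw",
                   scheme = "within_tip")
  expect_length(ex$null_values, 4L)
  # complementary swap patterns exchange the samples, so values pair up
  s <- sort(ex$null_values)
  expect_equal(s[c(1, 3)], s[c(2, 4)], tolerance = 1e-12)
})
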