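# Independent brute-force oracles. These deliberately avoid the package's
# traversal machinery: descendant tip sets are enumerated recursively from
# the raw edge matrix, and parsimony minima come from exhaustive enumeration
# of ancestral labelings.

# list of descendant tip-label sets, one per edge, plus edge lengths
brute_edge_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    rows <- which(tree$edge[, 1] == node)
    unlist(lapply(tree$edge[rows, 2], desc))
  }
  lapply(seq_len(nrow(tree$edge)), function(i)
    list(tips = desc(tree$edge[i, 2]), len = tree$edge.length[i]))
}

brute_unifrac <- function(ds, a, b, metric = "unweighted") {
  counts <- ds$counts
  Na <- sum(counts[, a]); Nb <- sum(counts[, b])
  edges <- brute_edge_sets(ds$tree)
  na <- vapply(edges, function(e) sum(counts[e$tips, a]), numeric(1))
  nb <- vapply(edges, function(e) sum(counts[e$tips, b]), numeric(1))
  l <- vapply(edges, `[[`, numeric(1), "len")
  if (metric == "unweighted") {
    denom <- sum(l[na > 0 | nb > 0])
    if (denom == 0) return(0)
    return(sum(l[xor(na > 0, nb > 0)]) / denom)
  }
  W <- sum(l * abs(na / Na - nb / Nb))
  if (metric == "weighted_raw") return(W)
  # root-to-tip depths by path walking
  ntip <- length(ds$tree$tip.label)
  depth_of <- function(node) {
    d <- 0
    repeat {
      row <- which(ds$tree$edge[, 2] == node)
      if (length(row) == 0L) return(d)
      d <- d + ds$tree$edge.length[row]
      node <- ds$tree$edge[row, 1]
    }
  }
  dj <- vapply(seq_len(ntip), depth_of, numeric(1))
  D <- sum(dj * (counts[ds$tree$tip.label, a] / Na +
                 counts[ds$tree$tip.label, b] / Nb))
  W / D
}

# minimum label changes by exhaustive assignment of states to internal nodes
brute_fitch <- function(tree, tip_labels) {
  ntip <- length(tree$tip.label)
  if (!is.null(names(tip_labels))) tip_labels <- tip_labels[tree$tip.label]
  states <- sort(unique(tip_labels))
  nint <- tree$Nnode
  if (nint == 0L || length(states) == 1L) return(0L)
  grid <- expand.grid(rep(list(states), nint), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(tip_labels, unlist(grid[g, ], use.names = FALSE))
    cost <- sum(assign_[tree$edge[, 1]] != assign_[tree$edge[, 2]])
    best <- min(best, cost)
  }
  as.integer(best)
}

# multiset of tip-set bipartitions, for topology isomorphism checks
bipartitions <- function(tree) {
  sets <- brute_edge_sets(tree)
  sort(vapply(sets, function(e) paste(sort(e$tips), collapse = "|"),
              character(1)))
}

random_test_tree <- function(ntip, rate = 1) {
  tr <- random_topology(sprintf("t%02d", seq_len(ntip)))
  tr$edge.length <- stats::rexp(length(tr$edge.length), rate)
  tr
}

random_test_dataset <- function(ntip = 8, depth = 20, rate = 1) {
  tr <- random_test_tree(ntip, rate)
  p <- stats::rgamma(ntip, 1); p <- p / sum(p)
  counts <- cbind(s1 = stats::rmultinom(1, depth, p)[, 1],
                  s2 = stats::rmultinom(1, depth, p)[, 1])
  rownames(counts) <- tr$tip.label
  bind_dataset(tr, counts)
}

fixture_path <- function(f) system.file("extdata", f, package = "unifracnull")

fixture_dataset <- function(stem) {
  tr <- parse_newick(paste(readLines(fixture_path(paste0(stem, ".nwk"))),
                           collapse = ""))
  bind_dataset(tr, read_abundance_table(fixture_path(paste0(stem, ".tsv"))))
}
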