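#' Minimum number of sample-label changes on a tree (Fitch parsimony)
#'
#' Scores how well the sample labels cluster on the tree: the minimum number
#' of state changes needed to explain the tip labels under small parsimony.
#' Branch lengths are ignored.  Multifurcations use the generalized
#' (Hartigan) rule: at an internal node with \eqn{k} children, each state is
#' scored by how many children's state sets contain it; the node's set is the
#' states attaining the maximum count \eqn{m}, and the change count increases
#' by \eqn{k - m}.  For bifurcations this reduces to the familiar
#' intersection/union rule.
#'
#' @param tree A `phylo` object.
#' @param tip_labels Character vector of sample labels, either named by tip
#'   label or in `tree$tip.label` order.
#' @return Non-negative integer: the parsimony change count.
#' @examples
#' tr <- parse_newick("((A1,A2),(B1,B2));")
#' fitch_changes(tr, c(A1 = "a", A2 = "a", B1 = "b", B2 = "b"))  # 1
#' @export
fitch_changes <- function(tree, tip_labels) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (!is.null(names(tip_labels))) {
    miss <- setdiff(tree$tip.label, names(tip_labels))
    if (length(miss))
      stop("unlabeled tip(s): ", paste(miss, collapse = ", "), call. = FALSE)
    tip_labels <- tip_labels[tree$tip.label]
  }
  if (length(tip_labels) != ntip || anyNA(tip_labels))
    stop("need exactly one label per tip", call. = FALSE)
  states <- sort(unique(tip_labels))
  ns <- length(states)
  if (ntip == 1L || ns == 1L) return(0L)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  sets <- matrix(FALSE, nnode, ns)
  sets[cbind(seq_len(ntip), match(tip_labels, states))] <- TRUE
  changes <- 0L
  kids <- split(po$edge[, 2], po$edge[, 1])
  # a node is processed at the last of its child edges in postorder, by which
  # point every internal child has itself been processed
  done <- logical(nnode)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]
    if (done[p]) next
    ch <- kids[[as.character(p)]]
    if (any(!done[ch] & ch > ntip)) next  # not all children resolved yet
    cnt <- colSums(sets[ch, , drop = FALSE])
    m <- max(cnt)
    sets[p, ] <- cnt == m
    changes <- changes + length(ch) - m
    done[p] <- TRUE
  }
  as.integer(changes)
}

#' Random rooted bifurcating topology over given tips
#'
#' Uniform sequential pair joining: starting from the tips as lineages, each
#' step joins a uniformly chosen pair of available lineages under a new
#' parent, until a single (root) lineage remains.  All branch lengths are 1
#' (parsimony ignores them).  Used to build the P test null: sample labels
#' stay attached to their tips while the topology is randomized.
#'
#' @param tip_labels Character vector of tip names (length >= 2).
#' @param seed Optional integer seed.
#' @return A `phylo` object with `length(tip_labels)` tips and
#'   `length(tip_labels) - 1` internal nodes.
#' @export
random_topology <- function(tip_labels, seed = NULL) {
  n <- length(tip_labels)
  if (n < 2L) stop("need >= 2 tips", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  avail <- seq_len(n)                     # node ids of live lineages
  nxt <- 2L * n - 1L                      # internal ids n+2 .. 2n-1; root n+1
  parent_v <- integer(0); child_v <- integer(0)
  while (length(avail) > 2L) {
    pick <- sample.int(length(avail), 2L)
    parent_v <- c(parent_v, nxt, nxt)
    child_v <- c(child_v, avail[pick])
    avail <- c(avail[-pick], nxt)
    nxt <- nxt - 1L
  }
  parent_v <- c(parent_v, n + 1L, n + 1L)  # root joins the last two
  child_v <- c(child_v, avail)
  structure(list(edge = cbind(parent_v, child_v),
                 edge.length = rep(1, length(child_v)),
                 Nnode = n - 1L,
                 tip.label = tip_labels),
            class = "phylo")
}

#' P test: parsimony significance test with topology randomization
#'
#' The complement of the tip-label randomization tests: sample labels stay
#' constant and the tree topology itself is randomized.  The statistic is the
#' Fitch parsimony count of sample-label changes ([fitch_changes()]); few
#' changes mean the samples occupy distinct clades.  Counted tips are
#' expanded first ([expand_replicates()]) so each sequence occurrence is one
#' labeled tip and abundance enters through tip multiplicity; all-zero tips
#' are pruned.  The null is built from `n_randomizations` random topologies
#' over the same labeled tips ([random_topology()]); because small change
#' counts indicate clustering, the lower tail is significant:
#' \eqn{p = (1 + \#\{null \le observed\}) / (1 + n)}.
#'
#' @param ds A `unifrac_dataset` with two or more samples.
#' @param n_randomizations Number of random topologies (default 999).
#' @param seed Integer seed.
#' @return An object of class `ptest_result`: `observed_changes`,
#'   `null_changes`, `p_value`, `n_randomizations`, `seed`.
#' @export
p_test <- function(ds, n_randomizations = 999, seed = 1) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  if (ncol(ds$counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (n_randomizations < 1) stop("n_randomizations must be >= 1", call. = FALSE)
  exp_ds <- prune_empty_tips(expand_replicates(ds))
  counts <- exp_ds$counts
  lab <- colnames(counts)[apply(counts > 0, 1L, which)]
  names(lab) <- rownames(counts)
  observed <- fitch_changes(exp_ds$tree, lab)
  null_changes <- integer(n_randomizations)
  tips <- rownames(counts)
  for (i in seq_len(n_randomizations)) {
    rt <- random_topology(tips, seed = .iter_seed(seed, i))
    null_changes[i] <- fitch_changes(rt, lab)
  }
  p <- (1 + sum(null_changes <= observed)) / (1 + n_randomizations)
  structure(list(observed_changes = observed, null_changes = null_changes,
                 p_value = p, n_randomizations = n_randomizations,
                 seed = seed),
            class = "ptest_result")
}

#' @export
print.ptest_result <- function(x, ...) {
  cat("P test (parsimony, topology randomization)\n")
  cat("  observed changes:", x$observed_changes, "\n")
  cat("  null changes: n =", x$n_randomizations,
      " median", stats::median(x$null_changes), "\n")
  cat("  p-value:", format(x$p_value), "\n")
  invisible(x)
}
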