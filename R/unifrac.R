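# Cached traversal structure: postorder edge list, lengths, and root-to-tip
# depths. Everything the metrics need besides the count matrix, computed once
# per tree so that permutation tests only touch counts.
.uf_cache <- function(tree) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    return(list(ntip = 1L, nnode = 2L, parent = tree$edge[, 1],
                child = tree$edge[, 2], elen = tree$edge.length,
                tip_depth = tree$edge.length[1]))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  parent <- po$edge[, 1]; child <- po$edge[, 2]; elen <- po$edge.length
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)
  for (i in rev(seq_along(parent)))  # preorder sweep for depths
    depth[child[i]] <- depth[parent[i]] + elen[i]
  # descendant-tip indicator per node; lets permutation loops get all branch
  # totals with one matrix product instead of a traversal
  A <- matrix(0, nnode, ntip)
  A[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  for (i in seq_along(parent))
    A[parent[i], ] <- A[parent[i], ] + A[child[i], ]
  list(ntip = ntip, nnode = nnode, parent = parent, child = child,
       elen = elen, tip_depth = depth[seq_len(ntip)],
       Aedge = A[child, , drop = FALSE])
}

.tip_depths <- function(tree) .uf_cache(tree)$tip_depth

# Per-branch descendant totals: rows follow the cached postorder edge list,
# one column per column of `counts`.
.branch_counts <- function(cache, counts) {
  if (is.null(cache$Aedge)) {  # single-tip tree
    return(matrix(as.numeric(counts), 1L, ncol(counts)))
  }
  cache$Aedge %*% counts
}

#' Per-branch descendant count totals
#'
#' For every non-root branch \eqn{b}, counts the descendants of \eqn{b}
#' belonging to each sample — the quantities both UniFrac metrics sum over.
#' One post-order traversal, linear in nodes times samples.
#'
#' @param ds A `unifrac_dataset`.
#' @return An object of class `branch_partition`: a list with `length`
#'   (branch lengths), `n` (branches-by-samples matrix of descendant totals),
#'   `child`/`parent` (node indices of each branch, \pkg{ape} numbering),
#'   `tip_depth` (root-to-tip path lengths) and `totals` (per-sample totals).
#' @export
branch_partition <- function(ds) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  cache <- .uf_cache(ds$tree)
  n <- .branch_counts(cache, ds$counts)
  colnames(n) <- colnames(ds$counts)
  structure(list(length = cache$elen, n = n,
                 child = cache$child, parent = cache$parent,
                 tip_depth = cache$tip_depth,
                 totals = colSums(ds$counts)),
            class = "branch_partition")
}

# Scalar metric on a two-column branch-count view. `metric` is one of
# "unweighted", "weighted_raw", "weighted_normalized".
# `tipc` (tips x 2 counts) is needed only for the normalization denominator.
.uf_metric <- function(metric, elen, n2, Na, Nb, tip_depth = NULL, tipc = NULL) {
  if (metric == "unweighted") {
    pa <- n2[, 1] > 0; pb <- n2[, 2] > 0
    denom <- sum(elen[pa | pb])
    if (denom == 0) {
      warning("all occupied branches have zero length; unweighted UniFrac defined as 0")
      return(0)
    }
    return(sum(elen[xor(pa, pb)]) / denom)
  }
  # a null draw (within_tip swaps) can empty a sample; treat an empty
  # sample's relative abundances as all-zero rather than 0/0
  fa <- if (Na > 0) n2[, 1] / Na else numeric(nrow(n2))
  fb <- if (Nb > 0) n2[, 2] / Nb else numeric(nrow(n2))
  W <- sum(elen * abs(fa - fb))
  if (metric == "weighted_raw") return(W)
  D <- sum(tip_depth * ((if (Na > 0) tipc[, 1] / Na else 0) +
                        (if (Nb > 0) tipc[, 2] / Nb else 0)))
  if (D == 0)
    stop("normalization denominator is zero (all root-to-tip lengths zero)",
         call. = FALSE)
  W / D
}

.check_metric <- function(metric) {
  match.arg(metric, c("unweighted", "weighted_raw", "weighted_normalized"))
}

.pair_setup <- function(ds, a, b) {
  ia <- .sample_index(ds, a); ib <- .sample_index(ds, b)
  Na <- sum(ds$counts[, ia]); Nb <- sum(ds$counts[, ib])
  if (Na == 0) stop("sample '", colnames(ds$counts)[ia],
                    "' has zero total count", call. = FALSE)
  if (Nb == 0) stop("sample '", colnames(ds$counts)[ib],
                    "' has zero total count", call. = FALSE)
  list(ia = ia, ib = ib, Na = Na, Nb = Nb)
}

#' Unweighted UniFrac distance between two samples
#'
#' The fraction of branch length unique to either sample, among branch length
#' leading to tips present in at least one of them:
#' \deqn{U = \frac{\sum_b \ell_b\, [\,n_b(a) > 0 \;\mathrm{xor}\; n_b(b) > 0\,]}
#'               {\sum_b \ell_b\, [\,n_b(a) > 0 \;\mathrm{or}\; n_b(b) > 0\,]}}
#' where \eqn{n_b(s)} is the number of sample-\eqn{s} sequences descending
#' from branch \eqn{b}.  A presence/absence metric: multiplying any sample's
#' counts by a positive integer leaves it unchanged, as does converting
#' between the expanded and collapsed tree encodings.
#'
#' @param ds A `unifrac_dataset`.
#' @param a,b Sample IDs (or column indices).
#' @return A number in \[0, 1\].
#' @examples
#' ds <- bind_dataset(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"),
#'   matrix(c(1L,1L,0L,0L, 0L,0L,1L,1L), 4, 2,
#'          dimnames = list(c("A","B","C","D"), c("s1","s2"))))
#' unweighted_unifrac(ds, "s1", "s2")  # 1: no branch shared
#' @export
unweighted_unifrac <- function(ds, a, b) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  p <- .pair_setup(ds, a, b)
  cache <- .uf_cache(ds$tree)
  n2 <- .branch_counts(cache, ds$counts[, c(p$ia, p$ib), drop = FALSE])
  .uf_metric("unweighted", cache$elen, n2, p$Na, p$Nb)
}

#' Weighted UniFrac distance between two samples
#'
#' The raw statistic weights each branch by the difference in relative
#' abundance of its descendants:
#' \deqn{W = \sum_b \ell_b \left| \frac{n_b(a)}{N_a} - \frac{n_b(b)}{N_b} \right|.}
#' With `normalized = TRUE`, \eqn{W} is divided by
#' \eqn{D = \sum_j d_j (c_j(a)/N_a + c_j(b)/N_b)} — the abundance-weighted
#' average root-to-tip distance \eqn{d_j} — which scales the result to
#' \[0, 1\].  Both variants are invariant to the expanded/collapsed tree
#' encoding because the branches that expansion adds have length zero.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Divide by the maximum attainable value for these
#'   abundances (default `FALSE`; the raw statistic is the historical default
#'   for significance testing).
#' @return A non-negative number (in \[0, 1\] when normalized).
#' @examples
#' ds <- bind_dataset(parse_newick("(A:1,B:1);"),
#'   matrix(c(2L,0L, 0L,3L), 2, 2, dimnames = list(c("A","B"), c("s1","s2"))))
#' weighted_unifrac(ds, "s1", "s2")                     # 2
#' weighted_unifrac(ds, "s1", "s2", normalized = TRUE)  # 1
#' @export
weighted_unifrac <- function(ds, a, b, normalized = FALSE) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  p <- .pair_setup(ds, a, b)
  cache <- .uf_cache(ds$tree)
  tipc <- ds$counts[, c(p$ia, p$ib), drop = FALSE]
  n2 <- .branch_counts(cache, tipc)
  .uf_metric(if (normalized) "weighted_normalized" else "weighted_raw",
             cache$elen, n2, p$Na, p$Nb, cache$tip_depth, tipc)
}

#' Pairwise UniFrac distance matrix
#'
#' @param ds A `unifrac_dataset` with at least two samples of positive total.
#' @param metric One of `"unweighted"`, `"weighted_raw"`,
#'   `"weighted_normalized"`.
#' @return A symmetric matrix with zero diagonal, sample IDs as dimnames.
#' @export
pairwise_matrix <- function(ds, metric = c("unweighted", "weighted_raw",
                                           "weighted_normalized")) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  metric <- match.arg(metric)
  samples <- colnames(ds$counts)
  if (length(samples) < 2L) stop("need >= 2 samples", call. = FALSE)
  m <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  cache <- .uf_cache(ds$tree)
  for (i in seq_along(samples)[-length(samples)]) {
    for (j in seq((i + 1L), length(samples))) {
      v <- tryCatch({
        p <- .pair_setup(ds, i, j)
        tipc <- ds$counts[, c(i, j), drop = FALSE]
        n2 <- .branch_counts(cache, tipc)
        .uf_metric(metric, cache$elen, n2, p$Na, p$Nb, cache$tip_depth, tipc)
      }, error = function(e)
        stop("pair (", samples[i], ", ", samples[j], "): ",
             conditionMessage(e), call. = FALSE))
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}
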