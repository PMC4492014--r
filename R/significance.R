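# Null-model schemes for the tip-label randomization test. All three hold the
# tree topology and branch lengths constant and move counts among tips:
#   sequence   - expand the dataset so each sequence occurrence is its own
#                tip, then apply a uniform permutation of the per-tip count
#                vectors across all expanded tips (random reassignment of
#                individual sequences across samples)
#   otu        - collapse the dataset so each OTU is one tip, then apply a
#                uniform permutation of per-tip count vectors (clonal
#                sequences travel together: random reassignment of OTUs)
#   within_tip - for each tip independently with probability 1/2, exchange
#                the two samples' counts (per-tip label swap reading of
#                "swapping sample labels and their counts on a tip-by-tip
#                basis")
PERMUTATION_SCHEMES <- c("sequence", "otu", "within_tip")

# deterministic per-iteration seed stream, kept below 2^31
.iter_seed <- function(seed, i) {
  ((as.double(seed) %% 2147483647) * 48271 + i * 7919) %% 2147483629 + 1
}

.scheme_dataset <- function(ds, scheme) {
  switch(scheme,
         sequence = expand_replicates(ds),
         otu = collapse_replicates(ds),
         within_tip = ds)
}

# one draw of permuted tip-count rows (matrix in, matrix out)
.permute_counts <- function(counts, scheme) {
  if (scheme == "within_tip") {
    if (ncol(counts) != 2L)
      stop("within_tip scheme requires exactly two samples", call. = FALSE)
    swap <- stats::runif(nrow(counts)) < 0.5
    out <- counts
    out[swap, ] <- counts[swap, 2:1]
    out
  } else {
    out <- counts[sample.int(nrow(counts)), , drop = FALSE]
    rownames(out) <- rownames(counts)
    out
  }
}

#' Draw one randomized dataset under a null-model scheme
#'
#' Topology and branch lengths are untouched; only the association between
#' tips and count vectors changes.  `"sequence"` first expands the dataset
#' (each sequence occurrence its own zero-length tip), `"otu"` first collapses
#' it (each OTU one counted tip), then both permute the per-tip count vectors
#' uniformly at random across tips.  `"within_tip"` swaps the two samples'
#' counts within each tip independently with probability 1/2.
#'
#' @param ds A `unifrac_dataset` (two samples for `"within_tip"`).
#' @param scheme One of `"sequence"`, `"otu"`, `"within_tip"`.
#' @param seed Integer seed; identical seeds give identical permutations.
#' @return A permuted `unifrac_dataset` (in the scheme's encoding).
#' @export
permute_dataset <- function(ds, scheme = PERMUTATION_SCHEMES, seed = NULL) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  scheme <- match.arg(scheme)
  ds2 <- .scheme_dataset(ds, scheme)
  if (!is.null(seed)) set.seed(seed)
  ds2$counts <- .permute_counts(ds2$counts, scheme)
  ds2
}

.sig_result <- function(observed, null_values, scheme, metric, seed,
                        exact = FALSE, n_total = NULL) {
  k <- sum(null_values >= observed)   # ties count toward k (conservative)
  n <- length(null_values)
  if (exact) {
    p <- k / n
    structure(list(observed = observed, null_values = null_values,
                   p_value = p, scheme = scheme, metric = metric,
                   n_permutations = if (is.null(n_total)) n else n_total,
                   seed = NA_integer_, exact = TRUE),
              class = "unifrac_sig")
  } else {
    structure(list(observed = observed, null_values = null_values,
                   p_value = (k + 1) / (n + 1), p_naive = k / n,
                   scheme = scheme, metric = metric,
                   n_permutations = n, seed = seed, exact = FALSE),
              class = "unifrac_sig")
  }
}

#' @export
print.unifrac_sig <- function(x, ...) {
  cat(if (isTRUE(x$exact)) "Exact" else "Monte Carlo",
      "UniFrac significance test\n")
  cat("  metric:", x$metric, "  scheme:", x$scheme, "\n")
  cat("  observed:", format(x$observed), "\n")
  cat("  null:", x$n_permutations,
      if (isTRUE(x$exact)) "arrangements" else "permutations",
      " mean", format(mean(x$null_values)), "\n")
  cat("  p-value:", format(x$p_value), "\n")
  invisible(x)
}

#' Monte Carlo UniFrac significance test
#'
#' Compares the observed UniFrac distance between two samples with its
#' distribution under a tip-label randomization null model.  Large distances
#' relative to the null indicate that the samples harbor phylogenetically
#' distinct communities; the p-value is the upper-tail probability
#' \eqn{(1 + \#\{null \ge observed\}) / (1 + n)} (the pseudo-count keeps
#' Monte Carlo p-values valid; the plug-in estimate \eqn{k/n} is also
#' reported as `p_naive`).
#'
#' The observed statistic is computed on the dataset exactly as given — by
#' the zero-branch-length invariance it is identical under the expanded and
#' collapsed encodings.  The null distribution, in contrast, depends on the
#' scheme: `"sequence"` and `"otu"` nulls differ whenever any tip carries a
#' total count above 1, because the expanded encoding lets clonal sequences
#' be split across samples during randomization.
#'
#' @param ds A `unifrac_dataset`.
#' @param a,b Sample IDs (or column indices).
#' @param metric `"unweighted"`, `"weighted_raw"` or `"weighted_normalized"`.
#' @param scheme Null-model scheme; see [permute_dataset()].
#' @param n_permutations Number of Monte Carlo permutations (default 999).
#' @param seed Integer seed; each permutation uses a stream derived from
#'   `(seed, iteration)`, so results are reproducible.
#' @return A `unifrac_sig` object: `observed`, `null_values`, `p_value`,
#'   `p_naive`, `scheme`, `metric`, `n_permutations`, `seed`.
#' @examples
#' ds <- bind_dataset(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"),
#'   matrix(c(3L,3L,0L,0L, 0L,0L,3L,3L), 4, 2,
#'          dimnames = list(c("A","B","C","D"), c("s1","s2"))))
#' monte_carlo_test(ds, "s1", "s2", scheme = "otu",
#'                  n_permutations = 99, seed = 1)
#' @export
monte_carlo_test <- function(ds, a, b,
                             metric = c("unweighted", "weighted_raw",
                                        "weighted_normalized"),
                             scheme = PERMUTATION_SCHEMES,
                             n_permutations = 999, seed = 1) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  p <- .pair_setup(ds, a, b)
  observed <- .uf_value(ds, p$ia, p$ib, metric)

  pair <- ds
  pair$counts <- ds$counts[, c(p$ia, p$ib), drop = FALSE]
  null_ds <- .scheme_dataset(pair, scheme)
  cache <- .uf_cache(null_ds$tree)
  counts <- null_ds$counts
  null_values <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    set.seed(.iter_seed(seed, i))
    cperm <- .permute_counts(counts, scheme)
    n2 <- .branch_counts(cache, cperm)
    null_values[i] <- .uf_metric(metric, cache$elen, n2,
                                 sum(cperm[, 1]), sum(cperm[, 2]),
                                 cache$tip_depth, cperm)
  }
  .sig_result(observed, null_values, scheme, metric, seed)
}

.uf_value <- function(ds, ia, ib, metric) {
  cache <- .uf_cache(ds$tree)
  tipc <- ds$counts[, c(ia, ib), drop = FALSE]
  n2 <- .branch_counts(cache, tipc)
  .uf_metric(metric, cache$elen, n2, sum(tipc[, 1]), sum(tipc[, 2]),
             cache$tip_depth, tipc)
}

# enumerate all distinct arrangements of multiset rows; returns integer
# matrix, one row per arrangement, entries indexing the unique row types
.multiset_permutations <- function(type, mult, limit) {
  ntypes <- length(mult)
  npos <- sum(mult)
  total <- round(exp(lgamma(npos + 1) - sum(lgamma(mult + 1))))
  if (total > limit)
    stop("exact enumeration infeasible: ", total,
         " distinct arrangements (limit ", limit,
         "); use monte_carlo_test()", call. = FALSE)
  out <- matrix(0L, total, npos)
  row <- integer(npos)
  idx <- 0L
  rec <- function(pos, left) {
    if (pos > npos) {
      idx <<- idx + 1L
      out[idx, ] <<- row
      return(invisible())
    }
    for (t in seq_len(ntypes)) {
      if (left[t] == 0L) next
      row[pos] <<- t
      left2 <- left; left2[t] <- left2[t] - 1L
      rec(pos + 1L, left2)
    }
  }
  rec(1L, mult)
  out
}

#' Exact permutation test by full enumeration
#'
#' Enumerates every distinct arrangement of the null model's permutable units
#' (count vectors across tips for `"sequence"`/`"otu"`, swap patterns for
#' `"within_tip"`), evaluates the metric on each, and reports the exact
#' reference distribution and p-value \eqn{\#\{null \ge observed\}/total}
#' with no pseudo-count.  All arrangements of a multiset are equally likely
#' under a uniform permutation, so `null_values` carries one entry per
#' distinct arrangement with equal weight.  Serves as the oracle for
#' [monte_carlo_test()] and exposes how the `"sequence"` and `"otu"` nulls
#' differ on replicated data.
#'
#' @inheritParams monte_carlo_test
#' @param max_arrangements Refuse enumeration beyond this many distinct
#'   arrangements (default 2e5).
#' @return A `unifrac_sig` object with `exact = TRUE`.
#' @export
exact_test <- function(ds, a, b,
                       metric = c("unweighted", "weighted_raw",
                                  "weighted_normalized"),
                       scheme = PERMUTATION_SCHEMES,
                       max_arrangements = 2e5) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  p <- .pair_setup(ds, a, b)
  observed <- .uf_value(ds, p$ia, p$ib, metric)

  pair <- ds
  pair$counts <- ds$counts[, c(p$ia, p$ib), drop = FALSE]
  null_ds <- .scheme_dataset(pair, scheme)
  cache <- .uf_cache(null_ds$tree)
  counts <- null_ds$counts

  if (scheme == "within_tip") {
    ntips <- nrow(counts)
    total <- 2^ntips
    if (total > max_arrangements)
      stop("exact enumeration infeasible: ", total, " swap patterns (limit ",
           max_arrangements, "); use monte_carlo_test()", call. = FALSE)
    null_values <- numeric(total)
    for (m in seq_len(total)) {
      swap <- as.logical(bitwAnd(bitwShiftR(m - 1L, seq_len(ntips) - 1L), 1L))
      cperm <- counts
      cperm[swap, ] <- counts[swap, 2:1]
      n2 <- .branch_counts(cache, cperm)
      null_values[m] <- .uf_metric(metric, cache$elen, n2,
                                   sum(cperm[, 1]), sum(cperm[, 2]),
                                   cache$tip_depth, cperm)
    }
    return(.sig_result(observed, null_values, scheme, metric, NA,
                       exact = TRUE, n_total = total))
  }

  key <- apply(counts, 1L, paste, collapse = ",")
  utab <- counts[!duplicated(key), , drop = FALSE]
  type_of <- match(key, key[!duplicated(key)])
  mult <- tabulate(type_of, nbins = nrow(utab))
  arr <- .multiset_permutations(seq_len(nrow(utab)), mult, max_arrangements)
  null_values <- numeric(nrow(arr))
  for (i in seq_len(nrow(arr))) {
    cperm <- utab[arr[i, ], , drop = FALSE]
    n2 <- .branch_counts(cache, cperm)
    null_values[i] <- .uf_metric(metric, cache$elen, n2,
                                 sum(cperm[, 1]), sum(cperm[, 2]),
                                 cache$tip_depth, cperm)
  }
  .sig_result(observed, null_values, scheme, metric, NA,
              exact = TRUE, n_total = nrow(arr))
}
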