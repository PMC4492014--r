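#' Define a simulation scenario
#'
#' Describes the world the generator emulates: a random rooted bifurcating
#' tree over `n_otus` OTUs (sequential pair joining, exponential branch
#' lengths with rate `tree_rate`), a community composition drawn from a
#' symmetric Dirichlet with concentration `alpha`, and two samples of
#' multinomial counts at the stated sequencing depth.  `replication` is the
#' mean per-OTU count and sets the default depth (`n_otus * replication`);
#' values well above 1 put tips in the regime where the expanded and
#' collapsed tree encodings — and hence the sequence-level and OTU-level
#' nulls — diverge.  With `effect = "none"` both samples are drawn i.i.d.
#' from one composition (an exchangeable null).  With `effect =
#' "clade_shift"` the second sample's composition is multiplied by
#' `fold_change` inside a clade covering roughly `clade_fraction` of the tips
#' and renormalized, producing the phylogenetically clustered difference
#' UniFrac is designed to detect.
#'
#' @param n_otus Number of OTUs (tree tips), >= 1.
#' @param replication Mean per-OTU count (default 5).
#' @param depth Sequencing depth per sample (default `n_otus * replication`).
#' @param tree_rate Rate of the exponential branch-length distribution
#'   (default 1; mean branch length `1/tree_rate` substitutions/site).
#' @param alpha Symmetric Dirichlet concentration for the composition
#'   (default 1 = uniform over the simplex).
#' @param effect `"none"` or `"clade_shift"`.
#' @param clade_fraction Fraction of tips in the shifted clade, in (0, 1)
#'   (default 0.25).
#' @param fold_change Multiplier applied to the clade's composition in the
#'   second sample (default 4; 1 reduces to `effect = "none"`).
#' @return A `scenario` object (validated list).
#' @export
scenario <- function(n_otus = 32, replication = 5,
                     depth = round(n_otus * replication),
                     tree_rate = 1, alpha = 1,
                     effect = c("none", "clade_shift"),
                     clade_fraction = 0.25, fold_change = 4) {
  effect <- match.arg(effect)
  if (n_otus < 1) stop("n_otus must be >= 1", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (tree_rate <= 0 || alpha <= 0)
    stop("tree_rate and alpha must be positive", call. = FALSE)
  if (effect == "clade_shift") {
    if (clade_fraction <= 0 || clade_fraction >= 1)
      stop("clade_fraction must be in (0, 1)", call. = FALSE)
    if (fold_change <= 0) stop("fold_change must be positive", call. = FALSE)
  }
  structure(list(n_otus = as.integer(n_otus), replication = replication,
                 depth = as.integer(depth), tree_rate = tree_rate,
                 alpha = alpha, effect = effect,
                 clade_fraction = clade_fraction, fold_change = fold_change),
            class = "scenario")
}

.rdirichlet <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

# random rooted bifurcating tree with exponential branch lengths
.random_tree <- function(n, rate) {
  labels <- sprintf("otu%03d", seq_len(n))
  if (n == 1L)
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = stats::rexp(1, rate), Nnode = 1L,
                          tip.label = labels), class = "phylo"))
  tr <- random_topology(labels)
  tr$edge.length <- stats::rexp(length(tr$edge.length), rate)
  tr
}

# tips of the internal clade whose size is closest to fraction * ntips
.pick_clade <- function(tree, fraction) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) return(tree$tip.label)
  cache <- .uf_cache(tree)
  sizes <- rowSums(cache$Aedge)
  internal <- which(cache$child > ntip & sizes < ntip)
  cand <- if (length(internal)) internal else seq_along(cache$child)
  target <- fraction * ntip
  best <- cand[which.min(abs(sizes[cand] - target))]
  # ties broken by which.min (first in postorder) for determinism
  tree$tip.label[which(cache$Aedge[best, ] > 0)]
}

#' Simulate a two-sample dataset under a scenario
#'
#' @param sc A [scenario()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `unifrac_dataset` with samples `"s1"` and `"s2"`.
#' @examples
#' ds <- simulate_dataset(scenario(n_otus = 8, replication = 3), seed = 42)
#' colSums(ds$counts)
#' @export
simulate_dataset <- function(sc, seed = 1) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(seed)
  tree <- .random_tree(sc$n_otus, sc$tree_rate)
  comp <- .rdirichlet(sc$n_otus, sc$alpha)
  comp_b <- comp
  if (sc$effect == "clade_shift") {
    clade <- .pick_clade(tree, sc$clade_fraction)
    i <- match(clade, tree$tip.label)
    comp_b[i] <- comp_b[i] * sc$fold_change
    comp_b <- comp_b / sum(comp_b)
  }
  c1 <- stats::rmultinom(1, sc$depth, comp)[, 1]
  c2 <- stats::rmultinom(1, sc$depth, comp_b)[, 1]
  counts <- cbind(s1 = as.integer(c1), s2 = as.integer(c2))
  rownames(counts) <- tree$tip.label
  bind_dataset(tree, counts)
}

# two-sided Kolmogorov-Smirnov statistic between two samples (no test)
.ks_stat <- function(x, y) {
  allv <- sort(unique(c(x, y)))
  Fx <- vapply(allv, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(allv, function(v) mean(y <= v), numeric(1))
  max(abs(Fx - Fy))
}

#' Quantify how the choice of null model changes the test
#'
#' For each of `n_datasets` simulated datasets, runs the Monte Carlo test
#' under both the sequence-level and the OTU-level null, asserts that the
#' observed statistics agree between the expanded and collapsed encodings (to
#' 1e-12), and records both p-values together with the Kolmogorov–Smirnov
#' statistic between the two schemes' null samples.  With `replication > 1`
#' the encodings carry different permutable units and the nulls separate;
#' with `replication = 1` they coincide.
#'
#' @param sc A [scenario()]; meaningful with `replication > 1`.
#' @param n_datasets Number of simulated datasets (default 20).
#' @param n_permutations Monte Carlo permutations per test (default 199).
#' @param metric Metric for the significance tests (default `"weighted_raw"`).
#' @param seed Integer seed.
#' @return An object of class `discrepancy_report`: a data.frame (one row per
#'   dataset: observed unweighted/weighted values, `p_seq`, `p_otu`,
#'   `ks_stat`) plus a `summary` attribute with the distribution of p-value
#'   differences.
#' @export
discrepancy_experiment <- function(sc, n_datasets = 20, n_permutations = 199,
                                   metric = c("weighted_raw", "unweighted",
                                              "weighted_normalized"),
                                   seed = 1) {
  stopifnot(inherits(sc, "scenario"))
  metric <- match.arg(metric)
  rows <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    ds <- simulate_dataset(sc, seed = .iter_seed(seed, d))
    exp_ds <- expand_replicates(ds)
    col_ds <- collapse_replicates(ds)
    obs_u <- unweighted_unifrac(ds, "s1", "s2")
    obs_w <- weighted_unifrac(ds, "s1", "s2")
    stopifnot(abs(obs_u - unweighted_unifrac(exp_ds, "s1", "s2")) < 1e-12,
              abs(obs_u - unweighted_unifrac(col_ds, "s1", "s2")) < 1e-12,
              abs(obs_w - weighted_unifrac(exp_ds, "s1", "s2")) < 1e-12,
              abs(obs_w - weighted_unifrac(col_ds, "s1", "s2")) < 1e-12)
    t_seq <- monte_carlo_test(ds, "s1", "s2", metric = metric,
                              scheme = "sequence",
                              n_permutations = n_permutations,
                              seed = .iter_seed(seed, 10000 + d))
    t_otu <- monte_carlo_test(ds, "s1", "s2", metric = metric,
                              scheme = "otu",
                              n_permutations = n_permutations,
                              seed = .iter_seed(seed, 20000 + d))
    rows[[d]] <- data.frame(dataset = d, observed_unweighted = obs_u,
                            observed_weighted = obs_w,
                            p_seq = t_seq$p_value, p_otu = t_otu$p_value,
                            ks_stat = .ks_stat(t_seq$null_values,
                                               t_otu$null_values))
  }
  tab <- do.call(rbind, rows)
  attr(tab, "summary") <- c(mean_abs_p_diff = mean(abs(tab$p_seq - tab$p_otu)),
                            max_abs_p_diff = max(abs(tab$p_seq - tab$p_otu)),
                            mean_ks = mean(tab$ks_stat),
                            frac_ks_positive = mean(tab$ks_stat > 0))
  class(tab) <- c("discrepancy_report", "data.frame")
  tab
}

#' @export
print.discrepancy_report <- function(x, ...) {
  print.data.frame(x, ...)
  s <- attr(x, "summary")
  cat("\nsummary:", paste(names(s), signif(s, 4), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Empirical type-I error of a null-model scheme
#'
#' Simulates datasets under the scenario's null (`effect` must be `"none"`,
#' so both samples are i.i.d. draws from one composition and OTU count
#' vectors are exchangeable across tips), runs the Monte Carlo test under the
#' requested scheme, and reports the fraction of datasets rejected at level
#' `alpha`.
#'
#' @param sc A [scenario()] with `effect = "none"`.
#' @param n_datasets Number of simulated null datasets (default 200).
#' @param alpha Nominal level (default 0.05).
#' @param scheme Null-model scheme (default `"otu"`).
#' @param metric Metric (default `"weighted_raw"`).
#' @param n_permutations Permutations per test (default 199).
#' @param seed Integer seed.
#' @return A list: `rejection_rate`, `alpha`, `n_datasets`, `p_values`.
#' @export
type1_experiment <- function(sc, n_datasets = 200, alpha = 0.05,
                             scheme = PERMUTATION_SCHEMES,
                             metric = c("weighted_raw", "unweighted",
                                        "weighted_normalized"),
                             n_permutations = 199, seed = 1) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$effect != "none")
    stop("type-I experiment requires effect = 'none'", call. = FALSE)
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  pv <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    ds <- simulate_dataset(sc, seed = .iter_seed(seed, d))
    pv[d] <- monte_carlo_test(ds, "s1", "s2", metric = metric,
                              scheme = scheme,
                              n_permutations = n_permutations,
                              seed = .iter_seed(seed, 30000 + d))$p_value
  }
  list(rejection_rate = mean(pv <= alpha), alpha = alpha,
       n_datasets = n_datasets, p_values = pv)
}
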