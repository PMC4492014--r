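---
title: "UniFrac significance testing and the choice of null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UniFrac significance testing and the choice of null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unifracnull)
```

## The model

Two microbial community samples are observed as counts of sequences
attached to the tips of a rooted phylogenetic tree with non-negative branch
lengths. For each non-root branch $b$ with length $\ell_b$, let $n_b(s)$ be
the number of sample-$s$ sequences among the tips descending from $b$, and
$N_s$ the sample total. The package computes

$$U \;=\; \frac{\sum_b \ell_b\,\mathbf{1}[\,n_b(a)>0 \oplus n_b(b)>0\,]}
               {\sum_b \ell_b\,\mathbf{1}[\,n_b(a)>0 \vee n_b(b)>0\,]}
\qquad\text{(unweighted)}$$

$$W \;=\; \sum_b \ell_b \left|\frac{n_b(a)}{N_a}-\frac{n_b(b)}{N_b}\right|
\qquad\text{(weighted, raw)}$$

and the normalized variant $W/D$ with
$D = \sum_j d_j\,(c_j(a)/N_a + c_j(b)/N_b)$, where $d_j$ is the root-to-tip
path length of tip $j$ and $c_j(s)$ its count. $U$ and $W/D$ lie in $[0,1]$.
$U$ is a presence/absence metric: replacing any positive count by 1, or
scaling a sample's counts, changes nothing. Raw $W$ scales linearly with a
global branch-length rescaling. The root's own branch length, if present in
the Newick input, is ignored; contributions start at the root's children.
Branches with no descendants in either compared sample enter neither
numerator nor denominator, so each pairwise comparison is self-contained.

All of this is assembled from a single post-order branch accumulation
(`branch_partition()`), cached per tree so that permutation tests reduce to
one small matrix product per draw.

## Two encodings, one distance, two tests

The same data can be written on a tree two ways. In the *expanded* encoding,
a sequence observed $c$ times appears as $c$ tips with count 1, attached by
branches of length zero under a shared parent. In the *collapsed* encoding
(what OTU-picking pipelines produce), it is one tip with count $c$. Because
the extra branches have length zero, $U$, $W$ and $W/D$ are identical under
both encodings — the package asserts agreement to $10^{-12}$, and the test
suite verifies it on 500 simulated datasets.

A randomization test, however, permutes *tips*, and the two encodings have
different tips. `unifracnull` therefore makes the null model an explicit
argument rather than an accident of input format:

- **`scheme = "sequence"`** — expand first, then uniformly permute the
  per-tip count vectors across all expanded tips. Individual sequence
  occurrences are reassigned across samples; clonal populations are split.
- **`scheme = "otu"`** — collapse first, then uniformly permute per-tip
  count vectors. Whole OTUs travel between samples; sequences from the same
  clone stay together. This is the null most users of OTU tables want.
- **`scheme = "within_tip"`** — for each tip independently with probability
  1/2, exchange the two samples' counts. Included because "swapping sample
  labels and their counts on a tip-by-tip basis" admits both a global
  permutation and a per-tip swap reading; both are provided rather than
  guessing historical intent.

The first two schemes preserve the multiset of count vectors and the
per-sample grand totals exactly; the third preserves per-tip totals and the
pooled total. With no replicated sequence (every tip total $\le 1$) the
expanded and collapsed encodings coincide, and the package guarantees the
two schemes' nulls are *identical* under a shared seed — the transforms have
identity fast paths precisely so the permutation streams stay synchronized.

`monte_carlo_test()` reports $p = (1+k)/(1+n)$ with
$k = \#\{ \text{null} \ge \text{observed} \}$ (ties counted, pseudo-count for
validity) alongside the plug-in $k/n$. `exact_test()` enumerates every
distinct arrangement of the permutable multiset — all arrangements are
equally likely under a uniform permutation — and reports $k/\text{total}$
with no pseudo-count. Enumeration is refused beyond `max_arrangements`
(default $2\times10^5$) distinct arrangements; this guard replaces a raw
unit-count cutoff because replication collapses the arrangement count (8
expanded tips split 4/4 give 70 arrangements, while 10 distinct vectors
would give $10! \approx 3.6$M).

```{r fixture}
ds <- bind_dataset(
  parse_newick("((otuA:1,otuB:2):1,(otuC:1,otuD:3):2);"),
  read_abundance_table(system.file("extdata", "replicated_fixture.tsv",
                                   package = "unifracnull")))
exact_test(ds, "s1", "s2", metric = "weighted_raw", scheme = "sequence")
exact_test(ds, "s1", "s2", metric = "weighted_raw", scheme = "otu")
```

Same observed statistic, different reference distribution, different
p-value. That is the package's central demonstrable fact.

## The P test

The complementary randomization holds sample labels fixed and randomizes
the *topology*. The statistic is the minimum number of sample-label changes
on the tree under Fitch small parsimony (`fitch_changes()`), computed with
the generalized multifurcation rule: at a node with $k$ children, each
candidate state is scored by the number of children whose state sets contain
it; the node keeps the argmax states and the change count increases by $k$
minus the maximum. The test suite verifies this equals the brute-force
minimum over all ancestral labelings. Counted tips are expanded before
labeling, so abundance enters through tip multiplicity. The null draws
topologies by uniform sequential pair joining (each step joins a uniformly
chosen pair of live lineages); the randomizer is a small internal function
and deliberately easy to swap, since many tree-randomization theories exist
and none is canonical. Small change counts mean the samples cluster in
clades, so the lower tail is significant: $p=(1+\#\{null \le obs\})/(1+n)$.

## What the synthetic generator emulates

`scenario()` fixes a stated world: a rooted bifurcating tree over `n_otus`
tips from sequential pair joining with $\mathrm{Exp}(\texttt{tree\_rate})$
branch lengths; a community composition drawn once from a symmetric
Dirichlet(`alpha`); and two samples of multinomial counts at depth
`n_otus * replication`. Defaults — 32 OTUs, replication 5 (depth 160),
`tree_rate = 1`, `alpha = 1` — describe a small clone-library-scale survey
in which most OTUs carry counts well above 1, the regime where the two
encodings genuinely diverge; they were chosen once, before any calibration
was measured, and are not tuned. With `effect = "none"`, both samples are
i.i.d. from one composition and the symmetric Dirichlet makes per-OTU count
vectors exchangeable across tips — exactly the exchangeability the OTU-level
permutation assumes, so its p-values should be calibrated there (the
acceptance suite finds a rejection rate of about 0.05 at $\alpha = 0.05$
over 1000 null datasets). With `effect = "clade_shift"`, the internal clade
whose tip fraction is closest to `clade_fraction` has its composition
multiplied by `fold_change` in sample 2 and renormalized, giving the
phylogenetically clustered signal UniFrac targets; `fold_change = 1`
degenerates to the null, reproducibly under a shared seed.

What the generator does *not* emulate: sequencing error, chimeras, variable
library sizes, compositional biases of amplicon protocols, or realistic
phylogenies. A green calibration test therefore establishes internal
statistical coherence of scheme and generator, not field performance.

`discrepancy_experiment()` packages the comparison: per simulated dataset it
asserts encoding invariance of the observed statistics, runs both
label-permutation schemes, and reports the p-value gap and the
Kolmogorov–Smirnov statistic between the two null samples.
`type1_experiment()` reports rejection rates under the null scenario. No
winner is asserted between the schemes; the experiments quantify the
difference and leave the choice of null hypothesis to the analyst.

## Numerical and design choices

- **Branch lengths absent in Newick are 0, not an error** — the expanded
  encoding requires zero-length branches. Unrooted (trifurcating-top) files
  are accepted with the written top node as root; rooting changes both
  metrics, so this is documented rather than silent.
- **Collapse merges across zero-length paths of any depth**, not only single
  cherries, making it idempotent; a tip with single counts in two samples is
  still expanded (it encodes two sequence occurrences). Merged tips take the
  ancestor's label when present (expansion leaves the original name there,
  so collapse∘expand restores names), otherwise the first merged tip's name.
- **Pruning never relocates the root.** Unlinking a degree-1 root (as
  generic tip-dropping utilities do) deletes the shared basal branch and
  changes the unweighted denominator; keeping the root fixed makes
  `prune_empty_tips()` exactly metric-preserving, which the suite checks.
- **Degenerate inputs**: a zero-total sample is an error for an observed
  comparison; a within-tip null draw that empties one sample treats its
  relative abundances as all-zero rather than 0/0; an all-zero-length
  occupied tree makes $U$ 0 with a warning and the normalized $W$ an error.
- **Seeding**: every stochastic routine takes one integer seed; iteration
  $i$ uses a derived stream seed, kept below $2^{31}$, so results are
  byte-reproducible and insensitive to evaluation order.
- **Default weighted variant is raw** (unnormalized) for significance
  testing, with normalization opt-in; the raw statistic keeps the null
  distribution's branch-length units and matches historical defaults.

## Limitations

Pairwise two-sample tests lose power rapidly when applied across many
sample pairs (multiple-comparison corrections eat the budget), and small
p-values conflate effect size with sequencing depth; for many-sample
studies, testing whether UniFrac distance matrices associate with covariates
(ANOSIM/PERMANOVA-style) is usually preferable and is out of scope here, as
are OTU picking, rarefaction, variance-adjusted/generalized UniFrac, and
sparse-matrix performance engineering for NGS-scale trees.
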