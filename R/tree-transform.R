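# Internal recursive representation used by the encoding transforms.
# A node is list(name = chr | NA, length = numeric, children = list of nodes);
# tips have zero children. The root's length is carried but ignored by all
# metrics.

.phylo_to_treelist <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node.lab <- tree$node.label
  build <- function(node, len) {
    nm <- if (node <= ntip) tree$tip.label[node]
          else if (!is.null(node.lab) && nzchar(node.lab[node - ntip] %||% ""))
            node.lab[node - ntip] else NA_character_
    ch <- kids[[as.character(node)]]
    list(name = nm, length = len,
         children = lapply(ch, function(e)
           build(tree$edge[e, 2], tree$edge.length[e])))
  }
  build(root, 0)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.treelist_to_phylo <- function(tl) {
  tips <- list(); internals <- list()
  edges <- list(); elens <- numeric(0)
  # first pass: assign ids (tips 1..n in traversal order, internals after)
  count_tips <- function(nd) if (length(nd$children) == 0L) 1L else
    sum(vapply(nd$children, count_tips, integer(1)))
  ntip <- count_tips(tl)
  if (ntip == 1L) {
    # descend through any degree-1 chain, summing lengths
    len <- 0; nd <- tl
    while (length(nd$children) == 1L) { nd <- nd$children[[1]]; len <- len + nd$length }
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = len, Nnode = 1L,
                          tip.label = nd$name),
                     class = "phylo"))
  }
  tip.label <- character(ntip)
  node.label <- character(0)
  tip_i <- 0L; int_i <- 0L
  parent_v <- integer(0); child_v <- integer(0); elen_v <- numeric(0)
  assign_ids <- function(nd) {
    if (length(nd$children) == 0L) {
      tip_i <<- tip_i + 1L
      tip.label[tip_i] <<- nd$name
      tip_i
    } else {
      int_i <<- int_i + 1L
      my <- int_i
      node.label[my] <<- if (is.na(nd$name)) "" else nd$name
      for (ch in nd$children) {
        cid <- assign_ids(ch)
        parent_v <<- c(parent_v, -my)   # negative marks internal ids pre-offset
        child_v <<- c(child_v, cid)
        elen_v <<- c(elen_v, ch$length)
      }
      -my
    }
  }
  assign_ids(tl)
  nint <- int_i
  fix <- function(v) ifelse(v < 0, ntip - v, v)  # internal k -> ntip + k
  tr <- structure(list(edge = cbind(fix(parent_v), fix(child_v)),
                       edge.length = elen_v,
                       Nnode = nint,
                       tip.label = tip.label),
                  class = "phylo")
  if (any(nzchar(node.label))) tr$node.label <- node.label
  tr
}

#' Expand counted tips into replicate tips (one tip per sequence occurrence)
#'
#' Converts the collapsed encoding (one tip per OTU carrying per-sample
#' counts) into the expanded encoding: every tip whose total count across
#' samples is \eqn{c \ge 2} is replaced by an internal node at the original
#' tip position (keeping the original branch length and taking the original
#' tip's name as its label) with \eqn{c} child tips attached by branches of
#' length exactly 0.  Each child tip carries count 1 in exactly one sample and
#' is named `<orig>__<sample>__<k>`, `k = 1..count`.  Tips with total count
#' 0 or 1 are unchanged.  Because the added branches all have length zero,
#' both UniFrac metrics are unchanged by expansion; what changes is the set of
#' permutable units available to a tip-label randomization.
#'
#' @param ds A `unifrac_dataset` (see [bind_dataset()]) with integer counts.
#' @return A `unifrac_dataset` in the expanded encoding.
#' @examples
#' ds <- bind_dataset(parse_newick("(A:1,B:1);"),
#'                    matrix(c(4L, 1L), 2, 1, dimnames = list(c("A","B"), "s1")))
#' expand_replicates(ds)$tree$tip.label
#' @seealso [collapse_replicates()], the inverse transformation.
#' @export
expand_replicates <- function(ds) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  counts <- ds$counts
  tot <- rowSums(counts)
  if (all(tot <= 1L)) return(ds)
  samples <- colnames(counts)
  tl <- .phylo_to_treelist(ds$tree)
  new_rows <- list()
  expand_node <- function(nd) {
    if (length(nd$children) == 0L) {
      v <- counts[nd$name, , drop = TRUE]
      if (is.null(names(v))) names(v) <- samples  # 1-sample tables drop names
      if (sum(v) <= 1L) {
        new_rows[[nd$name]] <<- v
        return(nd)
      }
      kids <- list()
      for (s in samples) {
        if (v[[s]] == 0L) next
        for (k in seq_len(v[[s]])) {
          nm <- paste0(nd$name, "__", s, "__", k)
          row <- setNames(integer(length(samples)), samples)
          row[s] <- 1L
          new_rows[[nm]] <<- row
          kids[[length(kids) + 1L]] <- list(name = nm, length = 0,
                                            children = list())
        }
      }
      list(name = nd$name, length = nd$length, children = kids)
    } else {
      nd$children <- lapply(nd$children, expand_node)
      nd
    }
  }
  tl2 <- expand_node(tl)
  tree2 <- .treelist_to_phylo(tl2)
  counts2 <- do.call(rbind, new_rows)
  rownames(counts2) <- names(new_rows)
  bind_dataset(tree2, counts2)
}

#' Collapse replicate tips connected by zero-length branches
#'
#' Inverse of [expand_replicates()]: every maximal set of tips connected to a
#' common ancestor exclusively through zero-length branches is merged into a
#' single tip whose count vector is the element-wise sum of the merged tips'
#' vectors.  When an internal node's entire subtree collapses, the merged tip
#' sits at that node, inherits its branch length, and takes the node's label
#' if it has one (otherwise the first merged tip's name).  Merging works
#' across zero-length paths of any depth, so the operation is idempotent.
#'
#' @param ds A `unifrac_dataset`.
#' @return A `unifrac_dataset` in the collapsed encoding.
#' @export
collapse_replicates <- function(ds) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  # merges only start at zero-length tip branches; without any, identity
  tip_edges <- ds$tree$edge[, 2] <= length(ds$tree$tip.label)
  if (all(ds$tree$edge.length[tip_edges] > 0)) return(ds)
  counts <- ds$counts
  samples <- colnames(counts)
  new_rows <- list()
  zero <- setNames(integer(length(samples)), samples)
  # post-order; returns node (possibly turned into a tip) plus its count
  # vector when it is a tip
  walk <- function(nd) {
    if (length(nd$children) == 0L) {
      nd$vec <- counts[nd$name, ]
      return(nd)
    }
    nd$children <- lapply(nd$children, walk)
    is_zero_tip <- vapply(nd$children, function(ch)
      length(ch$children) == 0L && ch$length == 0, logical(1))
    if (all(is_zero_tip) && length(nd$children) >= 1L) {
      vec <- Reduce(`+`, lapply(nd$children, `[[`, "vec"))
      nm <- if (!is.na(nd$name)) nd$name else nd$children[[1]]$name
      return(list(name = nm, length = nd$length, children = list(), vec = vec))
    }
    if (sum(is_zero_tip) >= 2L) {
      merged <- nd$children[is_zero_tip]
      vec <- Reduce(`+`, lapply(merged, `[[`, "vec"))
      keep <- nd$children[!is_zero_tip]
      tip <- list(name = merged[[1]]$name, length = 0, children = list(),
                  vec = vec)
      nd$children <- c(list(tip), keep)
    }
    nd
  }
  tl2 <- walk(.phylo_to_treelist(ds$tree))
  collect <- function(nd) {
    if (length(nd$children) == 0L) new_rows[[nd$name]] <<- nd$vec
    else for (ch in nd$children) collect(ch)
  }
  collect(tl2)
  strip <- function(nd) {
    nd$vec <- NULL
    nd$children <- lapply(nd$children, strip)
    nd
  }
  tree2 <- .treelist_to_phylo(strip(tl2))
  counts2 <- do.call(rbind, new_rows)
  rownames(counts2) <- names(new_rows)
  bind_dataset(tree2, counts2)
}

#' Remove tips with all-zero counts
#'
#' Non-root degree-2 internal nodes created by pruning are unlinked with
#' their branch lengths summed, so root-to-tip path lengths of the remaining
#' tips are preserved.  The root itself is never relocated, even when it is
#' left with a single child: re-rooting would delete the shared basal branch
#' and change the unweighted UniFrac denominator, whereas pruning as defined
#' here leaves both metrics exactly unchanged.
#'
#' @param ds A `unifrac_dataset`.
#' @return A pruned `unifrac_dataset`.
#' @export
prune_empty_tips <- function(ds) {
  stopifnot(inherits(ds, "unifrac_dataset"))
  counts <- ds$counts
  keep <- rownames(counts)[rowSums(counts) > 0L]
  if (length(keep) == 0L)
    stop("pruning would remove all tips (no nonzero counts)", call. = FALSE)
  if (length(keep) == length(ds$tree$tip.label)) return(ds)
  walk <- function(nd, at_root) {
    if (length(nd$children) == 0L) {
      if (nd$name %in% keep) return(nd) else return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(nd$children, walk, at_root = FALSE))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L && !at_root) {
      kid <- kids[[1]]
      kid$length <- kid$length + nd$length  # unlink degree-2 node
      return(kid)
    }
    nd$children <- kids
    nd
  }
  tl <- walk(.phylo_to_treelist(ds$tree), at_root = TRUE)
  bind_dataset(.treelist_to_phylo(tl), counts[keep, , drop = FALSE])
}
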