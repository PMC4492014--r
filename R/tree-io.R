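#' Parse a Newick string into a rooted phylogenetic tree
#'
#' Wraps [ape::read.tree()] with strict validation of the invariants every
#' downstream computation relies on: unique non-empty tip labels, non-negative
#' branch lengths (missing lengths default to 0, which the expanded tree
#' encoding requires), and a single distinguished root.  Trees written
#' unrooted (trifurcating top node) are accepted; the written top node is
#' treated as the root.  Because rooting changes both UniFrac metrics, make
#' sure the root placement is meaningful for your data.
#'
#' @param text A single Newick statement terminated by `;`.
#' @return An object of class `phylo` (see \pkg{ape}); `edge.length` is always
#'   present, with absent lengths stored as 0.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @seealso [write_newick()], [read_abundance_table()], [bind_dataset()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  txt <- trimws(text)
  tip1 <- .parse_single_tip(txt)
  if (!is.null(tip1)) return(validate_tree(tip1))
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error: input did not yield a tree", call. = FALSE)
  validate_tree(tr)
}

# balance check with character offsets; ape's own errors lack positions
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i, call. = FALSE)
    } else if (ch == ";") { semi <- i; break }
  }
  if (is.na(semi))
    stop("Newick parse error: no terminating ';' (scanned ",
         length(chars), " characters)", call. = FALSE)
  if (depth != 0L)
    stop("Newick parse error: ", depth,
         " unclosed '(' at terminating ';' (character ", semi, ")", call. = FALSE)
  invisible(TRUE)
}

# ape::read.tree cannot represent a single-tip tree; handle "A;" / "A:1.5;"
.parse_single_tip <- function(txt) {
  m <- regmatches(txt, regexec(
    "^('[^']*'|[^():,;[:space:]]+)(:([0-9eE.+-]+))?;$", txt))[[1]]
  if (length(m) == 0L) return(NULL)
  label <- gsub("^'|'$", "", m[2])
  len <- if (nzchar(m[4])) as.numeric(m[4]) else 0
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = len,
                 Nnode = 1L,
                 tip.label = label),
            class = "phylo")
}

#' Validate the structural invariants of a phylogenetic tree
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly modified so that `edge.length` exists (absent
#'   lengths become 0).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyNA(tree$edge.length)) tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree", call. = FALSE)
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("empty tip label", call. = FALSE)
  dup <- unique(tl[duplicated(tl)])
  if (length(dup))
    stop("duplicate tip name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  # every non-root node has exactly one parent
  kids <- tree$edge[, 2]
  if (anyDuplicated(kids))
    stop("node with more than one parent", call. = FALSE)
  tree
}

#' Serialize a tree to Newick
#'
#' Round-trip guarantee: `parse_newick(write_newick(t))` is isomorphic to `t`
#' with identical tip names and branch lengths to full precision.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) == 1L) {
    return(paste0(tree$tip.label, ":",
                  format(tree$edge.length[1], digits = 17), ";"))
  }
  ape::write.tree(tree, digits = 15)
}

#' Read a tip-by-sample abundance table
#'
#' The expected format is TSV with a header row of sample IDs (first field a
#' tip-ID column label, conventionally `#TIP_ID`), one row per tip, and
#' non-negative integer counts in the remaining cells.
#'
#' @param x Either a path to a TSV file or a character scalar containing the
#'   table text itself (detected by the presence of a newline or tab).
#' @return An integer matrix with tip names as rownames and sample IDs as
#'   colnames.
#' @export
read_abundance_table <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  lines <- if (grepl("[\n\t]", x)) strsplit(x, "\n", fixed = TRUE)[[1]] else readLines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("abundance table needs a header and >= 1 row", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  samples <- header[-1]
  if (length(samples) < 1L) stop("no sample columns in header", call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header", call. = FALSE)
  body <- cells[-1]
  tips <- vapply(body, `[`, character(1), 1L)
  dup <- unique(tips[duplicated(tips)])
  if (length(dup))
    stop("duplicate tip row(s): ", paste(dup, collapse = ", "), call. = FALSE)
  counts <- matrix(0L, length(tips), length(samples),
                   dimnames = list(tips, samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(header))
      stop("row ", i, " ('", tips[i], "') has ", length(row) - 1L,
           " cells, expected ", length(samples), call. = FALSE)
    vals <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad))
      stop("invalid count at row ", i, " ('", tips[i], "'), column '",
           samples[bad[1]], "': '", row[-1][bad[1]],
           "' (must be a non-negative integer)", call. = FALSE)
    counts[i, ] <- as.integer(vals)
  }
  counts
}

#' Write a tip-by-sample abundance table as TSV
#'
#' @param counts Integer matrix with tip rownames and sample colnames.
#' @param path Optional file path; if `NULL` the TSV text is returned.
#' @param id_column Label for the tip-ID column (default `"#TIP_ID"`).
#' @return The TSV text invisibly (or visibly when `path` is `NULL`).
#' @export
write_abundance_table <- function(counts, path = NULL, id_column = "#TIP_ID") {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  header <- paste(c(id_column, colnames(counts)), collapse = "\t")
  rows <- vapply(seq_len(nrow(counts)), function(i)
    paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t"), character(1))
  txt <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Bind a tree and an abundance table into a validated dataset
#'
#' Every table row must name a tree tip; tree tips absent from the table are
#' assigned all-zero count vectors so that the binding is total.  The count
#' matrix of the returned dataset has one row per tree tip, in tip-label
#' order of the tree.
#'
#' @param tree A `phylo` object (see [parse_newick()]).
#' @param counts Integer matrix of counts, tip names as rownames, sample IDs
#'   as colnames (see [read_abundance_table()]); or a data.frame coercible to
#'   such a matrix.
#' @return An object of class `unifrac_dataset`: a list with elements `tree`
#'   and `counts`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tab <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'               dimnames = list(c("A", "C"), c("s1", "s2")))
#' ds <- bind_dataset(tr, tab)
#' ds$counts
#' @export
bind_dataset <- function(tree, counts) {
  tree <- validate_tree(tree)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have tip rownames and sample colnames", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(counts != round(counts))) stop("non-integer counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  unmatched <- setdiff(rownames(counts), tree$tip.label)
  if (length(unmatched))
    stop("table tip(s) absent from tree: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  full <- matrix(0L, length(tree$tip.label), ncol(counts),
                 dimnames = list(tree$tip.label, colnames(counts)))
  full[rownames(counts), ] <- counts
  structure(list(tree = tree, counts = full), class = "unifrac_dataset")
}

#' @export
print.unifrac_dataset <- function(x, ...) {
  cat("unifrac_dataset:", length(x$tree$tip.label), "tips,",
      ncol(x$counts), "samples\n")
  cat("sample totals:",
      paste(colnames(x$counts), colSums(x$counts), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# sample-resolution helper used throughout: name or index -> column index
.sample_index <- function(ds, s) {
  if (is.character(s)) {
    i <- match(s, colnames(ds$counts))
    if (is.na(i)) stop("unknown sample: ", s, call. = FALSE)
    i
  } else as.integer(s)
}
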