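#' Parse a newick string into a phylo object
#'
#' Thin wrapper around [ape::read.tree()] that validates the result for use
#' in quartet scoring: leaf labels must be unique and non-empty. Internal
#' node labels, when present, are interpreted downstream as support values
#' on the subtending edge (the usual convention in gene-tree files).
#'
#' @param text A single newick string (terminating `;` optional for ape).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick string: ", substr(text, 1L, 60L), call. = FALSE)
  }
  validate_tree(tr)
  tr
}

#' @keywords internal
validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label", call. = FALSE)
  invisible(tr)
}

#' Read a species tree (single newick) from a file
#' @param file Path to a newick file containing one tree.
#' @return A `phylo` object.
#' @export
read_species_tree <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 1L) {
    stop("expected exactly one species tree in ", file,
         " (found ", length(lines), " non-empty lines)", call. = FALSE)
  }
  parse_newick(lines)
}

#' Read gene trees (one newick per line) from a file
#' @param file Path to a newick file, one tree per line.
#' @return A list of `phylo` objects.
#' @export
read_gene_trees <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene trees in ", file, call. = FALSE)
  lapply(lines, parse_newick)
}

#' Unroot a tree, suppressing the degree-2 root
#'
#' Scoring operates on unrooted trees: a rooted input has its root node
#' suppressed and the two root edges merged (lengths summed). Idempotent.
#'
#' @param tree A `phylo` object with at least 3 leaves.
#' @return An unrooted `phylo` (root node of degree >= 3).
#' @export
unroot_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) stop("need >= 3 leaves to unroot", call. = FALSE)
  tree <- ape::collapse.singles(tree)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree) else tree
}

#' Internal edges of a tree
#'
#' @param tree A `phylo` object.
#' @return Integer vector of row indices into `tree$edge` whose child node is
#'   internal (for an unrooted tree these are exactly the internal edges).
#' @export
internal_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  which(tree$edge[, 2L] > ntip)
}

#' Leaf cluster below an edge
#'
#' @param tree A `phylo` object.
#' @param edge Row index into `tree$edge`.
#' @return Character vector of tip labels descending from the edge's child.
#' @export
edge_cluster <- function(tree, edge) {
  child <- tree$edge[edge, 2L]
  ntip <- length(tree$tip.label)
  if (child <= ntip) return(tree$tip.label[child])
  tree$tip.label[tips_below(tree)[[child]]]
}

# tip indices below every node, as a list indexed by node number
#' @keywords internal
tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Bipartitions induced by internal edges
#'
#' Each internal edge of an unrooted tree splits the leaf set in two; the
#' returned cluster is the side containing the edge's child node. A binary
#' unrooted tree on l leaves has exactly l - 3 internal edges.
#'
#' @param tree An unrooted `phylo`.
#' @return Named list: `edge` (integer vector of edge row indices) and
#'   `cluster` (list of character vectors of tip labels).
#' @export
internal_bipartitions <- function(tree) {
  ie <- internal_edges(tree)
  below <- tips_below(tree)
  list(edge = ie,
       cluster = lapply(ie, function(e) tree$tip.label[below[[tree$edge[e, 2L]]]]))
}

#' Normalize a support value to the percentage scale
#'
#' Values in [0, 1] are read as probabilities and values in (1, 100] as
#' percentages, so that thresholds like 33 (percent) and 0.95 (posterior)
#' can be compared on one scale.
#'
#' @param x Numeric vector of support values or thresholds.
#' @return Numeric vector on the 0-100 scale.
#' @export
support_as_percent <- function(x) {
  ifelse(!is.na(x) & x <= 1, 100 * x, x)
}

#' Collapse poorly supported gene-tree branches
#'
#' Contracts every internal edge whose support label is strictly below the
#' threshold; edges without a (numeric) support label are retained. The
#' common preprocessing step for estimated gene trees is collapsing branches
#' below 33% bootstrap support before quartet scoring.
#'
#' @param tree A `phylo` with support values stored as internal node labels.
#' @param threshold Support threshold; percentage and probability scales are
#'   auto-detected via [support_as_percent()]. `threshold = 0` is a no-op.
#' @return A `phylo`, possibly multifurcating, with the same leaf set.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), is.numeric(threshold), threshold >= 0)
  if (threshold == 0 || is.null(tree$node.label)) return(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ie <- internal_edges(tree)
  if (!length(ie)) return(tree)
  thr <- support_as_percent(threshold)
  drop <- logical(nrow(tree$edge))
  for (e in ie) {
    child <- tree$edge[e, 2L]
    lab <- tree$node.label[child - ntip]
    if (is.null(lab) || is.na(lab) || !nzchar(lab)) next
    val <- suppressWarnings(as.numeric(lab))
    if (is.na(val)) {
      warning("non-numeric support label '", lab, "' retained", call. = FALSE)
      next
    }
    if (support_as_percent(val) < thr) drop[e] <- TRUE
  }
  if (!any(drop)) return(tree)
  contract_edges(tree, which(drop))
}

# Contract the given internal edges: each contracted edge's child node is
# merged into its parent (children re-attached; the edge's length vanishes).
#' @keywords internal
contract_edges <- function(tree, edges) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nall <- ntip + nnode
  if (any(tree$edge[edges, 2L] <= ntip)) stop("cannot contract a terminal edge", call. = FALSE)
  parent_of <- integer(nall)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  merged <- logical(nall)
  merged[tree$edge[edges, 2L]] <- TRUE
  # representative: nearest non-merged ancestor
  rep_of <- seq_len(nall)
  for (v in seq_len(nall)) {
    r <- v
    while (merged[r]) r <- parent_of[r]
    rep_of[v] <- r
  }
  keep <- setdiff(seq_len(nrow(tree$edge)), edges)
  new_parent <- rep_of[tree$edge[keep, 1L]]
  new_child <- tree$edge[keep, 2L]
  # renumber surviving internal nodes
  surv <- which(!merged & seq_len(nall) > ntip)
  newnum <- integer(nall)
  newnum[seq_len(ntip)] <- seq_len(ntip)
  newnum[surv] <- ntip + seq_along(surv)
  out <- list(
    edge = cbind(newnum[new_parent], newnum[new_child]),
    tip.label = tree$tip.label,
    Nnode = length(surv)
  )
  if (!is.null(tree$edge.length)) out$edge.length <- tree$edge.length[keep]
  if (!is.null(tree$node.label)) out$node.label <- tree$node.label[surv - ntip]
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Write a (possibly annotated) tree in newick format
#'
#' A recursive writer that supports the annotation dialects used by
#' [score_tree()]: plain internal-node labels (e.g. local posterior
#' probabilities), branch lengths, both, or a bracketed key=value comment
#' block carrying the full per-branch record.
#'
#' @param tree A `phylo`; annotations, if any, read from `tree$node.label`,
#'   `tree$edge.length` and the `node.comment` attribute (character vector
#'   indexed by internal node, set by [score_tree()] in "full" mode).
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 8) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  comments <- attr(tree, "node.comment")
  fmt_len <- function(x) {
    if (is.null(x) || is.na(x)) "" else paste0(":", format(x, digits = digits, scientific = FALSE))
  }
  rec <- function(node, edge_row) {
    if (node <= ntip) {
      s <- tree$tip.label[node]
    } else {
      parts <- vapply(kids[[as.character(node)]],
                      function(e) rec(tree$edge[e, 2L], e), character(1))
      lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
      if (is.null(lab) || is.na(lab)) lab <- ""
      com <- if (!is.null(comments) && !is.na(comments[node])) comments[node] else ""
      s <- paste0("(", paste(parts, collapse = ","), ")", lab, com)
    }
    len <- if (!is.null(edge_row) && !is.null(tree$edge.length)) tree$edge.length[edge_row] else NULL
    paste0(s, fmt_len(len))
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  out <- paste0(rec(root, NULL), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
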