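#' Quadripartitions around an internal branch of the species tree
#'
#' An internal branch of an unrooted binary tree splits the leaves into four
#' clusters (A, B | C, D): the two subtrees hanging off each endpoint. The
#' branch's own resolution is AB|CD; rearranging the clusters gives the two
#' alternative resolutions AC|BD and AD|BC. Clusters are ordered
#' canonically (A and C hold the smallest taxon of their side, and the side
#' containing taxon 1 comes first) so that the alternative labelling is
#' reproducible across runs and rerootings.
#'
#' @param tree An unrooted binary `phylo` (species tree).
#' @param edge Row index into `tree$edge` of an internal edge.
#' @return A list of four character vectors `A`, `B`, `C`, `D`; the species
#'   tree resolution is AB|CD.
#' @export
quadripartition_of_edge <- function(tree, edge) {
  ntip <- length(tree$tip.label)
  parent <- tree$edge[edge, 1L]
  child <- tree$edge[edge, 2L]
  if (child <= ntip) stop("edge is terminal, not internal", call. = FALSE)
  below <- tips_below(tree)
  deg <- function(v) {
    sum(tree$edge[, 1L] == v) + sum(tree$edge[, 2L] == v)
  }
  if (deg(child) != 3L || deg(parent) != 3L) {
    stop("unscorable polytomy edge: endpoints must have degree 3", call. = FALSE)
  }
  kidrows <- which(tree$edge[, 1L] == child)
  C <- tree$tip.label[below[[tree$edge[kidrows[1L], 2L]]]]
  D <- tree$tip.label[below[[tree$edge[kidrows[2L], 2L]]]]
  prows <- setdiff(which(tree$edge[, 1L] == parent), edge)
  side <- lapply(prows, function(e) tree$tip.label[below[[tree$edge[e, 2L]]]])
  if (length(side) == 1L) {
    # parent is a non-root node: second cluster is everything above it
    side[[2L]] <- setdiff(tree$tip.label, c(C, D, side[[1L]]))
  }
  A <- side[[1L]]; B <- side[[2L]]
  idx <- function(x) min(match(x, tree$tip.label))
  if (idx(B) < idx(A)) { tmp <- A; A <- B; B <- tmp }
  if (idx(D) < idx(C)) { tmp <- C; C <- D; D <- tmp }
  if (idx(C) < idx(A)) { tmp <- A; A <- C; C <- tmp; tmp <- B; B <- D; D <- tmp }
  list(A = A, B = B, C = C, D = D)
}

# Precompute the traversal structure of a gene tree once so that the same
# tree can be scored against many branches cheaply.
#' @keywords internal
gene_tree_profile <- function(gt) {
  if (is.null(gt) || !inherits(gt, "phylo") || length(gt$tip.label) < 4L) {
    return(NULL)
  }
  gt <- unroot_tree(gt)
  po <- ape::reorder.phylo(gt, "postorder")
  ntip <- length(po$tip.label)
  nall <- ntip + po$Nnode
  kids <- vector("list", nall)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], po$edge[k, 2L])
  }
  root <- setdiff(po$edge[, 1L], po$edge[, 2L])[1L]
  list(tree = po, ntip = ntip, nall = nall, kids = kids, root = root,
       tip.label = po$tip.label)
}

# Sum over the 12 matchings between a quadripartition pairing (a,b | c,d)
# and a tripartition whose three parts have per-cluster intersection counts
# in the rows of V3 (3 x 4): one sibling pair collapses into a single part,
# the remaining two clusters map to the remaining two parts.
#' @keywords internal
matching_sum <- function(V3, a, b, cc, d) {
  tot <- 0
  for (i in 1:3) {
    p <- V3[i, ]
    q <- V3[if (i == 1L) 2L else 1L, ]
    r <- V3[if (i == 3L) 2L else 3L, ]
    tot <- tot + p[a] * p[b] * (q[cc] * r[d] + q[d] * r[cc]) +
      p[cc] * p[d] * (q[a] * r[b] + q[b] * r[a])
  }
  tot
}

#' Quartet topology counts of one gene tree around one branch
#'
#' Counts, among the quartets formed by taking one leaf from each of the four
#' clusters of the quadripartition, how many are resolved by the gene tree as
#' each of the three topologies: `c1` for AB|CD (the species-tree
#' resolution), `c2` for AC|BD, `c3` for AD|BC, together with `m`, the
#' number of quartets whose four leaves are all present in the gene tree.
#'
#' The counts are accumulated in a single post-order pass: every node stores
#' the size of its subtree's intersection with each cluster, every internal
#' node contributes its tripartition (for a polytomy of degree d, each of
#' the choose(d, 3) restricted tripartitions), and a 12-term product formula
#' scores each tripartition against each pairing. Every resolved quartet is
#' counted at exactly the two endpoints of its internal path, so the doubled
#' sum is halved; a parity failure raises an internal-consistency error.
#'
#' Gene trees may be multifurcating and may miss taxa; unresolved quartets
#' count toward `m` but toward no `c_j`, hence `c1 + c2 + c3 <= m` with
#' equality for binary gene trees containing all four-cluster taxa.
#'
#' @param gene_tree A `phylo` (any rooting; unrooted internally), or `NULL`.
#' @param quad A quadripartition as returned by [quadripartition_of_edge()].
#' @return Named numeric vector `c(c1, c2, c3, m)`.
#' @export
gene_tree_quartet_counts <- function(gene_tree, quad) {
  prof <- gene_tree_profile(gene_tree)
  quartet_counts_profile(prof, quad)
}

#' @keywords internal
quartet_counts_profile <- function(prof, quad) {
  zero <- c(c1 = 0, c2 = 0, c3 = 0, m = 0)
  if (is.null(prof)) return(zero)
  cls <- integer(length(prof$tip.label))
  for (j in 1:4) cls[prof$tip.label %in% quad[[j]]] <- j
  totals <- vapply(1:4, function(j) sum(cls == j), numeric(1))
  m_g <- prod(totals)
  if (m_g == 0) return(zero)
  cnt <- matrix(0, nrow = prof$nall, ncol = 4L)
  tips <- which(cls > 0L)
  cnt[cbind(tips, cls[tips])] <- 1
  ed <- prof$tree$edge
  for (k in seq_len(nrow(ed))) {
    cnt[ed[k, 1L], ] <- cnt[ed[k, 1L], ] + cnt[ed[k, 2L], ]
  }
  doubled <- c(0, 0, 0)
  for (u in (prof$ntip + 1L):prof$nall) {
    kk <- prof$kids[[u]]
    if (is.null(kk)) next
    V <- cnt[kk, , drop = FALSE]
    if (u != prof$root) V <- rbind(V, totals - cnt[u, ])
    d <- nrow(V)
    if (d < 3L) next
    triples <- utils::combn(d, 3L)
    for (t in seq_len(ncol(triples))) {
      V3 <- V[triples[, t], , drop = FALSE]
      doubled[1L] <- doubled[1L] + matching_sum(V3, 1L, 2L, 3L, 4L)
      doubled[2L] <- doubled[2L] + matching_sum(V3, 1L, 3L, 2L, 4L)
      doubled[3L] <- doubled[3L] + matching_sum(V3, 1L, 4L, 2L, 3L)
    }
  }
  if (any(doubled %% 2 != 0)) {
    stop("internal consistency error: odd doubled quartet count", call. = FALSE)
  }
  cj <- doubled / 2
  if (sum(cj) > m_g + 1e-9) {
    stop("internal consistency error: resolved quartets exceed present quartets",
         call. = FALSE)
  }
  c(c1 = cj[1L], c2 = cj[2L], c3 = cj[3L], m = m_g)
}

#' Brute-force quartet counts (enumeration oracle)
#'
#' Enumerates every quartet (a in A, b in B, c in C, d in D), classifies the
#' topology the gene tree induces on it via the four-point condition on
#' topological leaf-to-leaf distances, and tallies the three resolutions.
#' Intended for small instances; must agree exactly with
#' [gene_tree_quartet_counts()].
#'
#' @inheritParams gene_tree_quartet_counts
#' @return Named numeric vector `c(c1, c2, c3, m)`.
#' @export
brute_force_quartet_counts <- function(gene_tree, quad) {
  zero <- c(c1 = 0, c2 = 0, c3 = 0, m = 0)
  if (is.null(gene_tree) || length(gene_tree$tip.label) < 4L) return(zero)
  gt <- unroot_tree(gene_tree)
  gt$edge.length <- rep(1, nrow(gt$edge))
  ntip <- length(gt$tip.label)
  D <- ape::dist.nodes(gt)[seq_len(ntip), seq_len(ntip)]
  present <- lapply(quad, function(cl) which(gt$tip.label %in% cl))
  if (any(lengths(present) == 0L)) return(zero)
  cj <- c(0, 0, 0)
  m_g <- 0
  for (a in present[[1L]]) for (b in present[[2L]])
    for (cc in present[[3L]]) for (d in present[[4L]]) {
      m_g <- m_g + 1
      s <- c(D[a, b] + D[cc, d], D[a, cc] + D[b, d], D[a, d] + D[b, cc])
      top <- which(s == min(s))
      if (length(top) == 1L) cj[top] <- cj[top] + 1
    }
  c(c1 = cj[1L], c2 = cj[2L], c3 = cj[3L], m = m_g)
}

#' Averaged quartet support for one branch over a set of gene trees
#'
#' Aggregates per-gene quartet counts around one branch into the averaged
#' quartet frequencies `z = (z1, z2, z3)` used by the posterior model: only
#' genes containing at least one quartet around the branch ("effective"
#' genes) contribute; `m_bar` is the mean number of present quartets per
#' effective gene; and `z_j = sum_g c_j^g / m_bar`. The effective number of
#' multinomial trials `n` is `z1 + z2 + z3` by default (unresolved quartets
#' observe no outcome); `strict_n = TRUE` instead uses the number of
#' effective genes, which coincides with the default for binary gene trees.
#'
#' @param quad A quadripartition (see [quadripartition_of_edge()]).
#' @param gene_trees List of `phylo` objects (or precomputed profiles).
#' @param strict_n Logical; see above.
#' @return A list with `z` (length-3 numeric), `n` (effective gene count
#'   under the chosen rule), `n_genes` (genes with >= 1 present quartet),
#'   `m_bar`, `m_total` (product of the four cluster sizes) and `counts`
#'   (summed per-gene counts).
#' @export
quartet_support <- function(quad, gene_trees, strict_n = FALSE) {
  stopifnot(length(gene_trees) >= 1L)
  counts <- vapply(gene_trees, function(g) {
    if (is.list(g) && !inherits(g, "phylo")) quartet_counts_profile(g, quad)
    else gene_tree_quartet_counts(g, quad)
  }, numeric(4))
  eff <- counts[4L, ] >= 1
  m_total <- prod(lengths(quad))
  if (!any(eff)) {
    return(list(z = c(0, 0, 0), n = 0, n_genes = 0, m_bar = NA_real_,
                m_total = m_total, counts = c(0, 0, 0)))
  }
  m_bar <- mean(counts[4L, eff])
  csum <- rowSums(counts[1:3, eff, drop = FALSE])
  z <- csum / m_bar
  n <- if (strict_n) sum(eff) else sum(z)
  list(z = unname(z), n = n, n_genes = sum(eff), m_bar = m_bar,
       m_total = m_total, counts = unname(csum))
}
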