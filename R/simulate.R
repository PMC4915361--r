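#' Simulate a Yule species tree
#'
#' Forward pure-birth simulation: starting from two lineages at the root,
#' every lineage speciates at rate `lambda`, so with k extant lineages the
#' waiting time to the next speciation is exponential with rate `k * lambda`.
#' The process stops when `l` lineages exist and the tree is read off one
#' further (memoryless) waiting time later. Branch lengths are in
#' coalescent units, the time scale on which the quartet model operates.
#'
#' @param l Number of leaves (>= 4).
#' @param lambda Speciation rate per lineage per coalescent time unit.
#' @param clamp_internal Optional length-2 numeric `c(lo, hi)`: internal
#'   edge lengths are clamped into this range after simulation (useful for
#'   fixtures that need branches neither trivially short nor saturated).
#' @param seed Optional integer seed for reproducibility.
#' @return A rooted, binary `phylo` with `l` leaves labelled `t1..tl`.
#' @export
sim_yule_tree <- function(l, lambda = 0.5, clamp_internal = NULL, seed = NULL) {
  stopifnot(l >= 4, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  # node bookkeeping: 0 is the (virtual) root; others indexed as created
  parent <- c(0L, 0L)
  pend <- c(0, 0)
  active <- c(1L, 2L)
  nxt <- 3L
  while (length(active) < l) {
    k <- length(active)
    pend[active] <- pend[active] + stats::rexp(1, k * lambda)
    i <- active[sample.int(k, 1L)]
    parent[nxt] <- i; parent[nxt + 1L] <- i
    pend[nxt] <- 0; pend[nxt + 1L] <- 0
    active <- c(setdiff(active, i), nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  pend[active] <- pend[active] + stats::rexp(1, l * lambda)
  nnode_all <- nxt - 1L
  is_tip <- seq_len(nnode_all) %in% active
  num <- integer(nnode_all + 1L)           # +1 slot for virtual root id 0
  num[active + 1L] <- seq_len(l)
  internals <- which(!is_tip)
  num[1L] <- l + 1L                        # root
  num[internals + 1L] <- l + 1L + seq_along(internals)
  edge <- cbind(num[parent[seq_len(nnode_all)] + 1L], num[seq_len(nnode_all) + 1L])
  tr <- list(edge = edge,
             edge.length = pend[seq_len(nnode_all)],
             tip.label = paste0("t", seq_len(l)),
             Nnode = length(internals) + 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  if (!is.null(clamp_internal)) {
    stopifnot(length(clamp_internal) == 2L, clamp_internal[1L] <= clamp_internal[2L])
    ii <- internal_edges(tr)
    tr$edge.length[ii] <- pmin(pmax(tr$edge.length[ii], clamp_internal[1L]),
                               clamp_internal[2L])
  }
  tr
}

#' Simulate gene trees under the multi-species coalescent
#'
#' Standard coalescent-within-species-tree simulation with one sampled
#' lineage per species: gene lineages enter each species branch at its
#' child end; within a branch of length L (coalescent units) any pair of the
#' k present lineages coalesces at rate 1 per pair, so the waiting time is
#' exponential with rate k(k-1)/2; lineages not merged by the parent end
#' propagate upward, and coalescence above the root continues until a single
#' lineage remains. Gene trees are generated rooted and returned unrooted
#' (the representation scoring uses), with branch lengths recording
#' coalescent times.
#'
#' @param species_tree A rooted binary `phylo` with branch lengths in
#'   coalescent units (all present and non-negative).
#' @param n Number of independent gene trees.
#' @param seed Optional integer seed.
#' @return A list of `n` unrooted `phylo` objects on the species taxa.
#' @export
sim_msc_gene_trees <- function(species_tree, n, seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"), n >= 1)
  if (is.null(species_tree$edge.length) || anyNA(species_tree$edge.length)) {
    stop("species tree must have branch lengths in coalescent units", call. = FALSE)
  }
  if (any(species_tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sp <- ape::reorder.phylo(species_tree, "postorder")
  ntip <- length(sp$tip.label)
  nall <- ntip + sp$Nnode
  root <- setdiff(sp$edge[, 1L], sp$edge[, 2L])[1L]
  # distance of each node from the root (time coordinate, grows tipward)
  rd <- numeric(nall)
  co <- ape::reorder.phylo(sp, "cladewise")
  for (k in seq_len(nrow(co$edge))) {
    rd[co$edge[k, 2L]] <- rd[co$edge[k, 1L]] + co$edge.length[k]
  }
  blen <- numeric(nall)
  blen[sp$edge[, 2L]] <- sp$edge.length
  blen[root] <- Inf
  kids <- vector("list", nall)
  for (k in seq_len(nrow(sp$edge))) {
    kids[[sp$edge[k, 1L]]] <- c(kids[[sp$edge[k, 1L]]], sp$edge[k, 2L])
  }
  node_order <- c(unique(sp$edge[, 2L]), root)   # postorder: children first
  coalesce_branch <- function(lin, t0, L) {
    tcur <- t0
    floorc <- t0 - L
    while (length(lin) >= 2L) {
      k <- length(lin)
      w <- stats::rexp(1, k * (k - 1) / 2)
      if (tcur - w < floorc) break
      tcur <- tcur - w
      ij <- sample.int(k, 2L)
      a <- lin[[ij[1L]]]; b <- lin[[ij[2L]]]
      merged <- list(
        str = paste0("(", a$str, ":", a$t - tcur, ",", b$str, ":", b$t - tcur, ")"),
        t = tcur)
      lin <- c(lin[-ij], list(merged))
    }
    lin
  }
  sim_one <- function() {
    pool <- vector("list", nall)
    for (v in node_order) {
      lin <- if (v <= ntip) {
        list(list(str = sp$tip.label[v], t = rd[v]))
      } else {
        do.call(c, pool[kids[[v]]])
      }
      pool[kids[[v]]] <- list(NULL)
      pool[[v]] <- coalesce_branch(lin, rd[v], blen[v])
    }
    paste0(pool[[root]][[1L]]$str, ";")
  }
  strs <- vapply(seq_len(n), function(i) sim_one(), character(1))
  trees <- ape::read.tree(text = paste(strs, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, unroot_tree)
}

#' Add topological noise to gene trees
#'
#' Emulates gene-tree estimation error: each internal edge of each tree is,
#' independently with probability `rate`, re-resolved uniformly at random
#' among the three possible local arrangements of the four subtrees around
#' it (so a perturbed edge keeps its original resolution with probability
#' 1/3 and takes each nearest-neighbor-interchange alternative with
#' probability 1/3). Leaf sets are preserved; branch lengths travel with
#' their subtrees and are not otherwise adjusted.
#'
#' @param trees List of binary `phylo` objects.
#' @param rate Per-edge perturbation probability in [0, 1].
#' @param seed Optional integer seed.
#' @return List of `phylo` objects.
#' @export
perturb_gene_trees <- function(trees, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(trees, function(tr) {
    if (is.null(tr)) return(NULL)
    if (rate == 0) return(tr)
    tr <- unroot_tree(tr)
    ie <- internal_edges(tr)
    for (e in ie) {
      if (stats::runif(1) >= rate) next
      pick <- sample.int(3L, 1L)
      if (pick == 1L) next
      u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
      vrows <- which(tr$edge[, 1L] == v)
      urows <- setdiff(which(tr$edge[, 1L] == u), e)
      if (length(vrows) != 2L || length(urows) < 1L) next
      swap <- if (length(urows) == 1L) {
        c(vrows[pick - 1L], urows[1L])
      } else {
        c(vrows[1L], urows[pick - 1L])
      }
      tr$edge[swap[1L], 1L] <- u
      tr$edge[swap[2L], 1L] <- v
    }
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Randomly delete taxa from gene trees
#'
#' Each leaf of each tree is removed independently with probability `p`
#' (degree-2 nodes suppressed), emulating missing data. Trees reduced below
#' two leaves cannot be represented and are returned as `NULL`; trees with
#' fewer than four leaves are retained but carry no quartet information.
#'
#' @param trees List of `phylo` objects.
#' @param p Per-leaf deletion probability in [0, 1].
#' @param seed Optional integer seed.
#' @return List of `phylo` objects (with `NULL` for emptied trees).
#' @export
delete_taxa <- function(trees, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(trees, function(tr) {
    if (is.null(tr) || p == 0) return(tr)
    ntip <- length(tr$tip.label)
    keep <- which(stats::runif(ntip) >= p)
    if (length(keep) == ntip) return(tr)
    if (length(keep) < 2L) return(NULL)
    ape::collapse.singles(ape::keep.tip(tr, keep))
  })
}
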