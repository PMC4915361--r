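# Shared fixture builders: random trees of various shapes, all generated in
# code under the seed of the calling test.

# random unrooted binary tree on taxa "1".."l" with unit branch lengths
random_binary_tree <- function(l) {
  tr <- ape::rtree(l, tip.label = as.character(seq_len(l)))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$node.label <- NULL
  unroot_tree(tr)
}

# contract each internal edge independently with probability p
random_multifurcate <- function(tr, p) {
  ie <- internal_edges(tr)
  drop <- ie[stats::runif(length(ie)) < p]
  if (length(drop)) quartetpp:::contract_edges(tr, drop) else tr
}

# all (branch, gene tree) quartet-count pairs for a species/gene tree set,
# via both the traversal algorithm and the enumeration oracle
count_both_ways <- function(species_tree, gene_trees) {
  spu <- unroot_tree(species_tree)
  out <- list()
  for (e in internal_edges(spu)) {
    q <- quadripartition_of_edge(spu, e)
    for (g in gene_trees) {
      out[[length(out) + 1L]] <- list(
        fast = gene_tree_quartet_counts(g, q),
        slow = brute_force_quartet_counts(g, q))
    }
  }
  out
}

# bipartition signature set of an unrooted tree (order/rooting independent);
# each split is represented by the side not containing the first taxon
bipartition_signatures <- function(tr) {
  tr <- unroot_tree(tr)
  taxa <- sort(tr$tip.label)
  sigs <- vapply(internal_bipartitions(tr)$cluster, function(cl) {
    a <- sort(cl)
    if (taxa[1] %in% a) a <- setdiff(taxa, a)
    paste(a, collapse = ",")
  }, character(1))
  sort(sigs)
}

# does the tree contain the split separating `cluster` from the rest?
has_split <- function(tr, cluster) {
  tr <- unroot_tree(tr)
  taxa <- sort(tr$tip.label)
  a <- sort(cluster)
  if (taxa[1] %in% a) a <- setdiff(taxa, a)
  paste(a, collapse = ",") %in% bipartition_signatures(tr)
}
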