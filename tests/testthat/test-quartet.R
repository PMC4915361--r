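test_that("quadripartition of an edge exposes the four surrounding subtrees", {
  sp <- unroot_tree(parse_newick("((1,2),(3,4));"))
  q <- quadripartition_of_edge(sp, internal_edges(sp)[1])
  expect_equal(lengths(q), c(A = 1L, B = 1L, C = 1L, D = 1L))
  expect_setequal(unlist(q), as.character(1:4))
  # sides are {1},{2} vs {3},{4}
  expect_setequal(c(q$A, q$B), c("1", "2"))
  expect_setequal(c(q$C, q$D), c("3", "4"))

  sp2 <- unroot_tree(parse_newick("((1,2),((3,4),(5,6)));"))
  # edge separating {1,2} from {3,4},{5,6}
  found <- FALSE
  for (e in internal_edges(sp2)) {
    q2 <- quadripartition_of_edge(sp2, e)
    sz <- sort(lengths(q2))
    if (identical(unname(sz), c(1L, 1L, 2L, 2L))) {
      found <- TRUE
      expect_equal(prod(lengths(q2)), 4)  # m_total
    }
  }
  expect_true(found)

  # 5-taxon caterpillar: two internal edges, m_total = product of sizes
  sp3 <- unroot_tree(parse_newick("((((1,2),3),4),5);"))
  ie <- internal_edges(sp3)
  expect_length(ie, 2L)
  for (e in ie) {
    q3 <- quadripartition_of_edge(sp3, e)
    expect_equal(prod(lengths(q3)), prod(sort(lengths(q3))))
    expect_setequal(unlist(q3), as.character(1:5))
  }

  # polytomy endpoint is unscorable
  star <- parse_newick("((1,2),3,4,(5,6));")
  inner <- internal_edges(star)
  expect_error(quadripartition_of_edge(star, inner[1]), "polytomy")
})

test_that("single-gene-tree counts match hand enumeration on the basic cases", {
  sp <- unroot_tree(parse_newick("((1,2),(3,4));"))
  q <- quadripartition_of_edge(sp, internal_edges(sp)[1])
  expect_equal(gene_tree_quartet_counts(parse_newick("((1,2),(3,4));"), q),
               c(c1 = 1, c2 = 0, c3 = 0, m = 1))
  expect_equal(gene_tree_quartet_counts(parse_newick("((1,3),(2,4));"), q),
               c(c1 = 0, c2 = 1, c3 = 0, m = 1))
  expect_equal(gene_tree_quartet_counts(parse_newick("(1,2,3,4);"), q),
               c(c1 = 0, c2 = 0, c3 = 0, m = 1))
  # missing taxon: cluster C = {3,5}, gene tree lacks 5
  q5 <- list(A = "1", B = "2", C = c("3", "5"), D = "4")
  expect_equal(gene_tree_quartet_counts(parse_newick("((1,2),(3,4));"), q5),
               c(c1 = 1, c2 = 0, c3 = 0, m = 1))
  # gene tree below 4 leaves carries nothing
  expect_equal(gene_tree_quartet_counts(parse_newick("((1,2),3);"), q),
               c(c1 = 0, c2 = 0, c3 = 0, m = 0))
})

test_that("permuting the quadripartition pairing permutes the counts", {
  set.seed(4)
  for (i in 1:10) {
    g <- random_binary_tree(8)
    q <- list(A = c("1", "2"), B = c("3"), C = c("4", "5"), D = c("6", "7", "8"))
    base <- gene_tree_quartet_counts(g, q)
    q2 <- list(A = q$A, B = q$C, C = q$B, D = q$D)  # pair A with C
    alt <- gene_tree_quartet_counts(g, q2)
    expect_equal(unname(alt[c(2, 1, 3)]), unname(base[1:3]))
    expect_equal(alt[["m"]], base[["m"]])
  }
})

test_that("counts are conserved: sum equals m for binary complete trees, never exceeds m", {
  set.seed(5)
  for (i in 1:10) {
    sp <- random_binary_tree(7)
    g <- random_binary_tree(7)
    gm <- random_multifurcate(g, 0.5)
    for (e in internal_edges(sp)) {
      q <- quadripartition_of_edge(sp, e)
      cb <- gene_tree_quartet_counts(g, q)
      expect_equal(sum(cb[1:3]), cb[["m"]])
      cm <- gene_tree_quartet_counts(gm, q)
      expect_lte(sum(cm[1:3]), cm[["m"]])
    }
  }
})

test_that("traversal counting equals brute-force enumeration on random instances", {
  set.seed(6)
  n_instances <- 0
  for (rep in 1:6) {
    l <- sample(5:9, 1)
    sp <- random_binary_tree(l)
    gts <- replicate(8, random_binary_tree(l), simplify = FALSE)
    gts <- lapply(gts, random_multifurcate, p = 0.3)
    gts <- delete_taxa(gts, 0.2)
    pairs <- count_both_ways(sp, gts)
    for (p in pairs) expect_identical(p$fast, p$slow)
    n_instances <- n_instances + length(pairs)
  }
  expect_gte(n_instances, 100)
})

test_that("quartet_support averages per-gene counts with missing-data rules", {
  sp <- unroot_tree(parse_newick("((1,2),(3,4));"))
  q <- quadripartition_of_edge(sp, internal_edges(sp)[1])
  g1 <- parse_newick("((1,2),(3,4));")
  g2 <- parse_newick("((1,3),(2,4));")
  g3 <- parse_newick("((1,4),(2,3));")

  qs <- quartet_support(q, rep(list(g1), 10))
  expect_equal(qs$z, c(10, 0, 0))
  expect_equal(qs$n, 10)
  expect_equal(qs$m_bar, 1)

  qs2 <- quartet_support(q, list(g1, g1, g2, g3))
  expect_equal(qs2$z, c(2, 1, 1))
  expect_equal(qs2$n, 4)

  # a gene missing cluster D entirely is excluded from n and m_bar
  g_no4 <- parse_newick("((1,2),(3,5));")
  q5 <- list(A = "1", B = "2", C = "3", D = "4")
  qs3 <- quartet_support(q5, list(g1, g_no4))
  expect_equal(qs3$n_genes, 1)
  expect_equal(qs3$z, c(1, 0, 0))

  # no informative gene at all: flagged zero-signal record
  qs4 <- quartet_support(q5, list(g_no4))
  expect_equal(qs4$n, 0)
  expect_true(is.na(qs4$m_bar))

  # strict mode counts genes, not resolved quartets
  star <- parse_newick("(1,2,3,4);")
  qs5 <- quartet_support(q, list(g1, star))
  expect_equal(qs5$n, 1)       # star contributes no resolved quartet
  qs6 <- quartet_support(q, list(g1, star), strict_n = TRUE)
  expect_equal(qs6$n, 2)       # but does contain a present quartet
})

test_that("averaged frequencies never exceed the effective trial count", {
  set.seed(7)
  for (i in 1:5) {
    sp <- random_binary_tree(8)
    gts <- replicate(12, random_multifurcate(random_binary_tree(8), 0.4),
                     simplify = FALSE)
    gts <- delete_taxa(gts, 0.25)
    for (e in internal_edges(sp)) {
      q <- quadripartition_of_edge(sp, e)
      qs <- quartet_support(q, gts)
      expect_lte(sum(qs$z), qs$n_genes + 1e-9)
      expect_true(all(qs$z >= 0))
      if (qs$n_genes > 0) expect_lte(qs$m_bar, qs$m_total)
    }
  }
})
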