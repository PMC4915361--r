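test_that("scoring a quartet tree against clean and tied gene trees", {
  sp <- parse_newick("((1,2),(3,4));")
  g1 <- parse_newick("((1,2),(3,4));")
  res <- score_tree(sp, rep(list(g1), 10))
  ann <- res$annotations
  expect_equal(nrow(ann), 1L)
  expect_equal(c(ann$f1, ann$f2, ann$f3), c(1, 0, 0))
  # closed-form check at z = (10, 0, 0), n = 10, lambda = 1/2
  expected <- local_pp(c(10, 0, 0), 10)
  expect_equal(c(ann$pp1, ann$pp2, ann$pp3), expected)
  expect_gt(ann$pp1, 0.99)

  g2 <- parse_newick("((1,3),(2,4));")
  g3 <- parse_newick("((1,4),(2,3));")
  tie <- c(rep(list(g1), 4), rep(list(g2), 4), rep(list(g3), 4))
  res2 <- score_tree(sp, tie)
  expect_equal(unlist(res2$annotations[, c("pp1", "pp2", "pp3")]),
               c(pp1 = 1, pp2 = 1, pp3 = 1) / 3)
  expect_equal(res2$annotations$ml, 0)
  expect_equal(res2$annotations$map, 0)
})

test_that("annotation table has one row per internal branch with stable columns", {
  set.seed(9)
  sp <- sim_yule_tree(9, 0.5)
  gts <- sim_msc_gene_trees(sp, 25)
  res <- score_tree(sp, gts)
  expect_equal(nrow(res$annotations), 9 - 3)
  expect_true(all(c("branch", "z1", "z2", "z3", "n", "f1", "pp1", "pp2",
                    "pp3", "ml", "map") %in% names(res$annotations)))
  tf <- tempfile(fileext = ".tsv")
  annotation_table(res$annotations, tf)
  back <- utils::read.delim(tf)
  expect_equal(back$pp1, res$annotations$pp1, tolerance = 1e-12)
})

test_that("branches with no informative gene are annotated NA, not pp = 1/3", {
  sp <- parse_newick("(((1,2),(3,4)),(5,6));")
  # no gene tree contains taxon 6, so the branch whose quadripartition
  # separates 5 from 6 can never see a complete quartet
  g_a <- parse_newick("((1,2),(3,4));")
  g_b <- parse_newick("((1,2),(5,3));")
  res <- score_tree(sp, list(g_a, g_a, g_b))
  ann <- res$annotations
  expect_true(any(is.na(ann$pp1)))
  expect_true(any(!is.na(ann$pp1)))
  expect_true(all(is.na(ann$ml[is.na(ann$pp1)])))
})

test_that("scoring is invariant to gene order and to rerooting, and never edits the topology", {
  set.seed(10)
  sp <- sim_yule_tree(8, 0.5)
  gts <- sim_msc_gene_trees(sp, 40)
  res <- score_tree(sp, gts)
  expect_identical(bipartition_signatures(res$tree), bipartition_signatures(sp))

  res_shuf <- score_tree(sp, rev(gts))
  key <- function(r) r$annotations[order(r$annotations$z1), c("z1", "z2", "z3", "pp1", "ml")]
  expect_equal(key(res_shuf), key(res), ignore_attr = TRUE)

  sp_reroot <- ape::root(unroot_tree(sp), outgroup = "t3", resolve.root = TRUE)
  gts_reroot <- lapply(gts, function(g) ape::root(g, outgroup = "t3", resolve.root = TRUE))
  res_r <- score_tree(sp_reroot, gts_reroot)
  expect_equal(key(res_r), key(res), ignore_attr = TRUE)
})

test_that("input validation: polytomies, unknown taxa and empty inputs are rejected", {
  poly <- parse_newick("((1,2),3,4,(5,6));")
  g <- parse_newick("((1,2),(3,4));")
  expect_error(score_tree(poly, list(g)), "polytom")
  sp <- parse_newick("((1,2),(3,4));")
  alien <- parse_newick("((1,2),(3,99));")
  expect_error(score_tree(sp, list(alien)), "absent")
  res <- score_tree(sp, list(alien, g), config = score_config(prune_extra = TRUE))
  expect_equal(res$annotations$n, 1)  # alien tree pruned below 4 taxa
  expect_error(score_tree(sp, list()), "no gene trees")
})

test_that("annotation modes control what the newick output carries", {
  sp <- parse_newick("((1,2),(3,4));")
  g <- parse_newick("((1,2),(3,4));")
  gts <- rep(list(g), 8)
  nw_pp <- write_newick(score_tree(sp, gts, score_config(annotation = "pp"))$tree)
  lab <- as.numeric(sub(".*\\)([0-9.]+)\\).*", "\\1", nw_pp))
  expect_true(lab >= 0 && lab <= 1)
  nw_full <- write_newick(score_tree(sp, gts, score_config(annotation = "full"))$tree)
  expect_match(nw_full, "pp1=")
  expect_match(nw_full, "z3=")
  expect_match(nw_full, "\\[&")
})

test_that("gene-tree collapsing is applied before scoring when configured", {
  sp <- parse_newick("((1,2),(3,4));")
  # strongly supported wrong topology vs weakly supported right one
  g_weak <- parse_newick("((1:1,2:1)10:1,(3:1,4:1)20:1);")
  g_alt <- parse_newick("((1,3)90,(2,4));")
  cfg <- score_config(collapse = 33)
  res <- score_tree(sp, list(g_weak, g_weak, g_weak, g_alt), cfg)
  # the three collapsed copies become stars: only the alternative counts
  expect_equal(res$annotations$z2, 1)
  expect_equal(res$annotations$z1, 0)
})
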