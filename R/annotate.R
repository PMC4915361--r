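#' Scoring configuration
#'
#' @param lambda Yule prior rate for branch lengths in coalescent units;
#'   1/2 gives the flat prior on the dominant topology probability.
#' @param annotation What [score_tree()] writes on internal edges: `"pp"`
#'   (posterior of the tree's own resolution as node label), `"len"`
#'   (estimated coalescent length), `"both"`, or `"full"` (label, length and
#'   a bracketed comment carrying the complete per-branch record).
#' @param collapse Optional support threshold: gene-tree branches with
#'   support strictly below it are contracted before scoring (percentage and
#'   probability scales auto-detected). `NULL` disables collapsing.
#' @param strict_n Use the literal effective-gene-count rule for the number
#'   of multinomial trials rather than `z1 + z2 + z3`; see
#'   [quartet_support()].
#' @param length_cap Finite stand-in for infinite length estimates.
#' @param length_type Which estimate is written as the edge length,
#'   `"ml"` or `"map"`.
#' @param prune_extra Prune gene-tree taxa absent from the species tree
#'   instead of raising an error.
#' @return A list of class `score_config`.
#' @export
score_config <- function(lambda = 0.5,
                         annotation = c("pp", "len", "both", "full"),
                         collapse = NULL,
                         strict_n = FALSE,
                         length_cap = 10,
                         length_type = c("ml", "map"),
                         prune_extra = FALSE) {
  stopifnot(lambda > 0, length_cap > 0)
  structure(list(lambda = lambda,
                 annotation = match.arg(annotation),
                 collapse = collapse,
                 strict_n = strict_n,
                 length_cap = length_cap,
                 length_type = match.arg(length_type),
                 prune_extra = prune_extra),
            class = "score_config")
}

#' Score every internal branch of a species tree against gene trees
#'
#' The end-to-end pipeline: for each internal branch of the (unrooted,
#' binary) species tree, averaged quartet frequencies for the three possible
#' resolutions are gathered from the gene trees, converted into local
#' posterior probabilities under the Yule prior, and into ML/MAP branch
#' lengths in coalescent units. The input topology is never altered; only
#' annotations are attached. Gene trees may be multifurcating and may miss
#' taxa; branches no gene tree informs are annotated `NA`.
#'
#' @param species_tree A `phylo`, binary once unrooted, >= 4 leaves.
#' @param gene_trees A list of `phylo` objects (or a `multiPhylo`).
#' @param config A [score_config()].
#' @return A list with `tree` (the annotated `phylo`) and `annotations`
#'   (a data frame, one row per internal branch; see [annotation_table()]).
#' @export
score_tree <- function(species_tree, gene_trees, config = score_config()) {
  stopifnot(inherits(species_tree, "phylo"))
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  gene_trees <- unclass(gene_trees)
  if (length(gene_trees) == 0L) stop("no gene trees supplied", call. = FALSE)
  sp <- unroot_tree(species_tree)
  taxa <- sp$tip.label
  if (length(taxa) < 4L) stop("species tree must have >= 4 leaves", call. = FALSE)
  if (!ape::is.binary(sp)) {
    stop("species tree has unscorable polytomies; resolve it before scoring",
         call. = FALSE)
  }
  gene_trees <- lapply(gene_trees, function(g) {
    if (is.null(g)) return(NULL)
    extra <- setdiff(g$tip.label, taxa)
    if (length(extra)) {
      if (!config$prune_extra) {
        stop("gene-tree taxa absent from species tree: ",
             paste(utils::head(extra, 5L), collapse = ", "),
             " (set prune_extra = TRUE to drop them)", call. = FALSE)
      }
      keep <- setdiff(g$tip.label, extra)
      if (length(keep) < 2L) return(NULL)
      g <- ape::keep.tip(g, keep)
    }
    if (!is.null(config$collapse)) g <- collapse_low_support(g, config$collapse)
    g
  })
  profiles <- lapply(gene_trees, gene_tree_profile)
  ie <- internal_edges(sp)
  rows <- vector("list", length(ie))
  nlab <- rep("", sp$Nnode)
  comments <- rep(NA_character_, length(taxa) + sp$Nnode)
  elen <- rep(NA_real_, nrow(sp$edge))
  ntip <- length(taxa)
  for (i in seq_along(ie)) {
    e <- ie[i]
    quad <- quadripartition_of_edge(sp, e)
    qs <- quartet_support(quad, profiles, strict_n = config$strict_n)
    pp <- local_pp(qs$z, qs$n, config$lambda)
    len <- branch_length_estimates(qs$z[1L], qs$n, config$lambda,
                                   cap = config$length_cap)
    f <- if (qs$n > 0) qs$z / qs$n else c(NA_real_, NA_real_, NA_real_)
    child <- sp$edge[e, 2L]
    rows[[i]] <- data.frame(
      branch = i, node = child,
      sizeA = length(quad$A), sizeB = length(quad$B),
      sizeC = length(quad$C), sizeD = length(quad$D),
      z1 = qs$z[1L], z2 = qs$z[2L], z3 = qs$z[3L],
      n = qs$n, n_genes = qs$n_genes, m_bar = qs$m_bar,
      f1 = f[1L], f2 = f[2L], f3 = f[3L],
      pp1 = pp[1L], pp2 = pp[2L], pp3 = pp[3L],
      ml = len$ml, map = len$map, capped = len$capped
    )
    if (config$annotation %in% c("pp", "both", "full")) {
      nlab[child - ntip] <- if (is.na(pp[1L])) "NA" else sprintf("%.4f", pp[1L])
    }
    if (config$annotation %in% c("len", "both", "full")) {
      elen[e] <- if (config$length_type == "ml") len$ml else len$map
    }
    if (config$annotation == "full") {
      comments[child] <- sprintf(
        "[&pp1=%.6g,pp2=%.6g,pp3=%.6g,z1=%.6g,z2=%.6g,z3=%.6g,n=%.6g,ml=%.6g,map=%.6g]",
        pp[1L], pp[2L], pp[3L], qs$z[1L], qs$z[2L], qs$z[3L], qs$n,
        len$ml, len$map)
    }
  }
  ann <- do.call(rbind, rows)
  out <- sp
  if (config$annotation != "len") out$node.label <- nlab
  out$edge.length <- elen
  if (config$annotation == "full") attr(out, "node.comment") <- comments
  list(tree = out, annotations = ann)
}

#' Per-branch annotation table
#'
#' Returns (or writes) the tab-separated per-branch record produced by
#' [score_tree()]: branch id, the four cluster sizes, averaged quartet
#' frequencies `z1..z3`, effective gene count `n`, normalized frequencies
#' `f1..f3`, the three local posterior probabilities `pp1..pp3`, and the
#' ML/MAP coalescent branch lengths. Branches without signal carry `NA`.
#'
#' @param annotations The `annotations` data frame from [score_tree()].
#' @param file Optional path to write a TSV; `NULL` returns the data frame.
#' @return The data frame, invisibly when writing.
#' @export
annotation_table <- function(annotations, file = NULL) {
  stopifnot(is.data.frame(annotations))
  if (!is.null(file)) {
    utils::write.table(annotations, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(annotations))
  }
  annotations
}
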