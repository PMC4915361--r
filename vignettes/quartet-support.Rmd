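---
title: "Quartet-based branch support and coalescent branch lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet-based branch support and coalescent branch lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetpp)
```

## The problem

Gene trees estimated from different loci routinely disagree with each other
and with the species tree, and under incomplete lineage sorting they are
*expected* to: the multi-species coalescent (MSC) predicts discordance as a
function of branch lengths measured in coalescent units (generations divided
by effective population size). Bootstrap-style support on a species tree
ignores this expectation. `quartetpp` instead asks, for every internal
branch of a given species tree: *given how often the gene trees take each
side, what is the posterior probability that this branch is correct, and how
long is it in coalescent units?*

## The model

An internal branch of an unrooted binary species tree defines a
quadripartition: four leaf clusters A, B | C, D, the subtrees hanging off
the branch's two endpoints. Picking one leaf from each cluster gives a
quartet with three possible unrooted topologies; the branch's own resolution
is AB|CD. Under the MSC, a quartet around a branch of length d coalescent
units shows the matching topology with probability

θ = 1 − (2/3) e^(−d),

and each alternative with probability (1 − θ)/2. For each branch we collect
from the n gene trees the averaged quartet frequencies z = (z1, z2, z3): per
gene, the number of quartets around the branch resolved as each topology,
divided by the average number of quartets present per informative gene
(so that with complete binary gene trees z1 + z2 + z3 = n).

Treating z as multinomial counts with the *locality* assumption — the four
clusters are taken as correct and only the branch joining them is in
question — and putting a Yule prior with rate λ on branch lengths (which
induces the density λ(3(1 − t)/2)^(2λ−1) on θ over [1/3, 1]; λ = 1/2 is
flat), the posterior that the branch is correct has the closed form

pp_j ∝ 2^(z_j) · h(z_j),   h(x) = B(x + 1, n − x + 2λ) · (1 − I_{1/3}(x + 1, n − x + 2λ)),

with B the beta function and I the regularized incomplete beta
(`local_pp()`). The maximum-likelihood branch length is
−ln(3/2 · (1 − z1/n)) when z1 ≥ n/3 and 0 otherwise; the MAP estimate under
the same prior replaces n by n + 2λ (`branch_length_estimates()`).

## Counting quartets efficiently

Enumerating all quartets around a branch is infeasible beyond toy sizes, so
`gene_tree_quartet_counts()` uses a single post-order pass per gene tree:
every node stores the sizes of its subtree's intersection with A, B, C and
D; every internal node contributes its tripartition (three leaf clusters
around the node); and the number of quartets a tripartition resolves as a
given topology is the sum over the 12 matchings between quadripartition and
tripartition of a product of four intersection sizes. Each resolved quartet
is seen at exactly the two endpoints of its internal path, so the total is
halved — and the halving is asserted to be exact, turning a whole class of
counting bugs into hard errors. Work per branch is linear in the total size
of the gene trees; scoring all l − 3 branches is Θ(l²n).

Two rules govern incomplete signal:

* **Missing taxa.** A gene contributes to a branch only if at least one
  quartet around it has all four leaves present ("effective" genes); `m_bar`
  is the mean number of present quartets over those genes.
* **Polytomies.** A gene-tree polytomy of degree d is scored over its
  choose(d, 3) restricted tripartitions; quartets whose four lineages all
  meet at one node resolve nothing, so c1 + c2 + c3 ≤ m, with equality for
  binary genes.

The package carries an independent oracle, `brute_force_quartet_counts()`,
which enumerates every quartet and classifies it by the four-point condition
on topological leaf distances. The test suite requires bit-exact agreement
between the two routes on hundreds of randomized binary, multifurcating and
taxon-depleted instances.

## Effective number of trials

When gene trees contain polytomies, counting every informative gene as one
multinomial trial would claim more trials than observed outcomes. The
default therefore sets n = z1 + z2 + z3, which equals the informative-gene
count whenever the genes are binary and shrinks gracefully with unresolved
mass; `strict_n = TRUE` restores the literal count of genes containing at
least one present quartet. Branches with no informative gene at all are
annotated `NA` rather than pp = 1/3: no data is not the same as a
three-way tie.

## Numerical choices

* All posterior arithmetic is in log space: pp_j is computed as
  exp(z_j ln 2 + log h(z_j) − logsumexp), since 2^(z2 − z1) overflows for
  realistic gene counts.
* The complement 1 − I_{1/3}(a, b) is evaluated as I_{2/3}(b, a)
  (`pbeta(2/3, b, a, log.p = TRUE)`), avoiding catastrophic cancellation
  when the incomplete beta is near 1.
* Averaged frequencies are generally fractional under missing data, so
  h uses the gamma continuation throughout; no integer assumptions are made.
* z1 = n gives an infinite length estimate; it is reported capped (default
  10 coalescent units, configurable) with a `capped` flag, because
  downstream newick consumers reject `inf`.
* `local_pp_numeric()` is a quadrature oracle for the closed form: it
  integrates t^(z_j) ((1 − t)/2)^(n − z_j) against the Yule density on
  [1/3, 1] on a common log scale. The two routes agree to 1e−6 across a
  grid of proportions, n ∈ {3, 10, 50, 500} and λ ∈ {0.25, 0.5, 2}.
* The alternative resolutions are ordered by a canonical rule (each side's
  clusters sorted by smallest taxon index, the side containing the first
  taxon first), so pp2/pp3 labels are reproducible across runs and
  rerootings; component 1 is always the species tree's own resolution.

## The simulator, and what it does and does not emulate

`sim_yule_tree()` grows a species tree by a forward pure-birth process
(waiting times exponential with rate kλ for k extant lineages, read off one
further memoryless waiting time after reaching l leaves), matching the prior
the posterior assumes. `sim_msc_gene_trees()` runs the standard
coalescent-within-branches simulation, one sampled lineage per species,
pairwise coalescence rate 1 in coalescent units, free coalescence above the
root. `perturb_gene_trees()` emulates gene-tree estimation error by
re-resolving each internal edge, with a configurable probability, uniformly
among the three local arrangements of the four surrounding subtrees — a
perturbed edge keeps its resolution with probability 1/3. `delete_taxa()`
removes each leaf independently.

These fixtures validate the mathematics and the counting machinery, and
calibration tests confirm the simulator reproduces θ(d) to within binomial
error. They do **not** emulate several features of real data: gene-tree
error is not i.i.d. NNI noise (real estimation error concentrates on short
branches and varies with alignment length), missing data is not missing at
random, and discordance sources other than lineage sorting (paralogy,
transfer, recombination within loci) are absent. Passing the simulation
tests therefore demonstrates correctness of the method, not robustness of
the model on any particular empirical dataset.

Fixture sizes used by the test suite — 8–10 taxa, up to 2,000 genes for the
recovery check and 10,000 for simulator calibration — were chosen as the
smallest scales at which the stochastic checks have comfortable power; the
recovery fixture clamps internal branches into [0.3, 2] coalescent units so
that no branch is either trivially short or saturated.

## Design decisions in the open

* **Support scales.** Gene-tree support labels and collapse thresholds mix
  percentage and probability conventions in the wild; values in [0, 1] are
  read as probabilities and in (1, 100] as percentages, and the common
  practice of collapsing branches below 33% support is exposed as
  `score_config(collapse = 33)`.
* **Unknown lengths stay unknown.** Absent edge lengths are `NA`, never 0 —
  zero is a meaningful coalescent length. Terminal branches are never
  assigned MSC lengths (a single lineage per species carries no coalescence
  information about them).
* **Foreign taxa are an error.** Gene-tree taxa missing from the species
  tree abort scoring unless `prune_extra = TRUE`; silent pruning hides
  input mismatches.
* **λ is fixed per run** (default 1/2), not estimated; alternative priors
  are out of scope.
* **Noise model.** A strict nearest-neighbor interchange never returns the
  original resolution, which makes "perturbation probability" and "change
  probability" coincide and both saturate; the uniform re-resolution used
  here keeps the per-edge perturbation probability interpretable (a
  saturated 4-taxon tree changes topology 2/3 of the time) and makes
  topological distance increase smoothly with the rate.

## Limitations

Single alleles per species only; no weighting of quartets by gene-tree
branch support; the locality assumption means a branch's posterior is
conditional on its surrounding clusters being correct, so support values on
a badly wrong backbone are not globally interpretable; and the posterior
model treats the averaged frequencies as exact multinomial counts, ignoring
gene-tree estimation noise — with noisy gene trees, branch lengths are
systematically underestimated (a property the test suite checks
directionally).
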