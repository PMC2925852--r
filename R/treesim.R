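# Guide-tree generation: ultrametric birth-death trees and the
# formula-defined non-clock tree.  Trees are ape "phylo" objects with branch
# lengths in expected substitutions per site.

#' Simulate an ultrametric birth-death tree with a fixed number of tips
#'
#' Draws a rooted, ultrametric, binary tree conditioned on the number of
#' extant tips, using the birth-death sampler of [ape::rphylo()].  Defaults
#' match the study conditions: speciation rate 0.1, extinction rate 0.1,
#' complete sampling.  Sampling fractions below 1 are approximated by
#' simulating `ntaxa / sampling` tips and keeping a uniform subsample.
#'
#' @param ntaxa Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates.
#' @param sampling Sampling fraction in (0, 1].
#' @param seed Optional integer seed; the same seed gives an identical tree.
#' @return A rooted ultrametric `phylo` with tips labelled `t1..tN`.
#' @examples
#' tr <- simulate_birth_death_tree(30, seed = 1)
#' @export
simulate_birth_death_tree <- function(ntaxa, birth = 0.1, death = 0.1,
                                      sampling = 1, seed = NULL) {
  stopifnot(ntaxa >= 2, birth >= 0, death >= 0, sampling > 0, sampling <= 1)
  draw <- function() {
    n0 <- max(ntaxa, ceiling(ntaxa / sampling))
    tr <- ape::rphylo(n0, birth = birth, death = death, fossils = FALSE)
    if (n0 > ntaxa) {
      keep <- sample(tr$tip.label, ntaxa)
      tr <- ape::keep.tip(tr, keep)
    }
    tr$tip.label <- paste0("t", seq_len(ntaxa))
    tr
  }
  tr <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  stopifnot(ape::Ntip(tr) == ntaxa)
  tr
}

#' Height of an ultrametric tree
#'
#' Root-to-tip path length; errors if the tree is not ultrametric within
#' `tol` (relative).
#'
#' @param tree A rooted `phylo`.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return The common root-to-tip distance.
#' @export
tree_height <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h > 0 && diff(range(depths)) > tol * h) {
    stop("tree is not ultrametric", call. = FALSE)
  }
  h
}

#' Rescale an ultrametric tree to a target height
#'
#' Multiplies every branch length by a single factor so that the
#' root-to-tip distance equals `height` (in expected substitutions per
#' site).  Topology and relative branch proportions are preserved.
#'
#' @param tree A rooted ultrametric `phylo` with positive height.
#' @param height Target height.
#' @return The rescaled `phylo`.
#' @export
scale_to_height <- function(tree, height) {
  stopifnot(height > 0)
  h <- tree_height(tree)
  if (h <= 0) stop("cannot scale a zero-height tree", call. = FALSE)
  tree$edge.length <- tree$edge.length * (height / h)
  tree
}

#' Build the formula-defined non-clock tree
#'
#' Takes (or draws) an unrooted binary 22-taxon topology and assigns branch
#' lengths by label: internal branches receive a random permutation of the
#' labels x = 0..18 and lengths `10^(2x/18 - 3)`; external branches a
#' random permutation of x = 0..21 and lengths `10^(2x/21 - 3)`.  Branch
#' lengths therefore span 0.001 to 0.1 on a log scale, mixing very short
#' and long branches in a non-clock arrangement.
#'
#' @param topology Optional unrooted binary `phylo` with 22 tips and
#'   19 internal edges.  When `NULL`, a topology is drawn from the
#'   birth-death sampler (branch lengths discarded).
#' @param seed Optional integer seed controlling both the topology draw
#'   and the label permutations.
#' @return An unrooted `phylo` with 41 edges; not ultrametric.
#' @export
build_nonclock_tree <- function(topology = NULL, seed = NULL) {
  build <- function() {
    tr <- topology
    if (is.null(tr)) {
      tr <- ape::unroot(simulate_birth_death_tree(22))
    }
    if (ape::Ntip(tr) != 22L) {
      stop("non-clock tree requires exactly 22 taxa", call. = FALSE)
    }
    tr <- ape::unroot(tr)
    if (nrow(tr$edge) != 41L) {
      stop("topology is not a binary unrooted 22-taxon tree", call. = FALSE)
    }
    external <- tr$edge[, 2] <= ape::Ntip(tr)
    stopifnot(sum(external) == 22L, sum(!external) == 19L)
    len <- numeric(nrow(tr$edge))
    len[!external] <- 10^(2 * sample(0:18) / 18 - 3)
    len[external] <- 10^(2 * sample(0:21) / 21 - 3)
    tr$edge.length <- len
    tr
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
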