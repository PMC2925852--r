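# Sequence simulation along a tree under a GTR-family model, with discrete
# gamma rate heterogeneity and invariable sites (Seq-Gen-style semantics:
# invariable sites have rate 0 and keep the state drawn at the root from pi;
# variable-site rates are the unscaled discrete-gamma category rates).

#' Discrete gamma category rates
#'
#' Yang's mean-of-quantile-interval discretisation of the Gamma(shape,
#' shape) rate distribution: categories have equal probability `1/ncat` and
#' each category's rate is the conditional mean over its quantile interval,
#' so the category rates average exactly 1.
#'
#' @param shape Gamma shape alpha (> 0).
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rates with mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  stopifnot(shape > 0, ncat >= 1)
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape, shape)
  r <- (stats::pgamma(q[-1], shape + 1, shape) -
          stats::pgamma(q[-(ncat + 1)], shape + 1, shape)) * ncat
  r
}

# Draw a per-site rate vector under the model's +I/+G structure.  Rate 0
# marks invariable sites; variable-site rates are rescaled by
# 1 / (1 - p_inv) so the mean rate over all sites is 1 and branch lengths
# keep their expected-substitutions-per-site meaning under +I.
draw_site_rates <- function(n_sites, params, spec) {
  rates <- rep(1, n_sites)
  if (spec$has_gamma) {
    cat_rates <- discrete_gamma_rates(params$gamma_shape, params$ncat)
    rates <- cat_rates[sample.int(params$ncat, n_sites, replace = TRUE)]
  }
  if (spec$has_inv) {
    rates <- rates / (1 - params$p_inv)
    rates[stats::runif(n_sites) < params$p_inv] <- 0
  }
  rates
}

# Evolve integer-coded states (1..nstate) down a tree.  `root_states` is a
# vector over sites; `site_rates` multiplies branch lengths per site.
# Transition matrices are computed once per (edge, rate class).
evolve_states <- function(tree, dec, root_states, site_rates) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  states <- matrix(0L, n_node, length(root_states))
  root <- n_tip + 1L
  states[root, ] <- root_states
  classes <- unique(site_rates)
  class_id <- match(site_rates, classes)
  nstate <- length(dec$values)
  # preorder traversal: cladewise order visits every parent before its children
  tree <- ape::reorder.phylo(tree, "cladewise")
  ord <- tree$edge
  len <- tree$edge.length
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1]; child <- ord[e, 2]
    child_states <- integer(ncol(states))
    for (ci in seq_along(classes)) {
      r <- classes[ci]
      sites <- which(class_id == ci)
      if (!length(sites)) next
      if (r == 0 || len[e] == 0) {
        child_states[sites] <- states[parent, sites]
        next
      }
      P <- prob_matrix(dec, len[e] * r)
      ps <- states[parent, sites]
      for (s in seq_len(nstate)) {
        here <- sites[ps == s]
        if (length(here)) {
          child_states[here] <- sample.int(nstate, length(here),
                                           replace = TRUE, prob = P[s, ])
        }
      }
    }
    states[child, ] <- child_states
  }
  states[seq_len(n_tip), , drop = FALSE]
}

#' Simulate a nucleotide alignment along a tree
#'
#' Generates an alignment under a GTR-family model: root states are drawn
#' from the stationary frequencies, sites evolve independently down the
#' tree with transition probabilities `expm(Q * t * r)`, where `r` is the
#' site's rate (a discrete-gamma category rate under +G; 0 with
#' probability `p_inv` under +I).
#'
#' @param tree A rooted or unrooted `phylo` with branch lengths in
#'   expected substitutions per site.
#' @param model A model name or `model_spec`; `params` is pinned to it.
#' @param params A `model_parameters` object (default [parameter_set()]
#'   values must be supplied explicitly).
#' @param n_sites Alignment length in base pairs.
#' @param seed Optional integer seed; identical seeds give identical
#'   alignments.
#' @return A character matrix (taxa x sites) over A/C/G/T with the tip
#'   labels as rownames and the per-site rate multipliers in
#'   `attr(, "site_rates")`.
#' @examples
#' tr <- simulate_birth_death_tree(6, seed = 1)
#' aln <- simulate_alignment(tr, "HKY+G", parameter_set("A"), 100, seed = 2)
#' @export
simulate_alignment <- function(tree, model, params, n_sites, seed = NULL) {
  spec <- model_spec(model)
  if (n_sites <= 0) stop("n_sites must be positive", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  params <- pin_parameters(params, spec)
  Q <- build_rate_matrix(params)
  dec <- decompose_rate_matrix(Q, params$base_freqs)
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  sim <- function() {
    rates <- draw_site_rates(n_sites, params, spec)
    root_states <- sample.int(4L, n_sites, replace = TRUE,
                              prob = params$base_freqs)
    tips <- evolve_states(tree, dec, root_states, rates)
    aln <- matrix(NUC_BASES[tips], nrow = nrow(tips),
                  dimnames = list(tree$tip.label, NULL))
    attr(aln, "site_rates") <- rates
    aln
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Convert an alignment matrix to phangorn's phyDat
#'
#' @param alignment Character matrix as returned by [simulate_alignment()].
#' @return A `phyDat` object.
#' @export
as_phyDat <- function(alignment) {
  phangorn::phyDat(alignment, type = "DNA")
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param alignment Character matrix (taxa x sites).
#' @param file Output path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @export
write_alignment <- function(alignment, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  dna <- ape::as.DNAbin(alignment)
  if (format == "fasta") {
    ape::write.FASTA(dna, file)
  } else {
    ape::write.dna(dna, file, format = "sequential", colsep = "")
  }
  invisible(file)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param file Input path.
#' @param format `"fasta"` or `"phylip"`.
#' @return A character matrix (taxa x sites), uppercase.
#' @export
read_alignment <- function(file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  dna <- if (format == "fasta") {
    ape::read.FASTA(file)
  } else {
    ape::read.dna(file, format = "sequential")
  }
  m <- toupper(as.character(as.matrix(dna)))
  matrix(m, nrow = nrow(m), dimnames = dimnames(m))
}
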