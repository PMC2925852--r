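# Independent oracles used across the suite.  These deliberately avoid the
# package's pruning recursion and rate-matrix plumbing: the rate matrix is
# rebuilt directly from the definition and transition probabilities come
# from Matrix::expm, so agreement with the package is a genuine two-route
# check.

oracle_rate_matrix <- function(freqs, rates) {
  Q <- matrix(0, 4, 4)
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    Q[pair[k, 1], pair[k, 2]] <- rates[k] * freqs[pair[k, 2]]
    Q[pair[k, 2], pair[k, 1]] <- rates[k] * freqs[pair[k, 1]]
  }
  diag(Q) <- -rowSums(Q)
  Q / -sum(freqs * diag(Q))
}

oracle_gamma_rates <- function(shape, ncat) {
  q <- qgamma(seq(0, 1, length.out = ncat + 1), shape, shape)
  vapply(seq_len(ncat), function(i) {
    ncat * integrate(function(x) x * dgamma(x, shape, shape),
                     q[i], q[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
}

# Likelihood by exhaustive enumeration of internal-node states (<= 5 taxa).
# Site likelihoods mix a rate-0 invariable category (weight p_inv) with the
# discrete-gamma categories rescaled by 1/(1 - p_inv).
oracle_log_likelihood <- function(alignment, tree, freqs, rates,
                                  gamma_shape = NA, p_inv = 0, ncat = 4) {
  Q <- oracle_rate_matrix(freqs, rates)
  cat_rates <- 1
  weights <- 1
  if (!is.na(gamma_shape)) {
    cat_rates <- oracle_gamma_rates(gamma_shape, ncat)
    weights <- rep(1 / ncat, ncat)
  }
  if (p_inv > 0) {
    cat_rates <- c(0, cat_rates / (1 - p_inv))
    weights <- c(p_inv, (1 - p_inv) * weights)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- max(tree$edge)
  internal <- (n_tip + 1):n_node
  root <- tree$edge[nrow(tree$edge), 1]
  codes <- matrix(match(alignment[tree$tip.label, , drop = FALSE],
                        c("A", "C", "G", "T")), nrow = n_tip)
  n_sites <- ncol(codes)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  lik <- numeric(n_sites)
  for (ci in seq_along(cat_rates)) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e) {
      if (cat_rates[ci] == 0) diag(4) else
        as.matrix(Matrix::expm(Q * tree$edge.length[e] * cat_rates[ci]))
    })
    cat_lik <- numeric(n_sites)
    for (g in seq_len(nrow(grid))) {
      states <- matrix(0L, n_node, n_sites)
      states[seq_len(n_tip), ] <- codes
      states[internal, ] <- grid[g, ]
      pr <- freqs[states[root, ]]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * P[[e]][cbind(states[tree$edge[e, 1], ],
                                states[tree$edge[e, 2], ])]
      }
      cat_lik <- cat_lik + pr
    }
    lik <- lik + weights[ci] * cat_lik
  }
  sum(log(lik))
}

# random binary tree with branch lengths, 3..5 taxa
random_small_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.8)
  tr
}

random_model_parameters <- function() {
  f <- stats::runif(4, 0.1, 1)
  model_parameters(
    base_freqs = f / sum(f),
    rates = c(stats::runif(5, 0.2, 5), 1),
    gamma_shape = stats::runif(1, 0.3, 2),
    p_inv = stats::runif(1, 0, 0.5)
  )
}

# fabricate a model_fits table from named log-likelihoods (and optional
# branch-length vectors) for criterion-level tests
make_fit_table <- function(lnL, n_sites = 1000, edge_lengths = NULL) {
  models <- names(lnL)
  fits <- tibble::tibble(
    model = models,
    free_params = vapply(models, free_parameters, integer(1)),
    category = vapply(models, model_category, character(1)),
    lnL = as.numeric(lnL),
    converged = TRUE,
    params = vector("list", length(models)),
    edge_lengths = if (is.null(edge_lengths)) {
      replicate(length(models), rep(0.1, 5), simplify = FALSE)
    } else {
      edge_lengths
    }
  )
  attr(fits, "n_sites") <- n_sites
  class(fits) <- c("model_fits", class(fits))
  fits
}

# nesting relation over the candidate set: a is a special case of b iff
# b frees at least the frequencies a frees, b's rate classes refine a's,
# and b carries at least a's +I/+G flags
is_nested_model <- function(a, b) {
  sa <- model_spec(a); sb <- model_spec(b)
  if (sa$has_inv && !sb$has_inv) return(FALSE)
  if (sa$has_gamma && !sb$has_gamma) return(FALSE)
  if (!sa$equal_freqs && sb$equal_freqs) return(FALSE)
  pa <- sa$pattern; pb <- sb$pattern
  for (i in 1:5) for (j in (i + 1):6) {
    if (pb[i] == pb[j] && pa[i] != pa[j]) return(FALSE)
  }
  TRUE
}

# one shared scaled-down replication of the simulation study, computed on
# first use and cached for the session
study_cache <- new.env(parent = emptyenv())

scaled_study <- function() {
  if (is.null(study_cache$run)) {
    study_cache$run <- run_condition(
      "I-2", generating = generating_models(), n_replicates = 2,
      n_sites = 300, seed = 1)
  }
  study_cache$run
}
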