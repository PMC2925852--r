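# Likelihood engine: JC distances and the NJ starting tree, Felsenstein
# pruning log-likelihoods, and maximum-likelihood fits of candidate models
# on the fixed NJ topology.

#' Jukes-Cantor distance matrix
#'
#' Pairwise distances `d = -3/4 log(1 - 4p/3)` where `p` is the mismatch
#' proportion over columns in which both sequences carry an unambiguous
#' base.  Saturated pairs (`p >= 0.75`) are capped at `cap` with a warning
#' rather than returning infinity, so downstream neighbor-joining always
#' receives finite input.
#'
#' @param alignment Character matrix (taxa x sites).
#' @param cap Ceiling substituted for undefined distances (default 5).
#' @return Symmetric numeric matrix with zero diagonal and the taxa as
#'   dimnames.
#' @export
jc_distance_matrix <- function(alignment, cap = 5) {
  stopifnot(is.matrix(alignment), nrow(alignment) >= 2)
  n <- nrow(alignment)
  taxa <- rownames(alignment)
  ok <- matrix(alignment %in% NUC_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      p <- mean(alignment[i, use] != alignment[j, use])
      if (p >= 0.75) {
        capped <- TRUE
        dij <- cap
      } else {
        dij <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (capped) {
    warning("saturated pairwise distances capped at ", cap, call. = FALSE)
  }
  d
}

#' Neighbor-joining starting tree
#'
#' Saitou-Nei agglomeration (via [ape::nj()]) with negative estimated
#' branch lengths clamped to zero; this is the fixed topology on which all
#' candidate models are fitted.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return An unrooted `phylo`.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d))
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Site-rate mixture implied by a spec: rates with mixing weights.  Under
# +I, variable-site rates are rescaled by 1 / (1 - p_inv) so the mixture
# mean stays 1 (the PAML/phangorn convention; matches the simulator).
rate_mixture <- function(params, spec) {
  rates <- 1
  weights <- 1
  if (spec$has_gamma) {
    rates <- discrete_gamma_rates(params$gamma_shape, params$ncat)
    weights <- rep(1 / params$ncat, params$ncat)
  }
  if (spec$has_inv) {
    rates <- c(0, rates / (1 - params$p_inv))
    weights <- c(params$p_inv, (1 - params$p_inv) * weights)
  }
  list(rates = rates, weights = weights)
}

# Integer-code an alignment (A,C,G,T -> 1..4; anything else 0 = missing)
# and compress to unique site patterns with weights.
encode_patterns <- function(alignment) {
  codes <- matrix(match(alignment, NUC_BASES, nomatch = 0L),
                  nrow = nrow(alignment))
  key <- apply(codes, 2, paste, collapse = ",")
  uq <- !duplicated(key)
  list(
    codes = codes[, uq, drop = FALSE],
    weights = as.vector(table(key)[key[uq]])
  )
}

#' Felsenstein pruning log-likelihood
#'
#' Computes the log-likelihood of an alignment on a tree under a
#' GTR-family model by the pruning algorithm, with per-node rescaling for
#' numerical stability.  The site likelihood mixes rate categories:
#' invariable sites contribute through a rate-0 category with weight
#' `p_inv`, and +G models through `ncat` equal-weight discrete-gamma
#' categories.  Missing or ambiguous characters contribute partial
#' likelihood 1 (treated as missing data).
#'
#' @param alignment Character matrix (taxa x sites); rownames must match
#'   the tree's tip labels.
#' @param tree A `phylo` (rooted or unrooted) covering all taxa.
#' @param model Model name or `model_spec`.
#' @param params `model_parameters`; pinned to `model` before use.
#' @return The log-likelihood (a single number, <= 0).
#' @export
log_likelihood <- function(alignment, tree, model, params) {
  spec <- model_spec(model)
  params <- pin_parameters(params, spec)
  if (!setequal(rownames(alignment), tree$tip.label)) {
    stop("alignment taxa do not match tree tip labels", call. = FALSE)
  }
  alignment <- alignment[tree$tip.label, , drop = FALSE]
  pi <- params$base_freqs
  Q <- build_rate_matrix(params)
  dec <- decompose_rate_matrix(Q, pi)
  mix <- rate_mixture(params, spec)
  pat <- encode_patterns(alignment)
  codes <- pat$codes
  npat <- ncol(codes)
  n_tip <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  len <- tree$edge.length
  root <- edge[nrow(edge), 1]

  # tip partial likelihoods (shared across rate categories)
  tip_partial <- function(tip) {
    m <- matrix(0, 4, npat)
    cc <- codes[tip, ]
    m[cbind(cc[cc > 0], which(cc > 0))] <- 1
    m[, cc == 0] <- 1
    m
  }
  tips <- lapply(seq_len(n_tip), tip_partial)

  site_lik <- matrix(0, length(mix$rates), npat)
  for (ci in seq_along(mix$rates)) {
    r <- mix$rates[ci]
    partials <- vector("list", max(edge))
    partials[seq_len(n_tip)] <- tips
    logscale <- numeric(npat)
    for (e in seq_len(nrow(edge))) {
      parent <- edge[e, 1]; child <- edge[e, 2]
      P <- if (r == 0) diag(4) else prob_matrix(dec, len[e] * r)
      contrib <- P %*% partials[[child]]
      if (is.null(partials[[parent]])) {
        partials[[parent]] <- contrib
      } else {
        partials[[parent]] <- partials[[parent]] * contrib
        mx <- apply(partials[[parent]], 2, max)
        mx[mx == 0] <- 1
        partials[[parent]] <- sweep(partials[[parent]], 2, mx, "/")
        logscale <- logscale + log(mx)
      }
    }
    site_lik[ci, ] <- as.vector(pi %*% partials[[root]]) * exp(logscale)
  }
  lik <- as.vector(mix$weights %*% site_lik)
  if (any(lik <= 0)) return(-Inf)
  sum(log(lik) * pat$weights)
}

# Map a base-model rate-class pattern to optim.pml's `subs` vector:
# the GT class is fixed at 1 (coded 0), remaining classes renumbered.
pattern_to_subs <- function(pattern) {
  gt_class <- pattern[6]
  out <- integer(6)
  free_classes <- unique(pattern[pattern != gt_class])
  for (k in seq_along(free_classes)) {
    out[pattern == free_classes[k]] <- k
  }
  out
}

#' Fit one candidate model on a fixed topology
#'
#' Maximum-likelihood fit of a GTR-family model by
#' [phangorn::optim.pml()]: branch lengths and the model's free parameters
#' (frequencies, exchangeability classes, gamma shape, proportion of
#' invariable sites) are optimised jointly on the given topology; the
#' topology itself is never re-estimated, so branch-length vectors are
#' comparable across all candidate fits of one dataset.
#'
#' @param data A `phyDat` object or character alignment matrix.
#' @param topology Unrooted `phylo`; typically the dataset's NJ tree.
#' @param model Model name or `model_spec` from the candidate set.
#' @param control A [phangorn::pml.control()] list.
#' @return A `model_fit` list: `model`, `lnL`, `free_params`, `params`
#'   (fitted `model_parameters`), `edge_lengths`, `n_sites`, `converged`.
#' @export
fit_model <- function(data, topology, model,
                      control = phangorn::pml.control(epsilon = 1e-8,
                                                      maxit = 10,
                                                      trace = 0)) {
  spec <- model_spec(model)
  if (is.matrix(data)) data <- as_phyDat(data)
  topology <- ape::unroot(topology)
  topology$edge.length[topology$edge.length < 1e-8] <- 1e-8
  subs <- pattern_to_subs(spec$pattern)
  k <- if (spec$has_gamma) 4L else 1L
  n_sites <- sum(attr(data, "weight"))
  fit <- tryCatch({
    f0 <- phangorn::pml(topology, data,
                        bf = if (spec$equal_freqs) rep(0.25, 4) else NULL,
                        k = k, shape = 1, inv = 0)
    phangorn::optim.pml(
      f0,
      optBf = !spec$equal_freqs,
      optQ = any(subs != 0), subs = subs,
      optGamma = spec$has_gamma, optInv = spec$has_inv,
      optEdge = TRUE, control = control
    )
  }, error = function(e) {
    warning("fit of ", spec$name, " failed: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  if (is.null(fit)) {
    return(structure(
      list(model = spec$name, spec = spec, lnL = NA_real_,
           free_params = spec$free_params, params = NULL,
           edge_lengths = rep(NA_real_, nrow(topology$edge)),
           n_sites = n_sites, converged = FALSE),
      class = "model_fit"
    ))
  }
  # optim.pml reorders edges internally; map branch lengths back onto the
  # caller's edge indexing so vectors are comparable across fits
  edge_key <- function(tr) paste(tr$edge[, 1], tr$edge[, 2])
  edge_lengths <- fit$tree$edge.length[match(edge_key(topology),
                                             edge_key(fit$tree))]
  fitted_params <- model_parameters(
    base_freqs = fit$bf,
    rates = fit$Q / fit$Q[6],
    gamma_shape = if (spec$has_gamma) fit$shape else NA_real_,
    p_inv = if (spec$has_inv) fit$inv else 0,
    ncat = k
  )
  structure(
    list(model = spec$name, spec = spec, lnL = as.numeric(stats::logLik(fit)),
         free_params = spec$free_params, params = fitted_params,
         edge_lengths = edge_lengths, n_sites = n_sites,
         converged = TRUE),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s  lnL = %.3f  (K = %d, %s)\n", x$model, x$lnL,
              x$free_params, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the candidate-model set on one dataset
#'
#' Builds the dataset's NJ starting tree (JC distances) unless a topology
#' is supplied, then fits every model in `models` on that fixed topology.
#' All fits share one edge indexing, as required by decision-theoretic
#' selection.
#'
#' @param alignment Character matrix (taxa x sites).
#' @param topology Optional unrooted `phylo`; defaults to the NJ tree.
#' @param models Tibble of models, as [candidate_models()] (default) or
#'   any subset of it.
#' @inheritParams fit_model
#' @return A tibble of class `model_fits` with columns `model`,
#'   `free_params`, `category`, `lnL`, `converged`, `params` (list) and
#'   `edge_lengths` (list); attributes `n_sites` and `tree`.
#' @export
fit_candidate_models <- function(alignment, topology = NULL,
                                 models = candidate_models(),
                                 control = phangorn::pml.control(
                                   epsilon = 1e-8, maxit = 10, trace = 0)) {
  data <- as_phyDat(alignment)
  if (is.null(topology)) {
    topology <- neighbor_joining(jc_distance_matrix(alignment))
  }
  fits <- purrr::map(models$model, function(m) {
    fit_model(data, topology, m, control = control)
  })
  out <- tibble::tibble(
    model = models$model,
    free_params = models$free_params,
    category = models$category,
    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    params = purrr::map(fits, "params"),
    edge_lengths = purrr::map(fits, "edge_lengths")
  )
  attr(out, "n_sites") <- ncol(alignment)
  attr(out, "tree") <- topology
  class(out) <- c("model_fits", class(out))
  out
}
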