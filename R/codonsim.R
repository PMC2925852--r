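# GY94 codon-model simulation.  The 61x61 generator allows only single-
# nucleotide changes; rates are proportional to the target-codon frequency
# times the nucleotide exchangeability of the changed base, multiplied by
# omega for nonsynonymous changes (universal genetic code).  Codon
# frequencies follow the F1x4 convention: the product of the position-wise
# nucleotide frequencies, identical across the three positions, renormalised
# over the 61 sense codons.

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

codon_amino_acids <- function() {
  code <- Biostrings::GENETIC_CODE
  code[code != "*"]
}

# F1x4 codon frequencies from nucleotide frequencies.
codon_frequencies <- function(base_freqs) {
  codons <- sense_codons()
  pos <- do.call(rbind, strsplit(codons, ""))
  f <- base_freqs[pos[, 1]] * base_freqs[pos[, 2]] * base_freqs[pos[, 3]]
  stats::setNames(f / sum(f), codons)
}

#' Configuration for GY94 codon simulation
#'
#' Bundles the settings of the codon-model simulation: the nucleotide
#' parameters of a GTR-family generating model (whose exchangeabilities and
#' frequencies parameterise the single-nucleotide-change term of the codon
#' matrix, and whose +I/+G structure acts as site-rate multipliers on
#' codon sites), the nonsynonymous/synonymous rate ratio, the alignment
#' length, and a mutation-rate scalar applied to branch lengths.
#'
#' @param model Generating model name or `model_spec` (GTR family).
#' @param params `model_parameters` for the nucleotide process.
#' @param omega Nonsynonymous/synonymous rate ratio (> 0); default 0.016.
#' @param length_nt Alignment length in nucleotides; must be divisible
#'   by 3 (default 999).
#' @param mutation_rate Scalar multiplying branch lengths before
#'   simulation (default 0.001).
#' @return A `codon_sim_config` object.
#' @export
codon_sim_config <- function(model, params, omega = 0.016,
                             length_nt = 999L, mutation_rate = 0.001) {
  spec <- model_spec(model)
  stopifnot(inherits(params, "model_parameters"))
  if (omega <= 0) stop("omega must be positive", call. = FALSE)
  if (length_nt %% 3 != 0) {
    stop("length_nt must be divisible by 3", call. = FALSE)
  }
  if (mutation_rate <= 0) stop("mutation_rate must be positive", call. = FALSE)
  structure(
    list(spec = spec, params = pin_parameters(params, spec), omega = omega,
         length_nt = as.integer(length_nt), mutation_rate = mutation_rate),
    class = "codon_sim_config"
  )
}

#' Build the normalised GY94 codon rate matrix
#'
#' @param params `model_parameters` carrying the nucleotide
#'   exchangeabilities and base frequencies.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @return A 61x61 rate matrix over the sense codons, rows summing to
#'   zero, normalised to one expected codon substitution per unit branch
#'   length, time-reversible with respect to the F1x4 codon frequencies.
#' @export
gy94_rate_matrix <- function(params, omega) {
  codons <- sense_codons()
  aa <- codon_amino_acids()
  cf <- codon_frequencies(params$base_freqs)
  n <- length(codons)
  pos <- do.call(rbind, strsplit(codons, ""))
  rate_lookup <- matrix(0, 4, 4, dimnames = list(NUC_BASES, NUC_BASES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    rate_lookup[idx[k, 1], idx[k, 2]] <- params$rates[k]
    rate_lookup[idx[k, 2], idx[k, 1]] <- params$rates[k]
  }
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(pos[i, ] != pos[j, ])
      if (length(diff) != 1L) next
      r <- rate_lookup[pos[i, diff], pos[j, diff]] * cf[j]
      if (aa[i] != aa[j]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(cf * diag(Q))
  Q / mu
}

#' Simulate a codon alignment under GY94
#'
#' Simulates codon sites down the tree under the GY94 generator built from
#' `config`, after multiplying branch lengths by the configured mutation
#' rate.  Site-rate multipliers (+I/+G of the nucleotide generating model)
#' apply per codon site.  The returned alignment is nucleotide characters;
#' it contains no stop codons by construction.
#'
#' @param tree A `phylo` with branch lengths.
#' @param config A [codon_sim_config()] object.
#' @param seed Optional integer seed.
#' @return Character matrix (taxa x `length_nt`) with
#'   `attr(, "site_rates")` giving the per-codon-site rates.
#' @export
simulate_codon_alignment <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "codon_sim_config"))
  codons <- sense_codons()
  cf <- codon_frequencies(config$params$base_freqs)
  Q <- gy94_rate_matrix(config$params, config$omega)
  dec <- decompose_rate_matrix(Q, cf)
  tree$edge.length <- tree$edge.length * config$mutation_rate
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  n_codon <- config$length_nt %/% 3L
  sim <- function() {
    rates <- draw_site_rates(n_codon, config$params, config$spec)
    root_states <- sample.int(length(codons), n_codon, replace = TRUE,
                              prob = cf)
    tips <- evolve_states(tree, dec, root_states, rates)
    nt <- t(apply(tips, 1, function(row) {
      unlist(strsplit(codons[row], ""), use.names = FALSE)
    }))
    rownames(nt) <- tree$tip.label
    attr(nt, "site_rates") <- rates
    nt
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}
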