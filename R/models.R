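# GTR model family: specifications, parameterisations, rate matrices.
#
# Exchangeabilities are stored throughout in the order AC, AG, AT, CG, CT, GT
# and are expressed relative to GT = 1.  Base frequencies are ordered A, C, G,
# T.  kappa-parameterised models (K80/HKY) are converted to exchangeability
# form (AG = CT = kappa, transversions = 1) so that a single rate-matrix
# builder serves the whole family.

NUC_BASES <- c("A", "C", "G", "T")
RATE_ORDER <- c("AC", "AG", "AT", "CG", "CT", "GT")

# The 14 base models: the "7 substitution schemes x 2 frequency variants" set
# (the equal-frequency variants carry the -ef / K81-style names).  `pattern`
# groups the six exchangeabilities into shared rate classes; the number of
# free rate parameters is (number of classes - 1), plus 3 when base
# frequencies are free.
.base_model_table <- function() {
  pat <- list(
    JC    = c(1, 1, 1, 1, 1, 1),
    F81   = c(1, 1, 1, 1, 1, 1),
    K80   = c(1, 2, 1, 1, 2, 1),
    HKY   = c(1, 2, 1, 1, 2, 1),
    TrNef = c(1, 2, 1, 1, 3, 1),
    TrN   = c(1, 2, 1, 1, 3, 1),
    K81   = c(1, 2, 3, 3, 2, 1),
    K81uf = c(1, 2, 3, 3, 2, 1),
    TIMef = c(1, 2, 3, 3, 4, 1),
    TIM   = c(1, 2, 3, 3, 4, 1),
    TVMef = c(1, 2, 3, 4, 2, 5),
    TVM   = c(1, 2, 3, 4, 2, 5),
    SYM   = c(1, 2, 3, 4, 5, 6),
    GTR   = c(1, 2, 3, 4, 5, 6)
  )
  equal <- c(TRUE, FALSE)[rep(1:2, 7)]
  tibble::tibble(
    base = names(pat),
    equal_freqs = equal,
    pattern = unname(pat),
    rate_params = unname(vapply(pat, function(p) length(unique(p)) - 1L,
                                integer(1))),
    base_params = unname(vapply(pat, function(p) length(unique(p)) - 1L,
                                integer(1))) + ifelse(equal, 0L, 3L)
  )
}

base_models_env <- new.env(parent = emptyenv())

base_model_table <- function() {
  if (is.null(base_models_env$tab)) base_models_env$tab <- .base_model_table()
  base_models_env$tab
}

#' Parse a model name into a model specification
#'
#' Model names follow the usual `"BASE"`, `"BASE+I"`, `"BASE+G"`,
#' `"BASE+I+G"` convention, where `BASE` is one of the 14 base models
#' (JC, F81, K80, HKY, TrNef, TrN, K81, K81uf, TIMef, TIM, TVMef, TVM,
#' SYM, GTR).
#'
#' @param name Model name such as `"HKY+I+G"`.
#' @return A `model_spec` object: a list with elements `name`, `base`,
#'   `has_inv`, `has_gamma`, `free_params` and `category`.
#' @examples
#' model_spec("GTR+I+G")
#' @export
model_spec <- function(name) {
  if (inherits(name, "model_spec")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  flags <- parts[-1]
  tab <- base_model_table()
  if (!base %in% tab$base) {
    stop("unknown base model: '", base, "'", call. = FALSE)
  }
  if (!all(flags %in% c("I", "G")) || anyDuplicated(flags)) {
    stop("malformed model name: '", name, "'", call. = FALSE)
  }
  has_inv <- "I" %in% flags
  has_gamma <- "G" %in% flags
  row <- tab[tab$base == base, ]
  structure(
    list(
      name = paste0(base, if (has_inv) "+I" else "", if (has_gamma) "+G" else ""),
      base = base,
      equal_freqs = row$equal_freqs,
      pattern = row$pattern[[1]],
      has_inv = has_inv,
      has_gamma = has_gamma,
      free_params = row$base_params + has_inv + has_gamma,
      category = model_category_string(has_inv, has_gamma)
    ),
    class = "model_spec"
  )
}

model_category_string <- function(has_inv, has_gamma) {
  c("base", "base+I", "base+G", "base+I+G")[1L + has_inv + 2L * has_gamma]
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "  (", x$free_params, " free parameters, ",
      x$category, ")\n", sep = "")
  invisible(x)
}

#' Number of free parameters of a substitution model
#'
#' Counts the free substitution-model parameters: exchangeability classes
#' beyond the reference (GT = 1), three frequency parameters for
#' unequal-frequency models, plus one each for the proportion of invariable
#' sites (+I) and the gamma shape (+G).  Branch lengths are not counted.
#'
#' @param model A model name or `model_spec`.
#' @return Integer in 0..10.
#' @examples
#' free_parameters("GTR+I+G") # 10
#' free_parameters("JC")      # 0
#' @export
free_parameters <- function(model) {
  model_spec(model)$free_params
}

#' Rate-heterogeneity category of a model
#'
#' Classifies a model as `"base"`, `"base+I"`, `"base+G"` or `"base+I+G"`
#' according to its invariable-sites and gamma flags.
#'
#' @inheritParams free_parameters
#' @return A string, one of the four categories.
#' @export
model_category <- function(model) {
  model_spec(model)$category
}

.expand_models <- function(bases) {
  ext <- c("", "+I", "+G", "+I+G")
  names <- as.vector(t(outer(bases, ext, paste0)))
  specs <- lapply(names, model_spec)
  tibble::tibble(
    model = names,
    base = vapply(specs, `[[`, character(1), "base"),
    has_inv = vapply(specs, `[[`, logical(1), "has_inv"),
    has_gamma = vapply(specs, `[[`, logical(1), "has_gamma"),
    free_params = vapply(specs, `[[`, integer(1), "free_params"),
    category = vapply(specs, `[[`, character(1), "category")
  )
}

#' The 56-model candidate set
#'
#' All 14 base models crossed with the four rate-heterogeneity categories;
#' this is the candidate set scored on every dataset.
#'
#' @return A tibble with 56 rows and columns `model`, `base`, `has_inv`,
#'   `has_gamma`, `free_params`, `category`.
#' @export
candidate_models <- function() {
  .expand_models(base_model_table()$base)
}

#' The 24 generating models
#'
#' The six bases JC, F81, K80, HKY, SYM and GTR crossed with the four
#' rate-heterogeneity categories: the models under which datasets are
#' simulated.  Every generating model is a member of [candidate_models()].
#'
#' @return A tibble with 24 rows, same columns as [candidate_models()].
#' @export
generating_models <- function() {
  .expand_models(c("JC", "F81", "K80", "HKY", "SYM", "GTR"))
}

#' Construct a set of substitution-model parameters
#'
#' Holds the continuous parameters from which rate matrices are built.
#' Either `rates` (six exchangeabilities relative to GT = 1) or `kappa`
#' (transition/transversion rate ratio; expands to AG = CT = kappa,
#' transversions = 1) may be given; `rates` wins if both are present.
#'
#' @param base_freqs Numeric length-4 stationary frequencies (A, C, G, T);
#'   must sum to 1.
#' @param rates Numeric length-6 exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param kappa Transition/transversion rate ratio.
#' @param gamma_shape Gamma shape alpha (> 0), or `NA` for no gamma
#'   heterogeneity.
#' @param p_inv Proportion of invariable sites in `[0, 1)`.
#' @param ncat Number of discrete gamma categories (default 4).
#' @return A `model_parameters` object.
#' @export
model_parameters <- function(base_freqs = rep(0.25, 4), rates = NULL,
                             kappa = NULL, gamma_shape = NA_real_,
                             p_inv = 0, ncat = 4L) {
  if (is.null(rates)) {
    rates <- if (is.null(kappa)) rep(1, 6) else c(1, kappa, 1, 1, kappa, 1)
  }
  base_freqs <- as.numeric(base_freqs)
  rates <- as.numeric(rates)
  if (length(base_freqs) != 4L || anyNA(base_freqs) || any(base_freqs < 0)) {
    stop("base_freqs must be 4 nonnegative numbers", call. = FALSE)
  }
  if (abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must sum to 1", call. = FALSE)
  }
  if (length(rates) != 6L || anyNA(rates) || any(rates < 0)) {
    stop("rates must be 6 nonnegative numbers (AC, AG, AT, CG, CT, GT)",
         call. = FALSE)
  }
  if (!is.na(gamma_shape) && gamma_shape <= 0) {
    stop("gamma_shape must be positive", call. = FALSE)
  }
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)", call. = FALSE)
  structure(
    list(
      base_freqs = stats::setNames(base_freqs / sum(base_freqs), NUC_BASES),
      rates = stats::setNames(rates, RATE_ORDER),
      kappa = if (is.null(kappa)) NA_real_ else kappa,
      gamma_shape = gamma_shape,
      p_inv = p_inv,
      ncat = as.integer(ncat)
    ),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat("  freqs:", paste(sprintf("%s=%.4g", NUC_BASES, x$base_freqs),
                        collapse = " "), "\n")
  cat("  rates:", paste(sprintf("%s=%.4g", RATE_ORDER, x$rates),
                        collapse = " "), "\n")
  cat(sprintf("  gamma_shape=%s  p_inv=%.3g  ncat=%d\n",
              format(x$gamma_shape), x$p_inv, x$ncat))
  invisible(x)
}

#' Simulation parameter sets A and B
#'
#' The two fixed parameter sets used for dataset simulation.  Set A:
#' frequencies 0.35/0.22/0.18/0.25 (A/C/G/T), exchangeabilities (rel. GT)
#' 2.675, 7.35, 6.125, 0.225, 30.7; kappa 2.0; alpha 0.67256; p_inv 0.25.
#' Set B: frequencies 0.35/0.15/0.25/0.25, exchangeabilities 2, 4, 1.8,
#' 1.4, 6; kappa 2.0; alpha 0.5; p_inv 0.5.  Each parameter is only active
#' for generating models that free it (see [pin_parameters()]).
#'
#' @param set `"A"` or `"B"`.
#' @return A `model_parameters` object with four discrete gamma categories.
#' @export
parameter_set <- function(set = c("A", "B")) {
  set <- match.arg(set)
  if (set == "A") {
    model_parameters(
      base_freqs = c(0.35, 0.22, 0.18, 0.25),
      rates = c(2.675, 7.35, 6.125, 0.225, 30.7, 1),
      kappa = 2.0, gamma_shape = 0.67256, p_inv = 0.25, ncat = 4L
    )
  } else {
    model_parameters(
      base_freqs = c(0.35, 0.15, 0.25, 0.25),
      rates = c(2, 4, 1.8, 1.4, 6, 1),
      kappa = 2.0, gamma_shape = 0.5, p_inv = 0.5, ncat = 4L
    )
  }
}

# kappa expansion reference pattern (K80/HKY class structure)
.kappa_pattern <- c(1, 2, 1, 1, 2, 1)

#' Pin parameters to a model specification
#'
#' Restricts a full parameter set to the parameters a given model frees:
#' equal-frequency bases get uniform frequencies; exchangeabilities are
#' collapsed onto the base model's rate-class pattern (K80/HKY-type classes
#' take the kappa value when one is supplied; otherwise classes take the
#' mean of their member rates, renormalised to GT = 1); `gamma_shape` is
#' dropped unless the model has +G and `p_inv` unless it has +I.
#'
#' @param params A `model_parameters` object (e.g. [parameter_set()]).
#' @param model A model name or `model_spec`.
#' @return A `model_parameters` object consistent with `model`.
#' @export
pin_parameters <- function(params, model) {
  spec <- model_spec(model)
  stopifnot(inherits(params, "model_parameters"))
  freqs <- if (spec$equal_freqs) rep(0.25, 4) else params$base_freqs
  pat <- spec$pattern
  if (identical(pat, .kappa_pattern) && !is.na(params$kappa)) {
    rates <- ifelse(pat == 2L, params$kappa, 1)
  } else {
    class_mean <- tapply(params$rates, pat, mean)
    rates <- as.numeric(class_mean[as.character(pat)])
    rates <- rates / rates[6]   # GT class back to 1
  }
  model_parameters(
    base_freqs = freqs, rates = rates,
    gamma_shape = if (spec$has_gamma) params$gamma_shape else NA_real_,
    p_inv = if (spec$has_inv) params$p_inv else 0,
    ncat = params$ncat
  )
}

#' Build a normalised GTR-family instantaneous rate matrix
#'
#' Constructs Q with off-diagonal entries `Q[i, j] = r[ij] * pi[j]`,
#' diagonal set so rows sum to zero, and the whole matrix scaled so that
#' the mean substitution rate `-sum(pi_i Q_ii)` equals 1, i.e. branch
#' lengths are expected substitutions per site.  The result is
#' time-reversible: `pi_i Q_ij = pi_j Q_ji`.
#'
#' @param params A `model_parameters` object.
#' @param model Optional model name or `model_spec`; when given, `params`
#'   is first passed through [pin_parameters()].
#' @return A 4x4 rate matrix with dimnames A, C, G, T.
#' @examples
#' build_rate_matrix(model_parameters())                 # JC: off-diag 1/3
#' build_rate_matrix(parameter_set("A"), "GTR")
#' @export
build_rate_matrix <- function(params, model = NULL) {
  if (!is.null(model)) params <- pin_parameters(params, model)
  stopifnot(inherits(params, "model_parameters"))
  pi <- params$base_freqs
  r <- params$rates
  Q <- matrix(0, 4, 4, dimnames = list(NUC_BASES, NUC_BASES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero mean rate)", call. = FALSE)
  Q / mu
}

# Eigendecomposition of a reversible rate matrix for fast P(t) = exp(Qt).
# Uses the similarity transform B = D^{1/2} Q D^{-1/2} (symmetric), so the
# decomposition is numerically stable and guaranteed real.
decompose_rate_matrix <- function(Q, base_freqs) {
  s <- sqrt(base_freqs)
  B <- Q * outer(s, 1 / s)   # B[i, j] = s_i Q_ij / s_j
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(
    values = e$values,
    right = e$vectors / s,        # D^{-1/2} V
    left = t(e$vectors * s)       # V' D^{1/2}
  )
}

# Transition probability matrix P(t) from a decomposition; tiny negative
# entries from roundoff are clamped and rows renormalised.
prob_matrix <- function(dec, t) {
  P <- dec$right %*% (exp(dec$values * t) * dec$left)
  P[P < 0] <- 0
  P / rowSums(P)
}
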