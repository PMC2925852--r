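# Model-selection criteria applied to a dataset's candidate-model fit
# table: hierarchical likelihood-ratio tests (with mixed chi-square for
# boundary hypotheses), AIC/AICc, BIC, and decision theory.

#' Likelihood-ratio test between two nested fits
#'
#' Computes `delta = 2 (lnL1 - lnL0)` and its p-value.  For regular tests
#' the null distribution is chi-square with `df` degrees of freedom.  For
#' boundary hypotheses (`mixed = TRUE`: the proportion of invariable sites
#' at 0, or the gamma shape at its no-heterogeneity limit) the mixed
#' distribution `0.5 chi2_0 + 0.5 chi2_1` is used: p = 1 when delta <= 0,
#' otherwise half the chi2_1 tail probability.
#'
#' @param lnL0,lnL1 Log-likelihoods of the null (simpler) and alternative
#'   (more complex) model.
#' @param df Degrees of freedom (>= 1).
#' @param mixed Use the boundary mixed chi-square null distribution.
#' @return An `lrt_result` list: `delta` (clamped at 0), `delta_raw`,
#'   `df`, `mixed`, `p_value`.
#' @examples
#' lrt(-1005, -1000, df = 1)
#' lrt(-1000, -999, df = 1, mixed = TRUE)
#' @export
lrt <- function(lnL0, lnL1, df, mixed = FALSE) {
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  delta_raw <- 2 * (lnL1 - lnL0)
  delta <- max(delta_raw, 0)
  p <- if (mixed) {
    if (delta <= 0) 1 else 0.5 * stats::pchisq(delta, 1, lower.tail = FALSE)
  } else {
    stats::pchisq(delta, df, lower.tail = FALSE)
  }
  structure(
    list(delta = delta, delta_raw = delta_raw, df = as.integer(df),
         mixed = isTRUE(mixed), p_value = p),
    class = "lrt_result"
  )
}

#' Information criteria
#'
#' `aic()`, `aicc()` and `bic()` evaluate the penalised-likelihood scores
#' `-2 lnL + 2K`, `-2 lnL + 2 K n / (n - K - 1)` and `-2 lnL + K log(n)`;
#' `n` is the sample size, taken as the sequence length, and `K` the number
#' of free model parameters.  Smaller scores are better.
#'
#' @param lnL Log-likelihood(s).
#' @param K Number of free parameters.
#' @param n Sample size (sequence length); for `aicc()`, must exceed
#'   `K + 1`.
#' @return Numeric score(s).
#' @export
aic <- function(lnL, K) -2 * lnL + 2 * K

#' @rdname aic
#' @export
aicc <- function(lnL, K, n) {
  if (any(n <= K + 1)) stop("AICc requires n > K + 1", call. = FALSE)
  -2 * lnL + 2 * K * n / (n - K - 1)
}

#' @rdname aic
#' @export
bic <- function(lnL, K, n) -2 * lnL + K * log(n)

# Shared argmin with the parsimony-first tie-break: smallest score, then
# fewest free parameters, then lexicographic model name.  Ties at the
# minimum are counted so their frequency is measurable.
argmin_model <- function(scores) {
  ord <- order(scores$score, scores$free_params, scores$model)
  chosen <- scores[ord[1], ]
  n_tied <- sum(scores$score == chosen$score)
  list(model = chosen$model, n_tied = n_tied)
}

usable_fits <- function(fits) {
  bad <- !fits$converged | !is.finite(fits$lnL)
  if (any(bad)) {
    warning("excluding non-converged fits: ",
            paste(fits$model[bad], collapse = ", "), call. = FALSE)
    fits <- fits[!bad, ]
  }
  if (nrow(fits) == 0) stop("no usable fits", call. = FALSE)
  fits
}

selection_result <- function(criterion, model, scores = NULL, trace = NULL,
                             n_tied = 1L) {
  structure(
    list(criterion = criterion, model = model, scores = scores,
         trace = trace, n_tied = n_tied),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s selects %s\n", x$criterion, x$model))
  invisible(x)
}

#' Select a model by an information criterion
#'
#' Scores every usable fit in the table and returns the minimiser; ties
#' are broken by fewer free parameters, then model name.
#'
#' @param fits A `model_fits` tibble from [fit_candidate_models()].
#' @param criterion `"AIC"`, `"AICc"` or `"BIC"`.
#' @param n_sites Sample size; defaults to the fit table's `n_sites`
#'   attribute.
#' @return A `selection_result` with the per-model score table attached.
#' @export
ic_select <- function(fits, criterion = c("AIC", "AICc", "BIC"),
                      n_sites = attr(fits, "n_sites")) {
  criterion <- match.arg(criterion)
  force(n_sites)
  fits <- usable_fits(fits)
  score <- switch(criterion,
    AIC = aic(fits$lnL, fits$free_params),
    AICc = aicc(fits$lnL, fits$free_params, n_sites),
    BIC = bic(fits$lnL, fits$free_params, n_sites)
  )
  scores <- tibble::tibble(model = fits$model,
                           free_params = fits$free_params,
                           lnL = fits$lnL, score = score)
  pick <- argmin_model(scores)
  selection_result(criterion, pick$model, scores = scores,
                   n_tied = pick$n_tied)
}

#' The default hLRT hierarchy
#'
#' A fixed binary decision tree of nested pairwise tests, expressed as
#' data so that alternative hierarchies are pluggable.  The default walks
#' the JC-to-GTR spine in the order: equal base frequencies (JC vs F81,
#' df 3), transition/transversion (df 1), equal transition rates (df 1),
#' and -- on the unequal-frequency branch only -- equal transversion-rate
#' classes (TrN vs GTR, df 3).  Rate-heterogeneity hypotheses follow the
#' base-model walk: gamma first, then invariable sites, both as mixed
#' boundary tests.  Note the fixed tree cannot terminate at every
#' candidate base; see [hlrt_reachable_models()].
#'
#' @return A tibble of test nodes with columns `id`, `null`, `alt`, `df`,
#'   `on_accept`, `on_reject` (either `node:<id>` or a terminal base
#'   model), with the starting node id in `attr(, "start")`.
#' @export
default_hierarchy <- function() {
  h <- tibble::tribble(
    ~id,      ~null,  ~alt,    ~df, ~on_accept,   ~on_reject,
    "freq",   "JC",   "F81",   3L,  "node:titv_e", "node:titv_u",
    "titv_e", "JC",   "K80",   1L,  "JC",          "node:tis_e",
    "titv_u", "F81",  "HKY",   1L,  "F81",         "node:tis_u",
    "tis_e",  "K80",  "TrNef", 1L,  "K80",         "TrNef",
    "tis_u",  "HKY",  "TrN",   1L,  "HKY",         "node:tvs_u",
    "tvs_u",  "TrN",  "GTR",   3L,  "TrN",         "GTR"
  )
  attr(h, "start") <- "freq"
  h
}

#' Base models reachable by an hLRT hierarchy
#'
#' Enumerates the terminal base models of a hierarchy's decision tree.
#' Combined with the four rate-heterogeneity categories these are the only
#' models the hLRT can ever return; under the default hierarchy the
#' SYM-like (and TIM/TVM/K81-like) models are structurally unreachable.
#'
#' @param hierarchy A hierarchy tibble, as [default_hierarchy()].
#' @return Sorted character vector of reachable base models.
#' @export
hlrt_reachable_models <- function(hierarchy = default_hierarchy()) {
  outs <- c(hierarchy$on_accept, hierarchy$on_reject)
  sort(unique(outs[!startsWith(outs, "node:")]))
}

#' Model selection by hierarchical likelihood-ratio tests
#'
#' Walks the hierarchy's decision tree over the fit table: each node
#' compares a nested model pair at significance level `alpha` (default
#' 0.01), rejection moving towards the more complex model.  After the
#' base model is settled, gamma rate heterogeneity and then invariable
#' sites are tested as mixed boundary hypotheses (df 1).  The terminal
#' model and the full ordered test trace are returned.
#'
#' @inheritParams ic_select
#' @param alpha Significance level for rejecting the null model.
#' @param hierarchy Hierarchy tibble, as [default_hierarchy()].
#' @return A `selection_result` whose `trace` lists every test performed.
#' @export
hlrt_select <- function(fits, alpha = 0.01, hierarchy = default_hierarchy()) {
  lnL_of <- function(model) {
    i <- match(model, fits$model)
    if (is.na(i) || !is.finite(fits$lnL[i]) || !fits$converged[i]) {
      stop("hLRT requires a converged fit for model '", model, "'",
           call. = FALSE)
    }
    fits$lnL[i]
  }
  trace <- list()
  run_test <- function(label, null, alt, df, mixed) {
    res <- lrt(lnL_of(null), lnL_of(alt), df, mixed)
    trace[[length(trace) + 1]] <<- tibble::tibble(
      test = label, null = null, alt = alt, delta = res$delta,
      df = df, mixed = mixed, p_value = res$p_value,
      rejected = res$p_value < alpha
    )
    res$p_value < alpha
  }
  node_id <- attr(hierarchy, "start")
  base <- NULL
  while (is.null(base)) {
    node <- hierarchy[hierarchy$id == node_id, ]
    if (nrow(node) != 1) stop("bad hierarchy node: ", node_id, call. = FALSE)
    rejected <- run_test(node$id, node$null, node$alt, node$df, mixed = FALSE)
    nxt <- if (rejected) node$on_reject else node$on_accept
    if (startsWith(nxt, "node:")) {
      node_id <- sub("^node:", "", nxt)
    } else {
      base <- nxt
    }
  }
  has_gamma <- run_test("gamma", base, paste0(base, "+G"), 1L, mixed = TRUE)
  g_suffix <- if (has_gamma) "+G" else ""
  has_inv <- run_test("inv", paste0(base, g_suffix),
                      paste0(base, "+I", g_suffix), 1L, mixed = TRUE)
  chosen <- paste0(base, if (has_inv) "+I" else "", g_suffix)
  selection_result("hLRT", chosen, trace = dplyr::bind_rows(trace))
}

#' Decision-theoretic model selection
#'
#' Implements BIC-weighted branch-length risk minimisation: candidate
#' models receive posterior weights
#' `w_j = exp(-(BIC_j - BIC_min)/2) / sum_k exp(-(BIC_k - BIC_min)/2)`,
#' and each model's risk is the weighted sum of Euclidean distances
#' between its branch-length vector and every other model's,
#' `R_i = sum_j ||B_i - B_j|| w_j`.  The minimal-risk model is selected;
#' ties are broken by fewer free parameters.  All fits must carry
#' branch-length vectors on the same edge indexing (guaranteed by
#' [fit_candidate_models()]).
#'
#' @inheritParams ic_select
#' @return A `selection_result` with weights and risks in `scores`.
#' @export
dt_select <- function(fits, n_sites = attr(fits, "n_sites")) {
  force(n_sites)
  fits <- usable_fits(fits)
  B <- do.call(rbind, fits$edge_lengths)
  if (anyNA(B)) stop("missing branch-length vectors", call. = FALSE)
  bic_scores <- bic(fits$lnL, fits$free_params, n_sites)
  w <- exp(-(bic_scores - min(bic_scores)) / 2)
  w <- w / sum(w)
  D <- as.matrix(stats::dist(B))
  risk <- as.vector(D %*% w)
  scores <- tibble::tibble(model = fits$model,
                           free_params = fits$free_params,
                           bic = bic_scores, weight = w, score = risk)
  pick <- argmin_model(scores)
  selection_result("DT", pick$model, scores = scores, n_tied = pick$n_tied)
}

#' Apply the four selection criteria to one fit table
#'
#' @inheritParams ic_select
#' @inheritParams hlrt_select
#' @param criteria Criteria to apply, a subset of
#'   `c("hLRT", "AIC", "AICc", "BIC", "DT")`.
#' @return A tibble with columns `criterion` and `model` (one row per
#'   criterion) and the full `selection_result` objects in the `result`
#'   list column.
#' @export
select_models <- function(fits, n_sites = attr(fits, "n_sites"),
                          alpha = 0.01, hierarchy = default_hierarchy(),
                          criteria = c("hLRT", "AIC", "BIC", "DT")) {
  allowed <- c("hLRT", "AIC", "AICc", "BIC", "DT")
  stopifnot(all(criteria %in% allowed))
  results <- lapply(criteria, function(cr) {
    switch(cr,
      hLRT = hlrt_select(fits, alpha = alpha, hierarchy = hierarchy),
      AIC = ic_select(fits, "AIC", n_sites),
      AICc = ic_select(fits, "AICc", n_sites),
      BIC = ic_select(fits, "BIC", n_sites),
      DT = dt_select(fits, n_sites)
    )
  })
  tibble::tibble(
    criterion = criteria,
    model = vapply(results, `[[`, character(1), "model"),
    result = results
  )
}
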