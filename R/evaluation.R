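# Performance statistics over replicate selections: accuracy, precision,
# dissimilarity, agreement profiles, model-bias composition tables with
# chi-square homogeneity tests, and randomized-block ANOVA with LSD.

#' Accuracy of a criterion over replicates
#'
#' Percentage of replicate datasets for which the criterion selected the
#' generating (true) model: `Number_matched / Number_test x 100`.
#'
#' @param selections Character vector of chosen model names, one per
#'   replicate.
#' @param true_model Name of the generating model.
#' @return Percentage in `[0, 100]`.
#' @examples
#' accuracy(c("JC", "JC", "HKY"), "JC")  # 66.67
#' @export
accuracy <- function(selections, true_model) {
  stopifnot(length(selections) >= 1)
  true_model <- model_spec(true_model)$name
  mean(selections == true_model) * 100
}

#' Precision of a criterion over replicates
#'
#' The number of distinct best-fit models selected across a replicate set,
#' each model counted once regardless of how often it was selected.
#' Smaller is more precise.
#'
#' @param selections Character vector of chosen model names.
#' @return Integer count of distinct models.
#' @export
precision_count <- function(selections) {
  stopifnot(length(selections) >= 1)
  length(unique(selections))
}

#' Dissimilarity between two criteria
#'
#' `(N - m) / N x 100`, where `m` counts replicates on which both criteria
#' chose the identical model.  Symmetric in its arguments.
#'
#' @param sel1,sel2 Equal-length character vectors of chosen models,
#'   aligned by replicate dataset.
#' @return Percentage in `[0, 100]`.
#' @export
dissimilarity <- function(sel1, sel2) {
  if (length(sel1) != length(sel2)) {
    stop("selection vectors must have equal length", call. = FALSE)
  }
  stopifnot(length(sel1) >= 1)
  mean(sel1 != sel2) * 100
}

#' Agreement profile of the four criteria
#'
#' For each replicate, counts how many distinct models the criteria chose
#' (1 = all agree, up to the number of criteria), and returns the
#' percentage of replicates in each count class.  Percentages sum to 100.
#'
#' @param selections A data frame or matrix with one column per criterion
#'   and one row per replicate dataset.
#' @return A tibble with columns `n_models` (1..ncol) and `pct`.
#' @export
agreement_profile <- function(selections) {
  m <- as.matrix(selections)
  stopifnot(nrow(m) >= 1, ncol(m) >= 2)
  counts <- apply(m, 1, function(row) length(unique(row)))
  k <- ncol(m)
  tibble::tibble(
    n_models = seq_len(k),
    pct = vapply(seq_len(k), function(i) mean(counts == i) * 100, numeric(1))
  )
}

# r x k chi-square homogeneity test on a count table; all-zero columns are
# dropped (they carry no information and break the expected-count formula).
chi2_homogeneity <- function(counts) {
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2 || nrow(counts) < 2) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  test <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(test$statistic), df = unname(test$parameter),
       p_value = unname(test$p.value))
}

# pool zero-total columns of an ordered count table into the nearest
# lower non-empty class (or the nearest higher for the first column).
pool_zero_columns <- function(counts) {
  repeat {
    zero <- which(colSums(counts) == 0)
    if (!length(zero) || ncol(counts) <= 2) break
    j <- zero[1]
    target <- if (j > 1) j - 1 else 2
    counts[, target] <- counts[, target] + counts[, j]
    counts <- counts[, -j, drop = FALSE]
  }
  counts
}

#' Model-bias composition tables and homogeneity tests
#'
#' Tabulates, per criterion, the composition of selected models either by
#' rate-heterogeneity category (4 classes, df 3) or by number of free
#' parameters (11 classes, df 10), and compares the criteria with the
#' chi-square homogeneity test: one overall r x k test plus all pairwise
#' 2 x k comparisons, judged against the Bonferroni-corrected level
#' `alpha / choose(r, 2)` (0.05 / 6 = 0.0083 for four criteria).  By
#' default only correct recoveries (selection equal to the generating
#' model) enter the table; `recovered_only = FALSE` tabulates all
#' selections instead.
#'
#' @param selections Tibble with columns `criterion`, `model` and
#'   `true_model` (one row per dataset x criterion).
#' @param classification `"category"` (4 classes) or `"free_params"`
#'   (11 classes; empty classes pooled into the adjacent class).
#' @param recovered_only Restrict to correct recoveries (default).
#' @param alpha Family-wise level for the pairwise comparisons.
#' @return A list with `counts` (criteria x classes matrix), `overall`
#'   (statistic, df, p_value) and `pairwise` (tibble with one row per
#'   criterion pair, including the Bonferroni threshold and significance
#'   flag).
#' @export
model_bias_tables <- function(selections,
                              classification = c("category", "free_params"),
                              recovered_only = TRUE, alpha = 0.05) {
  classification <- match.arg(classification)
  stopifnot(all(c("criterion", "model", "true_model") %in% names(selections)))
  if (recovered_only) {
    selections <- selections[selections$model == selections$true_model, ]
  }
  criteria <- unique(selections$criterion)
  if (classification == "category") {
    classes <- c("base", "base+I", "base+G", "base+I+G")
    cls <- vapply(selections$model, model_category, character(1))
  } else {
    classes <- as.character(0:10)
    cls <- as.character(vapply(selections$model, free_parameters, integer(1)))
  }
  counts <- table(factor(selections$criterion, levels = criteria),
                  factor(cls, levels = classes))
  counts <- matrix(counts, nrow = length(criteria),
                   dimnames = list(criteria, classes))
  test_counts <- if (classification == "free_params") {
    pool_zero_columns(counts)
  } else {
    counts
  }
  overall <- chi2_homogeneity(test_counts)
  pairs <- utils::combn(criteria, 2, simplify = FALSE)
  threshold <- alpha / length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    res <- chi2_homogeneity(test_counts[pr, , drop = FALSE])
    tibble::tibble(
      criterion1 = pr[1], criterion2 = pr[2],
      statistic = res$statistic, df = res$df, p_value = res$p_value,
      threshold = threshold, significant = res$p_value < threshold
    )
  })
  list(counts = counts, overall = overall, pairwise = pairwise)
}

#' Randomized-block ANOVA with LSD pairwise comparisons
#'
#' Standard two-way randomised-block decomposition, treatments being the
#' selection criteria and blocks the generating models, fitted with
#' [stats::aov()].  Fisher's LSD compares treatment means on the error
#' mean square: a pair differs when the absolute mean difference exceeds
#' `t(1 - alpha/2, df_error) * sqrt(2 MSE / b)` with `b` blocks.  LSD
#' decisions are reported both raw and gated on a significant omnibus F.
#'
#' @param data A data frame with columns `value`, `treatment`, `block`;
#'   the design must be complete (every treatment in every block).
#' @param alpha Significance level (default 0.01).
#' @return A list with `anova` (tibble: term, df, sumsq, meansq, statistic,
#'   p_value), `treatment_means`, `lsd` (pairwise tibble), `omnibus_p`,
#'   and `mse`.
#' @export
randomized_block_anova <- function(data, alpha = 0.01) {
  stopifnot(all(c("value", "treatment", "block") %in% names(data)))
  data$treatment <- factor(data$treatment)
  data$block <- factor(data$block)
  tab <- table(data$treatment, data$block)
  if (any(tab != 1)) {
    stop("design must be complete: one value per treatment x block",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ treatment + block, data = data)
  sm <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(sm)),
    df = sm$Df, sumsq = sm$`Sum Sq`, meansq = sm$`Mean Sq`,
    statistic = sm$`F value`, p_value = sm$`Pr(>F)`
  )
  mse <- anova_tbl$meansq[anova_tbl$term == "Residuals"]
  df_err <- anova_tbl$df[anova_tbl$term == "Residuals"]
  omnibus_p <- anova_tbl$p_value[anova_tbl$term == "treatment"]
  b <- nlevels(data$block)
  means <- tapply(data$value, data$treatment, mean)
  lsd_crit <- stats::qt(1 - alpha / 2, df_err) * sqrt(2 * mse / b)
  prs <- utils::combn(names(means), 2, simplify = FALSE)
  lsd <- purrr::map_dfr(prs, function(pr) {
    diff <- abs(means[pr[1]] - means[pr[2]])
    tibble::tibble(
      treatment1 = pr[1], treatment2 = pr[2],
      mean_diff = unname(diff), lsd = lsd_crit,
      significant = unname(diff > lsd_crit),
      significant_gated = unname(diff > lsd_crit) && omnibus_p < alpha
    )
  })
  list(anova = anova_tbl,
       treatment_means = tibble::tibble(treatment = names(means),
                                        mean = as.numeric(means)),
       lsd = lsd, omnibus_p = omnibus_p, mse = mse)
}
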