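# Tidiers and plots for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a candidate-model fit table
#'
#' Drops the list columns and adds the AIC/BIC scores, one row per model.
#'
#' @param x A `model_fits` tibble.
#' @param ... Unused.
#' @return A plain tibble with columns `model`, `free_params`, `category`,
#'   `lnL`, `aic`, `bic`, `converged`.
#' @method tidy model_fits
#' @export
tidy.model_fits <- function(x, ...) {
  n <- attr(x, "n_sites")
  tibble::tibble(
    model = x$model, free_params = x$free_params, category = x$category,
    lnL = x$lnL, aic = aic(x$lnL, x$free_params),
    bic = bic(x$lnL, x$free_params, n), converged = x$converged
  )
}

#' @rdname tidy.model_fits
#' @method glance model_fits
#' @export
glance.model_fits <- function(x, ...) {
  td <- tidy.model_fits(x)
  tibble::tibble(
    n_models = nrow(td),
    n_sites = attr(x, "n_sites"),
    n_converged = sum(td$converged),
    best_aic = td$model[which.min(td$aic)],
    best_bic = td$model[which.min(td$bic)]
  )
}

#' Tidy a condition result
#'
#' Extracts one of the evaluation tables as a plain tibble.
#'
#' @param x A `condition_result` or `codon_condition_result`.
#' @param table One of `"accuracy"`, `"precision"`, `"dissimilarity"`,
#'   `"agreement"`, `"agreement_mean"`, `"selections"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy condition_result
#' @export
tidy.condition_result <- function(x, table = "accuracy", ...) {
  choices <- c("accuracy", "precision", "dissimilarity", "agreement",
               "agreement_mean", "selections")
  table <- match.arg(table, choices)
  out <- x[[table]]
  if (is.null(out)) stop("result has no '", table, "' table", call. = FALSE)
  tibble::as_tibble(out)
}

#' @rdname tidy.condition_result
#' @method tidy codon_condition_result
#' @export
tidy.codon_condition_result <- function(x, table = "dissimilarity", ...) {
  tidy.condition_result(x, table = table, ...)
}

#' @rdname tidy.condition_result
#' @method glance condition_result
#' @export
glance.condition_result <- function(x, ...) {
  acc <- x$accuracy |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(value = mean(.data$accuracy), .groups = "drop")
  out <- tibble::as_tibble(
    stats::setNames(as.list(acc$value),
                    paste0("mean_accuracy_", acc$criterion)))
  diss <- x$dissimilarity |>
    dplyr::group_by(.data$criterion1, .data$criterion2) |>
    dplyr::summarise(value = mean(.data$dissimilarity), .groups = "drop")
  diss_cols <- stats::setNames(
    as.list(diss$value),
    paste0("mean_dissimilarity_", diss$criterion1, "_", diss$criterion2))
  dplyr::bind_cols(
    tibble::tibble(condition = x$condition$condition,
                   n_generating = nrow(x$generating),
                   n_replicates = x$condition$n_replicates),
    out, tibble::as_tibble(diss_cols)
  )
}

model_factor <- function(models) {
  levels <- generating_models()$model
  extra <- setdiff(unique(models), levels)
  factor(models, levels = c(levels, sort(extra)))
}

#' Plot per-model performance of a condition result
#'
#' Line charts over the generating models: accuracy or precision per
#' criterion, or pairwise dissimilarity per criterion pair.
#'
#' @param object A `condition_result`.
#' @param type `"accuracy"`, `"precision"` or `"dissimilarity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot condition_result
#' @export
autoplot.condition_result <- function(object,
                                      type = c("accuracy", "precision",
                                               "dissimilarity"), ...) {
  type <- match.arg(type)
  if (type == "dissimilarity") {
    df <- object$dissimilarity |>
      dplyr::mutate(pair = paste(.data$criterion1, .data$criterion2,
                                 sep = "-"),
                    true_model = model_factor(.data$true_model))
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$true_model, y = .data$dissimilarity,
      colour = .data$pair, group = .data$pair)) +
      ggplot2::labs(y = "dissimilarity (%)", colour = "pair")
  } else {
    df <- tidy.condition_result(object, type) |>
      dplyr::mutate(true_model = model_factor(.data$true_model))
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$true_model, y = .data[[type]],
      colour = .data$criterion, group = .data$criterion)) +
      ggplot2::labs(y = if (type == "accuracy") "accuracy (%)" else
        "distinct models selected", colour = "criterion")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "generating model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Stacked-bar chart of recovered model categories per criterion
#'
#' Shows the composition of (by default correctly) recovered models across
#' the four rate-heterogeneity categories, one bar per criterion.
#'
#' @param result A `condition_result`.
#' @return A ggplot object.
#' @export
plot_model_bias <- function(result) {
  counts <- result$bias_category$counts
  df <- tibble::as_tibble(as.table(counts), .name_repair = "minimal")
  names(df) <- c("criterion", "category", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$count,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::labs(y = "share of recovered models (%)", x = NULL,
                  fill = "category") +
    ggplot2::theme_minimal()
}
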