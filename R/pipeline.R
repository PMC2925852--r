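# End-to-end orchestration: built-in study conditions, the
# simulate -> NJ -> fit -> select -> evaluate pipeline for nucleotide and
# codon simulations, with per-dataset caching and seed bookkeeping.

#' The built-in simulation conditions
#'
#' The 14 nucleotide simulation conditions of the study: parameter sets A
#' and B crossed with ultrametric guide trees of heights 0.7/0.5/0.3/0.1
#' (30 taxa), taxon numbers 22/30/50, one non-clock 22-taxon tree, and
#' sequence lengths 300/1000/2000; 100 replicates per generating model.
#' Condition III-1 is an independent second run of the II-1 generating
#' process (the original used a different simulation program implementing
#' the same generative model).
#'
#' @return A tibble with columns `condition`, `parameter_set`, `tree`,
#'   `height`, `ntaxa`, `n_sites`, `n_replicates`.
#' @export
simulation_conditions <- function() {
  tibble::tribble(
    ~condition, ~parameter_set, ~tree,        ~height, ~ntaxa, ~n_sites,
    "I-1",   "A", "ultrametric", 0.7, 30L, 1000L,
    "I-2",   "A", "ultrametric", 0.5, 30L, 1000L,
    "I-3",   "A", "ultrametric", 0.3, 30L, 1000L,
    "I-4",   "A", "ultrametric", 0.1, 30L, 1000L,
    "I-5",   "B", "ultrametric", 0.7, 30L, 1000L,
    "I-6",   "B", "ultrametric", 0.5, 30L, 1000L,
    "I-7",   "B", "ultrametric", 0.3, 30L, 1000L,
    "I-8",   "B", "ultrametric", 0.1, 30L, 1000L,
    "II-1",  "A", "ultrametric", 0.5, 22L, 1000L,
    "II-2",  "A", "ultrametric", 0.5, 50L, 1000L,
    "III-1", "A", "ultrametric", 0.5, 22L, 1000L,
    "IV-1",  "A", "nonclock",    NA,  22L, 1000L,
    "V-1",   "A", "ultrametric", 0.5, 30L, 300L,
    "V-2",   "A", "ultrametric", 0.5, 30L, 2000L
  ) |>
    dplyr::mutate(n_replicates = 100L)
}

# n reproducible sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2147483646L, n))
}

criterion_pairs <- function(criteria) {
  utils::combn(criteria, 2, simplify = FALSE)
}

# Shared evaluation of a long selection table (dataset_id, true_model,
# replicate, criterion, model).  `full = FALSE` restricts to the agreement
# and dissimilarity summaries (used when the true model is outside the
# candidate set).
evaluate_selections <- function(selections, criteria, full = TRUE) {
  wide <- tidyr::pivot_wider(
    selections, names_from = "criterion", values_from = "model")

  agreement_by_model <- wide |>
    dplyr::group_by(.data$true_model) |>
    dplyr::group_modify(~ agreement_profile(.x[, criteria])) |>
    dplyr::ungroup()
  agreement_mean <- agreement_by_model |>
    dplyr::group_by(.data$n_models) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop")

  diss <- purrr::map_dfr(criterion_pairs(criteria), function(pr) {
    wide |>
      dplyr::group_by(.data$true_model) |>
      dplyr::summarise(
        dissimilarity = dissimilarity(.data[[pr[1]]], .data[[pr[2]]]),
        n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(criterion1 = pr[1], criterion2 = pr[2], .before = 1)
  })

  out <- list(selections = wide, selections_long = selections,
              agreement = agreement_by_model,
              agreement_mean = agreement_mean,
              dissimilarity = diss)
  if (!full) return(out)

  out$accuracy <- selections |>
    dplyr::group_by(.data$true_model, .data$criterion) |>
    dplyr::summarise(
      accuracy = accuracy(.data$model, .data$true_model[1]),
      n_replicates = dplyr::n(), .groups = "drop")
  out$precision <- selections |>
    dplyr::group_by(.data$true_model, .data$criterion) |>
    dplyr::summarise(precision = precision_count(.data$model),
                     .groups = "drop")
  out$bias_category <- model_bias_tables(selections, "category")
  out$bias_free_params <- model_bias_tables(selections, "free_params")

  n_models <- length(unique(selections$true_model))
  if (n_models >= 2 && length(criteria) >= 2) {
    out$anova_accuracy <- randomized_block_anova(
      data.frame(value = out$accuracy$accuracy,
                 treatment = out$accuracy$criterion,
                 block = out$accuracy$true_model))
    out$anova_precision <- randomized_block_anova(
      data.frame(value = out$precision$precision,
                 treatment = out$precision$criterion,
                 block = out$precision$true_model))
    out$anova_dissimilarity <- randomized_block_anova(
      data.frame(value = diss$dissimilarity,
                 treatment = paste(diss$criterion1, diss$criterion2,
                                   sep = "-"),
                 block = diss$true_model))
  }
  out
}

read_cached_dataset <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_cached_dataset <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

init_output_dir <- function(output_dir, config) {
  dir.create(file.path(output_dir, "datasets"), recursive = TRUE,
             showWarnings = FALSE)
  manifest_path <- file.path(output_dir, "manifest.json")
  config_hash <- rlang::hash(config)
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    if (!identical(manifest$config_hash, config_hash)) {
      stop("output_dir holds results from a different configuration; ",
           "use a fresh directory", call. = FALSE)
    }
  } else {
    jsonlite::write_json(
      c(config, list(config_hash = config_hash,
                     package_version = as.character(
                       utils::packageVersion("modselsim")))),
      manifest_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(config_hash)
}

#' Run one simulation condition end to end
#'
#' For each generating model x replicate: simulate an alignment along the
#' condition's guide tree, build the NJ starting tree, fit the candidate
#' set, and apply the selection criteria; then compute all evaluation
#' summaries.  The guide tree is drawn once per condition.  Sub-seeds for
#' the tree and every dataset are derived from `seed` by a fixed counter
#' scheme, so any single dataset is reproducible in isolation and
#' identical seeds give identical results.
#'
#' @param condition A condition id from [simulation_conditions()] (e.g.
#'   `"I-2"`) or a one-row data frame in the same format.
#' @param generating Tibble of generating models (default
#'   [generating_models()]; subset for scaled-down runs).
#' @param n_replicates,ntaxa,n_sites Optional overrides of the condition's
#'   replicate count and problem size; recorded in the result.
#' @param candidates Tibble of candidate models to fit (default the full
#'   56-model set).
#' @param seed Master seed (integer).
#' @param criteria Selection criteria to apply.
#' @param alpha hLRT significance level.
#' @param hierarchy hLRT hierarchy (see [default_hierarchy()]).
#' @param control Optimisation control passed to [fit_model()].
#' @param output_dir Optional directory for cached per-dataset selections
#'   and summary TSVs; reruns skip completed datasets and refuse to mix
#'   configurations.
#' @param verbose Print per-dataset progress.
#' @return A `condition_result` list: the resolved condition, guide tree,
#'   wide and long selection tables, and the evaluation summaries
#'   (`accuracy`, `precision`, `dissimilarity`, `agreement`,
#'   `agreement_mean`, `bias_category`, `bias_free_params`, and the
#'   randomized-block ANOVA tables when the design permits).
#' @export
run_condition <- function(condition = "I-2",
                          generating = generating_models(),
                          n_replicates = NULL, ntaxa = NULL, n_sites = NULL,
                          candidates = candidate_models(),
                          seed = 1L,
                          criteria = c("hLRT", "AIC", "BIC", "DT"),
                          alpha = 0.01, hierarchy = default_hierarchy(),
                          control = phangorn::pml.control(epsilon = 1e-8,
                                                          maxit = 10,
                                                          trace = 0),
                          output_dir = NULL, verbose = FALSE) {
  cond <- if (is.character(condition)) {
    row <- simulation_conditions()[simulation_conditions()$condition ==
                                     condition, ]
    if (nrow(row) != 1) stop("unknown condition: ", condition, call. = FALSE)
    row
  } else {
    tibble::as_tibble(condition)
  }
  if (!is.null(n_replicates)) cond$n_replicates <- as.integer(n_replicates)
  if (!is.null(ntaxa)) cond$ntaxa <- as.integer(ntaxa)
  if (!is.null(n_sites)) cond$n_sites <- as.integer(n_sites)

  params <- parameter_set(cond$parameter_set)
  n_models <- nrow(generating)
  n_rep <- cond$n_replicates
  seeds <- derive_seeds(seed, 1L + n_models * n_rep)
  tree <- if (cond$tree == "nonclock") {
    build_nonclock_tree(seed = seeds[1])
  } else {
    scale_to_height(
      simulate_birth_death_tree(cond$ntaxa, seed = seeds[1]), cond$height)
  }

  cache_dir <- NULL
  if (!is.null(output_dir)) {
    config <- list(condition = as.list(cond), seed = seed,
                   generating = generating$model, criteria = criteria,
                   alpha = alpha, candidates = candidates$model)
    init_output_dir(output_dir, config)
    cache_dir <- file.path(output_dir, "datasets")
  }

  selections <- purrr::map_dfr(seq_len(n_models), function(i) {
    true_model <- generating$model[i]
    purrr::map_dfr(seq_len(n_rep), function(j) {
      ds_id <- sprintf("%s_%s_%03d", cond$condition,
                       gsub("[+]", "", true_model), j)
      if (!is.null(cache_dir)) {
        cached <- file.path(cache_dir, paste0(ds_id, ".tsv"))
        if (file.exists(cached)) return(read_cached_dataset(cached))
      }
      ds_seed <- seeds[1L + (i - 1L) * n_rep + j]
      aln <- simulate_alignment(tree, true_model, params, cond$n_sites,
                                seed = ds_seed)
      fits <- fit_candidate_models(aln, models = candidates,
                                   control = control)
      sel <- select_models(fits, alpha = alpha, hierarchy = hierarchy,
                           criteria = criteria)
      if (verbose) {
        message(ds_id, ": ",
                paste(sel$criterion, sel$model, sep = "=", collapse = " "))
      }
      rows <- tibble::tibble(
        dataset_id = ds_id, true_model = true_model, replicate = j,
        criterion = sel$criterion, model = sel$model)
      if (!is.null(cache_dir)) write_cached_dataset(rows, cached)
      rows
    })
  })

  ev <- evaluate_selections(selections, criteria, full = TRUE)
  result <- c(
    list(condition = cond, generating = generating, seed = seed,
         criteria = criteria, tree = tree),
    ev
  )
  class(result) <- "condition_result"
  if (!is.null(output_dir)) write_result_tables(result, output_dir)
  result
}

write_result_tables <- function(result, output_dir) {
  wt <- function(x, name) {
    utils::write.table(x, file.path(output_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(result$selections, "selections")
  for (nm in c("accuracy", "precision", "dissimilarity", "agreement",
               "agreement_mean")) {
    if (!is.null(result[[nm]])) wt(result[[nm]], nm)
  }
  invisible(output_dir)
}

#' @export
print.condition_result <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("<condition_result> %s: %d generating models x %d replicates",
              cond$condition, nrow(x$generating), cond$n_replicates),
      sprintf("(%d taxa, %d sites)\n", cond$ntaxa, cond$n_sites))
  if (!is.null(x$accuracy)) {
    acc <- x$accuracy |>
      dplyr::group_by(.data$criterion) |>
      dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                       .groups = "drop")
    cat("mean accuracy (%):",
        paste(sprintf("%s=%.1f", acc$criterion, acc$mean_accuracy),
              collapse = "  "), "\n")
  }
  cat("agreement profile (%):",
      paste(sprintf("%d:%.1f", x$agreement_mean$n_models,
                    x$agreement_mean$pct), collapse = "  "), "\n")
  invisible(x)
}

#' Run the codon-model condition end to end
#'
#' Simulates datasets under the GY94 codon model crossed with each
#' generating GTR-family model's parameters, then runs the same NJ ->
#' fit -> select path on the resulting nucleotide alignments.  Because the
#' generating model lies outside the candidate set, evaluation is
#' restricted to the agreement profile and pairwise dissimilarity: there
#' is deliberately no accuracy or precision table in the result.
#'
#' @inheritParams run_condition
#' @param omega Nonsynonymous/synonymous rate ratio (default 0.016).
#' @param length_nt Alignment length in nucleotides (default 999).
#' @param mutation_rate Branch-length scalar (default 0.001).
#' @param ntaxa,height Guide-tree settings: a birth-death tree of `ntaxa`
#'   tips scaled to `height` (defaults 30 and 0.5).
#' @param n_replicates Replicates per generating model (default 100).
#' @return A `codon_condition_result` list with the selection tables,
#'   agreement profile and dissimilarity summaries.
#' @export
run_codon_condition <- function(generating = generating_models(),
                                n_replicates = 100L,
                                omega = 0.016, length_nt = 999L,
                                mutation_rate = 0.001,
                                ntaxa = 30L, height = 0.5,
                                candidates = candidate_models(),
                                seed = 1L,
                                criteria = c("hLRT", "AIC", "BIC", "DT"),
                                alpha = 0.01,
                                hierarchy = default_hierarchy(),
                                control = phangorn::pml.control(
                                  epsilon = 1e-8, maxit = 10, trace = 0),
                                verbose = FALSE) {
  params <- parameter_set("A")
  n_models <- nrow(generating)
  seeds <- derive_seeds(seed, 1L + n_models * n_replicates)
  tree <- scale_to_height(
    simulate_birth_death_tree(ntaxa, seed = seeds[1]), height)

  selections <- purrr::map_dfr(seq_len(n_models), function(i) {
    config <- codon_sim_config(generating$model[i], params, omega = omega,
                               length_nt = length_nt,
                               mutation_rate = mutation_rate)
    purrr::map_dfr(seq_len(n_replicates), function(j) {
      ds_id <- sprintf("VI_%s_%03d", gsub("[+]", "", generating$model[i]), j)
      ds_seed <- seeds[1L + (i - 1L) * n_replicates + j]
      aln <- simulate_codon_alignment(tree, config, seed = ds_seed)
      fits <- fit_candidate_models(aln, models = candidates,
                                   control = control)
      sel <- select_models(fits, alpha = alpha, hierarchy = hierarchy,
                           criteria = criteria)
      if (verbose) {
        message(ds_id, ": ",
                paste(sel$criterion, sel$model, sep = "=", collapse = " "))
      }
      tibble::tibble(
        dataset_id = ds_id, true_model = generating$model[i],
        replicate = j, criterion = sel$criterion, model = sel$model)
    })
  })

  ev <- evaluate_selections(selections, criteria, full = FALSE)
  result <- c(
    list(config = list(omega = omega, length_nt = length_nt,
                       mutation_rate = mutation_rate, ntaxa = ntaxa,
                       height = height, n_replicates = n_replicates),
         generating = generating, seed = seed, criteria = criteria,
         tree = tree),
    ev
  )
  class(result) <- "codon_condition_result"
  result
}

#' @export
print.codon_condition_result <- function(x, ...) {
  cat(sprintf(
    "<codon_condition_result> GY94 x %d generating models x %d replicates\n",
    nrow(x$generating), x$config$n_replicates))
  cat("agreement profile (%):",
      paste(sprintf("%d:%.1f", x$agreement_mean$n_models,
                    x$agreement_mean$pct), collapse = "  "), "\n")
  invisible(x)
}
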