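# Performance statistics and their supporting tests.

test_that("accuracy, precision and dissimilarity evaluate exactly", {
  sel <- c(rep("JC", 46), rep("HKY", 54))
  expect_equal(accuracy(sel, "JC"), 46)
  expect_equal(accuracy(rep("GTR", 10), "JC"), 0)
  expect_equal(accuracy(rep("JC", 10), "JC"), 100)

  expect_equal(precision_count(rep("JC", 100)), 1)
  expect_equal(precision_count(c("A", "A", "B")), 2)

  expect_equal(dissimilarity(sel, sel), 0)
  expect_equal(dissimilarity(rep("JC", 10), rep("HKY", 10)), 100)
  s2 <- c(rep("JC", 97), rep("GTR", 3))
  expect_equal(dissimilarity(rep("JC", 100), s2), 3)
  expect_error(dissimilarity(c("a", "b"), "a"), "equal length")
})

test_that("dissimilarity is symmetric and bounded on random selections", {
  withr::with_seed(41, {
    models <- candidate_models()$model
    for (i in 1:20) {
      a <- sample(models, 50, replace = TRUE)
      b <- sample(models, 50, replace = TRUE)
      d1 <- dissimilarity(a, b)
      expect_identical(d1, dissimilarity(b, a))
      expect_gte(d1, 0)
      expect_lte(d1, 100)
    }
  })
})

test_that("agreement profiles partition the replicates", {
  all_agree <- data.frame(h = rep("JC", 5), a = rep("JC", 5),
                          b = rep("JC", 5), d = rep("JC", 5))
  expect_equal(agreement_profile(all_agree)$pct, c(100, 0, 0, 0))

  withr::with_seed(43, {
    models <- candidate_models()$model
    sel <- as.data.frame(replicate(4, sample(models, 30, replace = TRUE)))
    prof <- agreement_profile(sel)
    expect_equal(sum(prof$pct), 100, tolerance = 1e-9)
    # "one model" percentage = 100 - percentage with any disagreement,
    # cross-checked against pairwise matches
    any_disagree <- mean(apply(sel, 1, function(r) length(unique(r)) > 1))
    expect_equal(prof$pct[1], 100 - any_disagree * 100, tolerance = 1e-9)
  })
})

test_that("perfect accuracy forces perfect precision", {
  sel <- rep("HKY+G", 20)
  expect_equal(accuracy(sel, "HKY+G"), 100)
  expect_equal(precision_count(sel), 1)
})

test_that("model-bias chi-square tests match the expected-count formula", {
  # two criteria with known category counts over JC/JC+I/JC+G/JC+I+G
  counts_x <- c(10, 5, 3, 2)
  counts_y <- c(4, 6, 8, 2)
  mods <- c("JC", "JC+I", "JC+G", "JC+I+G")
  sel <- rbind(
    data.frame(criterion = "X", model = rep(mods, counts_x)),
    data.frame(criterion = "Y", model = rep(mods, counts_y))
  )
  sel$true_model <- sel$model   # every row counts as a recovery
  mb <- model_bias_tables(sel, "category")
  expect_equal(unname(mb$counts["X", ]), counts_x)
  # chi-square homogeneity oracle: sum (O - E)^2 / E on the 2 x 4 table
  tab <- rbind(counts_x, counts_y)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(mb$overall$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(mb$overall$df, 3)

  # identical compositions: statistic 0, p = 1
  sel2 <- sel
  sel2$criterion <- rep(c("X", "Y"), each = nrow(sel) / 2)
  sel2$model <- rep(rep(mods, counts_x), 2)
  sel2$true_model <- sel2$model
  mb2 <- model_bias_tables(sel2, "category")
  expect_equal(mb2$overall$statistic, 0, tolerance = 1e-12)
  expect_equal(mb2$overall$p_value, 1)
})

test_that("pairwise bias comparisons use the Bonferroni threshold", {
  withr::with_seed(47, {
    mods <- generating_models()$model
    sel <- data.frame(
      criterion = rep(c("hLRT", "AIC", "BIC", "DT"), each = 60),
      model = sample(mods, 240, replace = TRUE)
    )
    sel$true_model <- sel$model
    mb <- model_bias_tables(sel, "category")
    expect_equal(nrow(mb$pairwise), 6)
    expect_equal(unique(mb$pairwise$threshold), 0.05 / 6)
    # free-parameter classification pools empty classes before testing
    mb11 <- model_bias_tables(sel, "free_params")
    expect_equal(ncol(mb11$counts), 11)
    expect_true(all(colSums(mb11$counts) >= 0))
  })
})

test_that("randomized-block ANOVA matches the sums-of-squares oracle", {
  # small complete design: 3 treatments x 4 blocks
  vals <- matrix(c(12, 15, 19,
                   10, 14, 18,
                   13, 16, 21,
                   9, 12, 16), nrow = 4, byrow = TRUE)
  df <- data.frame(
    value = as.vector(t(vals)),
    treatment = rep(c("T1", "T2", "T3"), times = 4),
    block = rep(paste0("B", 1:4), each = 3)
  )
  res <- randomized_block_anova(df, alpha = 0.05)

  # independent decomposition from the textbook formulas
  grand <- mean(df$value)
  t_means <- tapply(df$value, df$treatment, mean)
  b_means <- tapply(df$value, df$block, mean)
  ss_t <- 4 * sum((t_means - grand)^2)
  ss_b <- 3 * sum((b_means - grand)^2)
  ss_tot <- sum((df$value - grand)^2)
  ss_e <- ss_tot - ss_t - ss_b
  ms_t <- ss_t / 2
  ms_e <- ss_e / 6
  a <- res$anova
  expect_equal(a$sumsq[a$term == "treatment"], ss_t, tolerance = 1e-10)
  expect_equal(a$sumsq[a$term == "block"], ss_b, tolerance = 1e-10)
  expect_equal(a$statistic[a$term == "treatment"], ms_t / ms_e,
               tolerance = 1e-10)
  expect_equal(res$mse, ms_e, tolerance = 1e-10)

  # LSD flags exactly the pairs exceeding t * sqrt(2 MSE / b)
  crit <- qt(1 - 0.05 / 2, 6) * sqrt(2 * ms_e / 4)
  for (i in seq_len(nrow(res$lsd))) {
    expect_equal(res$lsd$significant[i], res$lsd$mean_diff[i] > crit)
  }

  # identical treatment columns: no treatment signal at all
  df0 <- df
  df0$value <- rep(b_means, each = 3)
  res0 <- randomized_block_anova(df0)
  a0 <- res0$anova
  expect_equal(a0$sumsq[a0$term == "treatment"], 0, tolerance = 1e-10)
  expect_true(all(res0$lsd$mean_diff < 1e-10))
  expect_false(any(res0$lsd$significant_gated))

  expect_error(randomized_block_anova(df[-1, ]), "complete")
})
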