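# Selection criteria: LRT arithmetic, information criteria, the hLRT
# decision tree, and decision-theoretic risk.

test_that("likelihood-ratio tests use the right null distributions", {
  r <- lrt(-1005, -1000, df = 1)
  expect_equal(r$delta, 10)
  expect_equal(r$p_value, pchisq(10, 1, lower.tail = FALSE))

  # boundary tests: half the mass at zero
  expect_equal(lrt(-1000, -1000, df = 1, mixed = TRUE)$p_value, 1)
  m <- lrt(-1000, -1000 + 2.706 / 2, df = 1, mixed = TRUE)
  expect_equal(m$p_value, 0.05, tolerance = 1e-3)
  expect_equal(m$p_value, 0.5 * pchisq(2.706, 1, lower.tail = FALSE))

  # marginally negative deltas are clamped but preserved raw
  neg <- lrt(-999.9999, -1000, df = 2)
  expect_equal(neg$delta, 0)
  expect_lt(neg$delta_raw, 0)
  expect_equal(neg$p_value, 1)
  expect_error(lrt(-1, -1, df = 0), "df")
})

test_that("information criteria evaluate their formulas exactly", {
  expect_equal(aic(-1000, 5), 2010)
  expect_equal(bic(-1000, 5, 1000), 2000 + 5 * log(1000))
  expect_equal(aicc(-1000, 5, 1000), 2000 + 2 * 5 * 1000 / (1000 - 5 - 1))
  expect_error(aicc(-1000, 10, 11), "n > K")
  # AICc converges to AIC for large n
  expect_lt(abs(aicc(-1000, 10, 1e6) - aic(-1000, 10)), 1e-3)
  # equal K: both orderings reduce to the likelihood ordering
  expect_lt(aic(-999, 5), aic(-1000, 5))
  expect_lt(bic(-999, 5, 100), bic(-1000, 5, 100))
})

test_that("IC selection minimises the score with parsimony tie-break", {
  # JC (K=0) and K80 (K=1) engineered to identical AIC: JC wins the tie
  fits <- make_fit_table(c(JC = -1000, K80 = -999, HKY = -1010))
  sel <- ic_select(fits, "AIC")
  expect_equal(sel$model, "JC")
  expect_equal(sel$n_tied, 2L)
  # BIC penalises the extra parameter, no tie
  expect_equal(ic_select(fits, "BIC")$model, "JC")
  # a clearly better complex model wins
  fits2 <- make_fit_table(c(JC = -1000, GTR = -900))
  expect_equal(ic_select(fits2, "AIC")$model, "GTR")
})

test_that("the hLRT walks its hierarchy to the documented terminals", {
  cand <- candidate_models()$model
  # all nulls retained: flat likelihood surface -> JC
  flat <- make_fit_table(setNames(rep(-1000, 56), cand))
  sel <- hlrt_select(flat)
  expect_equal(sel$model, "JC")
  # trace: freq, titv, gamma, inv (rate path stops after first acceptance)
  expect_equal(nrow(sel$trace), 4)
  expect_false(any(sel$trace$rejected))

  # every test rejects: lnL grows steeply with parameter count
  steep <- make_fit_table(setNames(
    -2000 + 50 * candidate_models()$free_params, cand))
  sel2 <- hlrt_select(steep)
  expect_equal(sel2$model, "GTR+I+G")
  expect_equal(nrow(sel2$trace), 6)
  expect_true(all(sel2$trace$rejected))

  # missing fits on the path are reported by name
  expect_error(hlrt_select(make_fit_table(c(JC = -1000))), "F81")
})

test_that("the default hierarchy cannot reach SYM-like models", {
  reachable <- hlrt_reachable_models()
  expect_setequal(reachable,
                  c("JC", "F81", "K80", "HKY", "TrNef", "TrN", "GTR"))
  expect_false("SYM" %in% reachable)
})

test_that("decision theory weights, risks and tie-breaks behave", {
  cand <- candidate_models()
  lnL <- setNames(rep(-1000, 56), cand$model)
  # identical branch vectors: all risks zero, parsimony picks JC
  fits <- make_fit_table(lnL)
  sel <- dt_select(fits)
  expect_equal(sel$model, "JC")
  expect_true(all(sel$scores$score == 0))
  expect_equal(sum(sel$scores$weight), 1, tolerance = 1e-12)

  # a dominant-BIC model (gap >> 100) selects its own branch lengths
  lnL2 <- lnL; lnL2["TrN"] <- -800
  edges <- replicate(56, runif(5, 0, 0.2), simplify = FALSE)
  fits2 <- make_fit_table(lnL2, edge_lengths = edges)
  sel2 <- dt_select(fits2)
  expect_equal(sel2$model, "TrN")

  # risk ordering is invariant to a constant shift of all BIC values
  # (a uniform lnL shift changes every BIC by the same constant)
  lnL3 <- lnL2 - 123.4
  fits3 <- make_fit_table(lnL3, edge_lengths = edges)
  sel3 <- dt_select(fits3)
  expect_equal(sel3$model, sel2$model)
  expect_equal(sel3$scores$score, sel2$scores$score, tolerance = 1e-9)
})

test_that("select_models returns one chosen model per criterion", {
  cand <- candidate_models()
  withr::with_seed(5, {
    lnL <- setNames(-2000 + 3 * cand$free_params + rnorm(56, 0, 2),
                    cand$model)
    edges <- replicate(56, runif(9, 0, 0.3), simplify = FALSE)
  })
  fits <- make_fit_table(lnL, edge_lengths = edges)
  sel <- select_models(fits)
  expect_equal(sel$criterion, c("hLRT", "AIC", "BIC", "DT"))
  expect_true(all(sel$model %in% cand$model))
  expect_equal(vapply(sel$result, class, character(1)),
               rep("selection_result", 4))
})
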