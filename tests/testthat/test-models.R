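# Model family structure, parameter accounting, and rate-matrix construction.

test_that("candidate and generating sets have the documented structure", {
  cand <- candidate_models()
  gen <- generating_models()
  expect_equal(nrow(cand), 56)
  expect_equal(anyDuplicated(cand$model), 0)
  expect_equal(nrow(gen), 24)
  expect_true(all(gen$model %in% cand$model))
  expect_setequal(unique(gen$base), c("JC", "F81", "K80", "HKY", "SYM", "GTR"))
  # four rate-heterogeneity categories split the sets evenly
  expect_equal(as.integer(table(gen$category)), rep(6L, 4))
  expect_equal(as.integer(table(cand$category)), rep(14L, 4))
})

test_that("free-parameter counts follow the base + I + G accounting", {
  expect_equal(free_parameters("GTR+I+G"), 10)
  expect_equal(free_parameters("JC"), 0)
  expect_equal(free_parameters("HKY+G"), 5)
  expect_equal(free_parameters("K80"), 1)
  expect_equal(free_parameters("F81"), 3)
  expect_equal(free_parameters("SYM+I"), 6)
  gen <- generating_models()
  expect_equal(sort(unique(gen$free_params)), 0:10)
  # distribution of the 24 generating models over the 11 parameter classes
  expect_equal(as.integer(table(factor(gen$free_params, levels = 0:10))),
               c(1L, 3L, 3L, 2L, 3L, 4L, 3L, 1L, 1L, 2L, 1L))
  # every flagged model nests its flag-free base with strictly fewer params
  flagged <- gen[gen$has_inv | gen$has_gamma, ]
  for (i in seq_len(nrow(flagged))) {
    expect_lt(free_parameters(flagged$base[i]), flagged$free_params[i])
  }
})

test_that("model categories are a bijection of the (I, G) flags", {
  expect_equal(model_category("JC+I+G"), "base+I+G")
  expect_equal(model_category("K80"), "base")
  expect_equal(model_category("TrN+I"), "base+I")
  expect_equal(model_category("SYM+G"), "base+G")
  expect_error(model_spec("JC+X"), "malformed")
  expect_error(model_spec("NOPE"), "unknown base model")
})

test_that("rate matrices are normalised, stationary and time-reversible", {
  # JC: equal rates and frequencies force all off-diagonals to 1/3
  Qjc <- build_rate_matrix(model_parameters())
  expect_equal(Qjc[upper.tri(Qjc) | lower.tri(Qjc)], rep(1 / 3, 12))

  withr::with_seed(7, {
    for (i in 1:5) {
      params <- random_model_parameters()
      Q <- build_rate_matrix(params)
      pi <- params$base_freqs
      expect_lt(max(abs(rowSums(Q))), 1e-12)
      expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
      # stationarity: pi is a left null vector
      expect_lt(max(abs(pi %*% Q)), 1e-12)
    }
  })

  # set-A GTR satisfies detailed balance to machine precision
  pa <- parameter_set("A")
  Qa <- build_rate_matrix(pa, "GTR")
  M <- pa$base_freqs * Qa
  expect_lt(max(abs(M - t(M))), 1e-12)
  # and matches the direct construction from the printed values
  expect_equal(Qa, oracle_rate_matrix(c(0.35, 0.22, 0.18, 0.25),
                                      c(2.675, 7.35, 6.125, 0.225, 30.7, 1)),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("invalid parameters are rejected", {
  expect_error(model_parameters(base_freqs = c(0.5, 0.5, 0.2, -0.2)),
               "nonnegative")
  expect_error(model_parameters(base_freqs = c(0.4, 0.4, 0.4, 0.4)),
               "sum to 1")
  expect_error(model_parameters(rates = c(-1, 1, 1, 1, 1, 1)), "nonnegative")
  expect_error(model_parameters(gamma_shape = 0), "positive")
  expect_error(model_parameters(p_inv = 1), "p_inv")
})

test_that("pinning restricts parameters to what a model frees", {
  pa <- parameter_set("A")
  jc <- pin_parameters(pa, "JC")
  expect_equal(unname(jc$base_freqs), rep(0.25, 4))
  expect_equal(unname(jc$rates), rep(1, 6))
  expect_equal(jc$p_inv, 0)
  expect_true(is.na(jc$gamma_shape))

  hky <- pin_parameters(pa, "HKY+G")
  expect_equal(unname(hky$rates), c(1, 2, 1, 1, 2, 1))  # kappa = 2
  expect_equal(unname(hky$base_freqs), c(0.35, 0.22, 0.18, 0.25))
  expect_equal(hky$gamma_shape, 0.67256)
  expect_equal(hky$p_inv, 0)

  sym <- pin_parameters(pa, "SYM+I")
  expect_equal(unname(sym$base_freqs), rep(0.25, 4))
  expect_equal(unname(sym$rates), unname(pa$rates))
  expect_equal(sym$p_inv, 0.25)
})

test_that("the two printed parameter sets are stored exactly", {
  pa <- parameter_set("A")
  expect_equal(unname(pa$base_freqs), c(0.35, 0.22, 0.18, 0.25))
  expect_equal(unname(pa$rates), c(2.675, 7.35, 6.125, 0.225, 30.7, 1))
  expect_equal(pa$gamma_shape, 0.67256)
  expect_equal(pa$p_inv, 0.25)
  expect_equal(pa$ncat, 4L)
  pb <- parameter_set("B")
  expect_equal(unname(pb$base_freqs), c(0.35, 0.15, 0.25, 0.25))
  expect_equal(unname(pb$rates), c(2, 4, 1.8, 1.4, 6, 1))
  expect_equal(pb$gamma_shape, 0.5)
  expect_equal(pb$p_inv, 0.5)
})
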