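# Sequence simulation: discrete gamma, invariable sites, saturation
# behaviour, base composition, and the GY94 codon path.

test_that("discrete gamma categories match the conditional-mean oracle", {
  for (shape in c(0.3, 0.67256, 2)) {
    r <- discrete_gamma_rates(shape, 4)
    expect_equal(r, oracle_gamma_rates(shape, 4), tolerance = 1e-8)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(diff(r) > 0))
  }
})

test_that("zero branch lengths copy the root draw to every taxon", {
  tr <- simulate_birth_death_tree(6, seed = 2)
  tr$edge.length <- rep(0, length(tr$edge.length))
  aln <- simulate_alignment(tr, "GTR+G", parameter_set("A"), 50, seed = 4)
  expect_true(all(apply(aln, 2, function(col) length(unique(col)) == 1)))
})

test_that("saturated JC pairs approach 1/4 identity", {
  # two taxa, total path length 10: P(same) = 1/4 + 3/4 exp(-4t/3)
  tr <- ape::read.tree(text = "(a:5,b:5);")
  aln <- simulate_alignment(tr, "JC", model_parameters(), 10000, seed = 6)
  p_same <- mean(aln["a", ] == aln["b", ])
  expected <- 0.25 + 0.75 * exp(-4 * 10 / 3)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(p_same - expected), 3 * se)
})

test_that("invariable sites appear at the configured proportion", {
  tr <- scale_to_height(simulate_birth_death_tree(8, seed = 3), 0.5)
  aln <- simulate_alignment(tr, "HKY+I", parameter_set("A"), 4000, seed = 9)
  rates <- attr(aln, "site_rates")
  p_hat <- mean(rates == 0)
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_lt(abs(p_hat - 0.25), 3 * se)
  # rate-0 sites are constant across taxa
  expect_true(all(apply(aln[, rates == 0, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))
  # variable-site rates rescaled so the overall mean rate stays 1
  expect_equal(mean(rates), 1, tolerance = 0.05)
})

test_that("base composition converges to the stationary frequencies", {
  tr <- scale_to_height(simulate_birth_death_tree(10, seed = 12), 2)
  aln <- simulate_alignment(tr, "GTR", parameter_set("A"), 5000, seed = 13)
  counts <- table(factor(as.vector(aln), levels = c("A", "C", "G", "T")))
  test <- chisq.test(counts, p = c(0.35, 0.22, 0.18, 0.25))
  expect_gt(test$p.value, 0.001)
})

test_that("identical seeds give byte-identical alignments", {
  tr <- simulate_birth_death_tree(6, seed = 1)
  a <- simulate_alignment(tr, "GTR+I+G", parameter_set("B"), 100, seed = 42)
  b <- simulate_alignment(tr, "GTR+I+G", parameter_set("B"), 100, seed = 42)
  expect_identical(a, b)
})

test_that("alignments round-trip through FASTA and PHYLIP", {
  tr <- simulate_birth_death_tree(5, seed = 4)
  aln <- simulate_alignment(tr, "HKY", parameter_set("A"), 60, seed = 5)
  for (fmt in c("fasta", "phylip")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_alignment(aln, tmp, fmt)
    back <- read_alignment(tmp, fmt)
    expect_equal(back[rownames(aln), ], aln, ignore_attr = TRUE)
  }
})

test_that("the GY94 generator has the stated structure", {
  pa <- pin_parameters(parameter_set("A"), "GTR")
  Q <- gy94_rate_matrix(pa, omega = 0.016)
  expect_equal(dim(Q), c(61, 61))
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # multi-nucleotide changes are forbidden
  codons <- rownames(Q)
  ndiff <- outer(codons, codons, function(a, b) {
    mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
           a, b)
  })
  expect_true(all(Q[ndiff > 1] == 0))
  # reversibility w.r.t. the F1x4 codon frequencies
  cf <- Q  # placeholder to appease lints; recompute directly:
  f <- pa$base_freqs
  pos <- do.call(rbind, strsplit(codons, ""))
  cf <- f[pos[, 1]] * f[pos[, 2]] * f[pos[, 3]]
  cf <- cf / sum(cf)
  M <- cf * Q
  expect_lt(max(abs(M - t(M))), 1e-12)

  # omega = 1 with uniform exchangeabilities and frequencies: all allowed
  # single-nucleotide changes share one rate (synonymy is invisible)
  Qn <- gy94_rate_matrix(model_parameters(), omega = 1)
  off <- Qn[ndiff == 1]
  expect_lt(diff(range(off)), 1e-12)
})

test_that("codon alignments have the right shape and no stop codons", {
  tr <- scale_to_height(simulate_birth_death_tree(6, seed = 7), 0.5)
  cfg <- codon_sim_config("HKY+G", parameter_set("A"), omega = 0.016,
                          length_nt = 99, mutation_rate = 1)
  aln <- simulate_codon_alignment(tr, cfg, seed = 8)
  expect_equal(dim(aln), c(6, 99))
  cods <- apply(aln, 1, function(s) {
    paste0(s[c(TRUE, FALSE, FALSE)], s[c(FALSE, TRUE, FALSE)],
           s[c(FALSE, FALSE, TRUE)])
  })
  expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  expect_error(codon_sim_config("HKY", parameter_set("A"), length_nt = 100),
               "divisible by 3")
  expect_error(codon_sim_config("HKY", parameter_set("A"), omega = 0),
               "positive")
})
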