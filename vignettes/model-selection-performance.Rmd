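---
title: "Evaluating phylogenetic model-selection criteria by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating phylogenetic model-selection criteria by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modselsim)
```

## The question

Maximum-likelihood and Bayesian phylogenetics require an explicit model of
nucleotide substitution, and in practice that model is chosen by a
statistical criterion: the hierarchical likelihood-ratio test (hLRT), the
Akaike information criterion (AIC), the Bayesian information criterion
(BIC), or decision theory (DT).  These criteria can and do disagree, and a
wrong model can bias branch lengths, support values and topology.
`modselsim` evaluates the four criteria the only way their behaviour can
be measured directly: by simulating data under *known* models and scoring
how each criterion recovers them.

The experiment is a factorial simulation: alignments are generated under
the 24 "fundamental" models of the GTR family — the six bases JC, F81,
K80, HKY, SYM and GTR, each without extras, with a proportion of
invariable sites (+I), with discrete-gamma rate heterogeneity (+G), and
with both — along fixed guide trees, then every dataset is fitted under a
56-model candidate set, each criterion selects a best-fit model, and the
selections are summarised as accuracy, precision, pairwise dissimilarity,
agreement profiles, and model-bias tables.

## The substitution models

All models are stationary, time-reversible, homogeneous Markov processes
on {A, C, G, T}.  The general case (GTR) has rate matrix
$Q_{ij} = r_{ij}\pi_j$ with six exchangeabilities $r_{ij}$ (stored
relative to $r_{GT} = 1$) and stationary frequencies $\pi$.  The 14 base
models of the candidate set are the "7 schemes × 2 frequency variants"
family familiar from ModelTest/jModelTest: each scheme constrains the six
exchangeabilities into shared classes (e.g. K80/HKY share one transition
and one transversion class), and each scheme comes in an
equal-frequency (π = ¼) and a free-frequency variant.  Free-parameter
counts follow directly: rate classes − 1, plus 3 for free frequencies,
plus 1 each for +I and +G, spanning 0 (JC) to 10 (GTR+I+G).

Rate matrices are normalised to one expected substitution per site per
unit branch length, so branch lengths and tree heights are expected
substitutions per site.

Rate heterogeneity uses Yang's discrete gamma with four equal-probability
categories, each category taking the conditional mean of its quantile
interval (`discrete_gamma_rates()`), and invariable sites are a rate-zero
category of probability `p_inv`.  One convention deserves emphasis
because the literature splits on it: under +I we rescale the variable-site
rates by $1/(1 - p_\mathrm{inv})$ so that the *mixture* mean rate is 1.
This is the PAML/phangorn convention; it keeps "tree height 0.5" meaning
0.5 expected substitutions per site even for +I models, and it makes the
simulator, the package's own pruning likelihood and the fitting engine
mutually consistent (the test suite verifies agreement to ~1e-13).  At a
likelihood optimum the convention is invisible — branch lengths absorb
the constant — but parameter values quoted for +I models assume it.

## Study conditions

`simulation_conditions()` holds the 14 built-in conditions: two printed
parameter sets (A: unequal frequencies, strongly unequal exchangeabilities
with a CT rate of 30.7, α = 0.67256, p_inv = 0.25; B: milder rates,
α = 0.5, p_inv = 0.5), ultrametric birth–death guide trees (speciation
0.1, extinction 0.1, full sampling) of 22/30/50 taxa scaled to heights
0.7/0.5/0.3/0.1, one non-clock 22-taxon tree whose internal branches take
the lengths $10^{2x/18-3}$ for a random permutation of labels
$x = 0..18$ (externals $10^{2x/21-3}$, $x = 0..21$), and sequence lengths
300/1000/2000 bp, with 100 replicates per generating model — 33,600
datasets at full scale.  The guide tree is drawn once per condition; the
original study's specific tree realisations are not recoverable, so each
run draws its own from the same stochastic process, which reproduces the
design in distribution rather than replaying the exact random numbers.
One condition (III-1) existed in the original design to compare two
simulation programs implementing the same generative model; here it is an
independent second run of the II-1 process.

A codon-model condition probes what happens when the generating model lies
*outside* the candidate set: GY94 codon alignments (999 bp, 30 sequences,
ω = 0.016, universal code, F1×4 codon frequencies) crossed with each
generating model's nucleotide parameters.  Because no candidate is the
true model, only agreement and dissimilarity are evaluated there —
`run_codon_condition()` deliberately produces no accuracy or precision
table.  The branch-length scalar (`mutation_rate`, default 0.001 as in
the original tool's settings) is exposed in the configuration: the
original tool coupled it with a coalescent time scale that is not
recoverable, so at the default the simulated divergence is very low, and
sensitivity analyses should vary this scalar.

## The selection pipeline

For each dataset the workflow mirrors the classic ModelTest/PAUP* recipe:

1. **Starting tree.** Jukes–Cantor distances
   ($d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, saturated pairs capped at
   5 with a warning) feed neighbor-joining; negative NJ branch estimates
   are clamped to zero.  The topology is then *fixed*: all 56 candidate
   models are fitted on it, optimising branch lengths and the model's
   free parameters only.  This both mirrors the historical workflow and
   guarantees the comparable branch-length vectors DT needs.
2. **Likelihood.** Fits use phangorn's `optim.pml` with rate-class
   constraints; the package carries its own Felsenstein-pruning
   implementation (`log_likelihood()`), tested against brute-force state
   enumeration on small trees and against phangorn, so the likelihood
   machinery is verified by two independent routes.  Optimisation stops
   when the outer iteration improves the log-likelihood by less than the
   control tolerance; a failed fit is flagged `converged = FALSE` and
   excluded from selection with a warning.
3. **Criteria.**
   - *hLRT*: a fixed path of nested pairwise tests at α = 0.01, with the
     mixed ½χ²₀ + ½χ²₁ null for the boundary hypotheses (+G, then +I,
     tested last).  The hierarchy is data
     (`default_hierarchy()`), so alternatives are pluggable.  The default
     walks equal-frequencies → ti/tv → equal transition rates → equal
     transversion classes (TrN vs GTR, on the unequal-frequency branch)
     → Γ → I.  A fixed decision tree cannot terminate at every candidate:
     `hlrt_reachable_models()` shows the default reaches only
     {JC, F81, K80, HKY, TrNef, TrN, GTR} × {·, +I, +G, +I+G} — in
     particular SYM-like models are structurally unreachable, which is
     exactly the behaviour reported for the default ModelTest hierarchy
     and the reason the hLRT's accuracy on SYM-like generating models is
     zero by construction.
   - *AIC/AICc/BIC*: $-2\ln L + 2K$, the small-sample correction, and
     $-2\ln L + K\ln n$ with $n$ the sequence length and $K$ the model's
     free parameters (0–10; branch lengths are shared across candidates
     and not counted).  AIC is the default reported flavour; AICc is
     available when $n$ is small relative to $K$.
   - *DT*: BIC-derived weights
     $w_j \propto \exp(-\Delta\mathrm{BIC}_j/2)$ and risk
     $R_i = \sum_j \lVert B_i - B_j\rVert_2\, w_j$ over the fits'
     branch-length vectors; the minimal-risk model wins.  The risk is
     invariant to constant shifts of BIC, and when all branch-length
     vectors coincide every risk is zero.
   - Ties anywhere are broken parsimony-first (fewer free parameters,
     then name) and counted, so their frequency is measurable.

## Evaluation statistics

Per generating model and criterion over $N$ replicates: **accuracy** is
$\mathrm{Number_{matched}}/\mathrm{Number_{test}} \times 100$;
**precision** is the number of *distinct* best-fit models selected
(smaller = more precise); for a criterion pair, **dissimilarity** is
$(N - m)/N \times 100$ with $m$ the replicates where both chose the same
model; the **agreement profile** is the percentage of replicates on which
the four criteria chose 1/2/3/4 distinct models (sums to 100).
**Model-bias tables** classify recovered models by rate-heterogeneity
category (4 classes) or free-parameter count (11 classes) and compare
criteria with χ² homogeneity tests — an overall r×k test plus pairwise
comparisons at the Bonferroni level 0.05/6 ≈ 0.0083; empty
parameter-count classes are pooled into the adjacent class before
testing.  Criterion means are compared by two-way randomized-block ANOVA
(criteria = treatments, generating models = blocks) with Fisher's LSD on
the error mean square, reported both raw and gated on a significant
omnibus F (α = 0.01).

```{r example, eval = FALSE}
library(modselsim)
res <- run_condition("I-2", n_replicates = 2, n_sites = 300, seed = 1)
glance(res)            # mean accuracy per criterion, dissimilarity per pair
autoplot(res)          # per-model accuracy lines
plot_model_bias(res)   # category composition of recovered models
```

## Numerical choices and degenerate inputs

* Transition probabilities come from the eigendecomposition of the
  similarity-transformed (symmetric) rate matrix, so $P(t)$ is exact,
  real, and cheap per branch/rate class; tiny negative entries from
  roundoff are clamped and rows renormalised.
* The pruning likelihood rescales partials per node and accumulates logs,
  so 2000-site, 50-taxon datasets are safe from underflow; ambiguous or
  missing characters get partial likelihood 1.
* Saturated JC distances (p ≥ 0.75) are capped rather than infinite;
  zero-length NJ branches are floored at 1e-8 before optimisation.
* Optimisation bounds and starts follow phangorn's defaults (neutral
  exchangeabilities, shape 1, p_inv 0, NJ branch lengths); candidate fits
  that error are excluded with a warning rather than aborting a run.
* Seeds: every stochastic function takes an explicit seed;
  `run_condition()` derives one sub-seed for the guide tree and one per
  dataset from the master seed by a fixed counter scheme, so a single
  dataset can be regenerated in isolation and identical master seeds give
  identical selection tables.

## What the generator does and does not emulate

The simulator reproduces the generative assumptions of the study —
stationarity, reversibility, homogeneity along the tree, site
independence, discrete-gamma + invariable-site rate variation, and exact
printed parameter values.  Real sequence data violate several of these
(compositional drift across lineages, site-pattern heterogeneity,
indels/alignment error, selection), so criterion performance measured
here is a best case for the models under test: passing results show the
criteria behave as designed *when the truth is in (or near) the candidate
set*, not that the selected model is adequate for any empirical
alignment.  The codon condition probes one mild violation — a generating
process outside the candidate family — and only criterion agreement, not
accuracy, is interpretable there.

## Replication scale

The full design (33,600 datasets × 56 fits) is a cluster-scale
computation.  The package's own replication profile — used by the test
suite and the acceptance script — runs the I-2 generating process with
all 24 generating models at 30 taxa and 300 bp with 2 replicates per
model (48 datasets, ~10 minutes on one CPU), which is sufficient to
reproduce the study's robust qualitative findings: BIC and DT clearly
more accurate on average than AIC and the hLRT and closely tracking each
other, hLRT accuracy on SYM-like models exactly zero, BIC–DT the least
dissimilar criterion pair and hLRT–AIC the most dissimilar, and an
agreement profile dominated by one-or-two chosen models with four-way
disagreement rare.  Quantities that depend on fine per-model resolution
(e.g. per-model accuracy at ±5% resolution) need the full 100-replicate
design and are reported here only in distribution.

## Known limitations

* The hLRT hierarchy is one fixed default; the original program's exact
  decision tree was never printed, and hierarchy choice is known to
  change hLRT behaviour.  Alternative hierarchies can be supplied as
  data, and the reachable-model introspection makes their structural
  limits explicit.
* DT's published construction leaves the norm and any sequence-length
  scaling of branch-length differences open; the Euclidean norm with
  BIC weights is implemented, and the norm is isolated in one function
  for sensitivity analysis.
* The codon condition's divergence scale depends on a non-recoverable
  coalescent coupling in the original tool; the branch-length scalar is
  a configuration knob, not an estimate.
* The gamma shape is optimised on a bounded interval (upper bound 100),
  so +G fits truncate the no-heterogeneity limit α → ∞: on data without
  rate heterogeneity a +G model's attainable optimum can sit a small,
  bounded amount below its gamma-free counterpart's, which is a property
  of every bounded ML implementation of this family, not an optimiser
  failure.
* Guide trees are redrawn per run from the stated birth–death process;
  quantities tied to one specific tree realisation are reproducible only
  in distribution.
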