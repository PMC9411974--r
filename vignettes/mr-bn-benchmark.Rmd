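---
title: "Benchmarking Mendelian randomization and Bayesian network causal discovery on simulated trait networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking Mendelian randomization and Bayesian network causal discovery on simulated trait networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given many continuous traits measured in one cohort, together with genetic
variants that act as instrumental variables (IVs) for those traits, which
ordered trait pairs (X, Y) are causally related? `mrbnbench` implements a
simulation benchmark for two families of answers:

* **Summary-statistic Mendelian randomization (MR)** — inverse-variance
  weighted (IVW) regression, MR-Egger and MR-PRESSO — run on every ordered
  trait pair, with or without a conditional-independence pre-filter of the
  instruments (the "UniqueIV" idea: keep only instruments that show no
  evidence of affecting any trait other than their exposure except through
  it).
* **A constrained four-variable Bayesian network (BN)** per trait pair:
  the two traits plus one weighted allele score for each, with the scores
  fixed as parents of their traits, so the only free edge is between the
  two traits. Bootstrap refitting turns the fitted edge into a
  directed-edge probability.

Everything is scored against a known simulated ground truth, where "X is
causal on Y" means a directed path X → Y exists in the generating graph,
with any number of intermediate traits.

```{r, eval = FALSE}
library(mrbnbench)
ex <- run_experiment(
  sim_config(n_replicates = 20, seed = 1),
  eval_config(p_pleio_grid = c(0, 0.2, 0.4), n_boot = 300)
)
head(ex$summary)
```

## The generative model

Each replicate draws:

1. **A causal DAG over `n_traits = 15` traits.** Traits are placed in a
   uniformly random order; the trait at position *i* receives a
   Poisson(`mean_children = 1.5`) number of children (truncated to the
   traits later in the order), giving each trait causal links to around
   1–2 others. Edge effects have magnitude uniform on
   `effect_range = [0.1, 0.4]` with random sign.
2. **Instruments.** Each trait gets 10–20 binary IVs (about 225 in
   total), with allele frequency uniform on `[0.1, 0.5]` and a primary
   effect drawn like an edge effect.
3. **Horizontal pleiotropy.** With probability `p_pleio` an instrument
   additionally affects *one* uniformly chosen non-primary trait
   directly. We deliberately model pleiotropy per instrument rather than
   per (instrument, trait) pair: with 15 traits a per-pair rate of even
   0.2 would make essentially every instrument invalid for every
   analysis (2.8 extra targets per IV on average), no filtering rule
   could retain a usable instrument set, and filtered MR could not
   outperform unfiltered MR — the opposite of the regime the benchmark
   is designed to explore. Per-instrument pleiotropy leaves a
   `1 − p_pleio` valid core that a conditional-independence filter can
   recover.
4. **Data.** Genotypes are Bernoulli(frequency); traits follow the
   linear-Gaussian structural equations in topological order:
   instrument effects (primary and pleiotropic) + parent-trait effects +
   N(0, `noise_sd`²) noise. The linear-Gaussian form matches the
   assumptions of the MR estimators and the Gaussian network score; the
   traits are continuous by construction.

`n_samples = 2000` is the cohort size: large enough that Bonferroni
selection at 0.05 over ~225 IVs (threshold ≈ 2.2 × 10⁻⁴) retains most
true instruments (a median per-trait R² around 1% gives first-stage F
statistics well above the selection threshold), yet small enough that
weakly confounded trait pairs remain genuinely hard, which is what makes
the FDR comparison informative.

What the generator does **not** emulate: linkage disequilibrium between
variants, diploid dosages, case-control traits, assortative or selective
sampling, and two-sample designs (exposure and outcome statistics come
from the same cohort, so weak-instrument bias acts toward the
confounded observational estimate rather than the null). Passing tests
therefore demonstrate correctness of the estimators and orderings of the
methods *under this idealised regime*, not performance on real biobank
data.

## Instrument selection and filtering

For every trait, `run_gwas()` computes all ~225 × 15 simple regressions
in closed form; `select_instruments()` keeps IVs with marginal
p ≤ `alpha/n_tests`, where `n_tests` is the replicate's actual total
instrument count (the "≈225" is an expectation, not a constant), and the
marginal slopes become the score weights.

`unique_iv_filter()` re-tests each selected instrument g against every
other trait Z in the regression Z ~ g + X and drops g if any coefficient
on g is significant at `ci_alpha = 0.01`. Under the structural model,
g ⊥ Z | X holds whenever g affects Z only through X — in particular for
all descendants of X — so true causal signal does not remove valid
instruments. Two deliberate design points:

* **The filter is pair-independent.** We screen over *all* other traits,
  including the outcome of the pair later analysed. Excluding the
  outcome (so that "causal signal is not filtered away") is unnecessary
  under the model — the causal path survives the conditional test — and
  actively harmful: it retains exactly the instruments that are
  pleiotropic on the outcome, concentrating them in the smaller filtered
  set and *raising* the filtered FDR above the unfiltered one. The
  `exclude_traits` argument remains available for sensitivity analyses.
* **Collider leakage is accepted.** If Z is a parent of X, conditioning
  on X induces dependence between g and Z; for the effect sizes above
  the induced partial correlation is usually below the detection
  threshold at n = 2000, so the filter loses some instruments of
  downstream traits but not catastrophically. This mirrors the known
  behaviour of conditional-independence filtering, which favours
  source traits.

This single-rule filter is a declared surrogate for the full
pipeline it imitates (which layers several CI tests); `ci_alpha` is
exposed so the operating point can be studied.

## The MR estimators

All three estimators consume per-instrument summary statistics
(b̂ₓ, SEₓ, b̂ᵧ, SEᵧ) with weights wⱼ = 1/SEᵧⱼ²:

* **IVW**: weighted regression through the origin;
  estimate Σw b̂ₓb̂ᵧ / Σw b̂ₓ², fixed-effect SE (Σw b̂ₓ²)^(−1/2).
* **MR-Egger**: the same regression with a free intercept (absorbing
  directional pleiotropy); the SE uses the estimated residual scale, as
  in ordinary weighted least squares. Requires ≥ 3 instruments.
* **MR-PRESSO**: leave-one-out IVW slopes define an observed weighted
  residual sum of squares; a parametric simulation (default 1000 draws)
  of b̂ₓ* ~ N(b̂ₓ, SEₓ²), b̂ᵧ* ~ N(β̂₍₋ⱼ₎b̂ₓ, SEᵧ²) supplies the reference
  distribution for the global heterogeneity p-value and per-instrument
  outlier p-values (Bonferroni-adjusted, removal below 0.05). The
  reported estimate and p-value are IVW on the retained instruments;
  the global p is kept as metadata and does not drive discoveries,
  because the benchmark counts causal predictions, i.e. slope tests.
  Requires ≥ 4 instruments.

Slope tests use a normal reference rather than a t distribution —
standard summary-statistic practice, slightly anticonservative at small
instrument counts (visible for Egger on filtered sets). Pairs with too
few instruments are recorded as untested: they can never be discovered,
which depresses power exactly as a real pipeline dropping such pairs
would.

Per method and filter variant, p-values are Benjamini–Yekutieli adjusted
across all ordered pairs tested in the replicate (at most 15 × 14 = 210),
via `stats::p.adjust(method = "BY")`. Discoveries use adjusted
p ≤ {0.1, 0.05, 0.01}.

## The four-variable Bayesian network

For each of the 105 unordered trait pairs, the table (T1, T2, S1, S2)
holds the two traits and their weighted allele scores (weights = marginal
slopes from the replicate's own GWAS, either the Bonferroni or the
UniqueIV set; scores are computed once per dataset, not rebuilt inside
each bootstrap resample — the cheaper reading, adopted deliberately).
The admissible structures always contain S1 → T1 and S2 → T2 and nothing
else touching the scores, leaving three candidates: no trait edge,
T1 → T2, or T2 → T1. Each candidate is scored by the Gaussian BIC
(per-node maximised log-likelihood minus (d/2)·log n with d counting
slopes, intercept and variance); with three candidates the search is
exact and needs no restarts. BIC is the conventional score for
linear-Gaussian networks; AIC would change only the penalty constant.

`average_network()` resamples the rows with replacement `n_boot` times
and tallies the best structures. The *strength* is the fraction of
resamples containing the trait edge; the *direction* is the fraction of
those oriented T1 → T2; the directed-edge probability is their product.
A pair whose edge never appears has probability exactly 0 in both
directions — which is why BN ROC curves cannot reach a true positive
rate of 1. Discoveries use probability ≥ {0.7, 0.8, 0.9}.

Numerical details: all bootstrap fits are computed from count-weighted
cross-products in a single matrix product (distributionally identical to
materialised resampling, and tested against an explicit per-resample
refit on the same index stream); residual sums of squares are floored at
10⁻¹²; a resample with a zero-variance column or collinear predictors
falls back to the no-edge structure; score ties break toward no edge,
then T1 → T2.

## Evaluation

Per replicate and variant, discoveries are scored against the
directed-path truth: FDR = FP/(TP+FP) (0 when nothing is discovered — the
standard empirical convention; the convention only matters for nearly
silent variants), power = TP/#positives, and the full 210-pair universe
defines the FPR denominator (untested pairs stay in it; the alternative
of excluding them would flatter methods that drop pairs). ROC curves
average per-replicate TPR/FPR over a fixed, evenly spaced grid of 201
thresholds; a common grid is what makes curves averageable across
replicates, so the grid is not augmented with per-replicate observed
statistic values. The degenerate endpoints (probability threshold 0,
p-value threshold 1) are dropped: they would declare every tested pair a
discovery and say nothing about ranking.

Replicate r of each pleiotropy setting runs under a child seed derived
deterministically from the experiment seed, so any single replicate can
be reproduced in isolation; failed replicates are logged, skipped and
counted.

## Problem sizes used in the shipped analyses

The checked-in analysis scripts and the acceptance protocol use 20–30
replicates per setting and 300 bootstrap resamples per pair (with 1000
retained as the package default for single-replicate analyses). These
desk-scale sizes give Monte-Carlo standard errors of a few percentage
points on mean FDR — adequate for the tolerance bands used — while a
full-scale run (100 replicates, 1000 bootstraps) changes the estimates
by less than those standard errors.

## Known limitations

* The UniqueIV rule here is one conditional test per (instrument, trait)
  pair, not the layered CI-test battery of the full pipeline it stands
  in for; absolute filtered-set sizes therefore differ from that
  pipeline even when the qualitative behaviour matches.
* One-sample bias and winner's curse are part of the simulated design,
  not removed.
* The BN analysis treats each pair in isolation; probabilities are not
  calibrated joint posteriors over the 15-trait graph.
* Degenerate replicates whose graphs have no directed-path pairs
  contribute power 0 and are flagged rather than resampled.
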