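---
title: "Detecting shifts in allometric scaling on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shifts in allometric scaling on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allogrades)
```

## The problem

Across amniotes, neuron numbers, brain masses, and body masses are linked by
power laws — straight lines on log10-log10 axes. Evolution occasionally
rewrites these scaling rules: a clade jumps to a new line (a new *grade*),
sometimes convergently with an unrelated clade. `allogrades` provides a
complete inferential chain for this situation on a rooted, time-calibrated
phylogeny:

1. **Shift detection.** A Bayesian reversible-jump search over multi-regime
   Ornstein–Uhlenbeck (OU) regressions locates branches where the allometric
   intercept and slope change, without specifying candidate locations in
   advance (`rjmcmc_run()`, `summarize_shifts()`).
2. **Grade confirmation.** The candidate grades implied by accepted shifts
   are tested and merged in a top-down PGLS model-selection cascade that
   also identifies convergent regimes (`merge_grades_cascade()`).
3. **Quantification.** Average fold changes between grade lines
   (`fold_change()`), relative measures as PGLS residuals
   (`relative_measure()`, `density_vs_size_regression()`), ancestral states
   (`ancestral_states_bm()`, `ancestral_relative_brain_size()`), and
   Brownian rates of residual evolution (`multirate_bm_fit()`,
   `compare_group_rates()`, `compare_trait_rates()`).

All user-facing functions take a species-by-trait data frame first (one row
per species, log10-scale trait columns, a `species` identifier) and return
tibbles or tidy-able objects, so results compose with the usual tidyverse
verbs.

## The multi-regime OU regression model

Let $x_i$ be the log10 predictor (body or structure mass) and $y_i$ the
log10 response (e.g. neuron number) at tip $i$ of an ultrametric tree of
depth $T$ (branch lengths in My). Branches are painted into regimes by a set
of *shift points*; a shift sits at the rootward end of its branch and is
inherited by all descendants until overridden. Each regime $k$ has an
optimum intercept $\theta_k$ (log10 units) and slope $\beta_k$
(dimensionless). The response evolves as an OU process with attraction
$\alpha$ (1/My) and diffusion $\sigma^2$ (log10$^2$/My) toward the regime
line, giving tip expectations

$$E[y_i] = \sum_k W_{ik}(\alpha)\,(\theta_k + \beta_k x_i),$$

where the weight $W_{ik}$ integrates the decaying influence
$e^{-\alpha(T - t)}$ of regime $k$ along tip $i$'s root-to-tip path (the
residual root weight $e^{-\alpha T}$ goes to the ancestral regime; rows sum
to one). The covariance between tips $i, j$ with MRCA at height $t_a$ is the
fixed-root OU covariance

$$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-2\alpha (T - t_a)}
           \left(1 - e^{-2\alpha t_a}\right).$$

The predictor is treated as error-free and fixed per tip; only the response
evolves. The root state equals the ancestral regime expectation (no
stationarity assumed); a stationary-root covariance is available in
`ou_covariance(stationary_root = TRUE)`.

### Priors

The shift-detection priors are the standard weakly informative choices for
this family of models:

| parameter | prior | default |
|---|---|---|
| $\alpha$ | half-Cauchy | scale 0.1 |
| $\sigma^2$ | half-Cauchy | scale 0.1 |
| number of shifts | Poisson, truncated | mean = 2% of branches, max = 20% |
| shift locations | uniform over branches, at most one per branch | — |
| $\theta_k$ | Normal | mean = mean(y), SD = 1.5 sd(y) |
| $\beta_k$ | Normal | mean = PGLS slope of y on x, SD = 0.3 |

`shift_priors()` realizes these for a given tree and dataset; every
hyperparameter can be overridden.

### The sampler

`rjmcmc_run()` uses Metropolis–Hastings within reversible jump with eight
move types chosen uniformly: log-scale random walks on $\alpha$ and
$\sigma^2$; Gaussian random walks on a random regime's $\theta$ and
$\beta$; birth of a shift on a uniformly chosen unshifted branch, with the
new regime's parameters proposed from their priors (so the prior densities
cancel and the acceptance ratio reduces to the likelihood ratio times the
Poisson pmf ratio); the matching death move; a global relocation to a
uniformly chosen free branch; and a local *slide* to an adjacent free
branch with a Hastings correction for unequal neighbour counts. The slide
move is what lets a shift parked one branch away from its optimum position
refine locally; without it, chains mix poorly across neighbouring
placements. Proposal step sizes adapt toward a 30% acceptance rate during
burn-in only and are frozen afterwards, so the post-burn-in kernel
satisfies detailed balance. Chains are bit-reproducible from their seed.

Defaults are desk-scale: 4 chains of 200,000 iterations, thinned to every
100th, with the first 20% of samples discarded as burn-in. Published
analyses of this kind run the same sampler for millions of iterations;
iteration counts are plain arguments, never constants. Convergence is
reported as Gelman's R-hat and an autocorrelation-based effective sample
size per parameter (`glance()` on the chains object), and
`summarize_shifts()` gates its output on R-hat < 1.1 for $\alpha$,
$\sigma^2$ and the shift count — failure flags the summary prominently
rather than suppressing it.

Shifts are *accepted* when their pooled posterior probability exceeds 0.7
and their clade holds at least 4 species — both thresholds are arguments.

### Numerical core

The fixed-root OU covariance on an ultrametric tree is a Brownian
covariance on a time-warped tree: substituting
$H(t) = (e^{-2\alpha (T - t)} - e^{-2\alpha T}) / (2\alpha)$ for node
heights makes $V_{ij} = \sigma^2 H(t_a)$. The sampler therefore evaluates
the likelihood by Felsenstein pruning in $O(n)$ per iteration, with only
non-positive exponents (stable for any $\alpha > 0$), rather than factoring
a dense covariance. The pruning path is cross-checked in the test suite
against an independent dense-matrix implementation
(`ou_regression_loglik()`) to 1e-8, and the covariance itself against
Monte-Carlo simulation of the process along the tree. Degenerate geometry
(a zero-length cherry after polytomy resolution) yields a $-\infty$
log-likelihood, i.e. such proposals are rejected.

## PGLS with Pagel's lambda

`fit_pgls()` fits $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 V(\lambda))$, where $V(\lambda)$ multiplies
the off-diagonal Brownian covariance by $\lambda \in [0, 1]$. $\lambda$ is
profiled by REML (default) or ML on a 0.05 grid followed by bounded
refinement; ties break toward the larger $\lambda$, and boundary estimates
are flagged. Coefficient tests use $t$ with $n - p$ degrees of freedom.
The GLS core whitens through the Cholesky factor; fits agree with
`nlme::gls(correlation = corPagel(...))` to numerical precision (test
suite) and with a dense closed form on small trees to 1e-8.

*Relative measures* are residuals from a single-slope PGLS within the group
of interest — relative brain size from brain-on-body, relative neuron
density from neurons-on-brain-mass — and scopes of fewer than 4 species are
refused because $\lambda$ is not meaningfully estimable there.

## The grade cascade

Accepted shifts partition species into putative grades
(`grades_from_shifts()`). `merge_grades_cascade()` starts from the full
model `y ~ x * grade` (one line per grade, shared $\lambda$ and residual
variance) and, top-down, tentatively merges each non-ancestral grade into
its ancestral grade, adopting the simpler model when the likelihood-ratio
test (df = 2) does not reject it at $\alpha = 0.05$. Retained grades are
then merged pairwise, most-similar pair first, to identify convergent
regimes. Comparisons use ML fits, because REML likelihoods of models with
different fixed effects are not comparable.

One design point deserves emphasis: within each comparison, $\lambda$ is
profiled on the reduced (null) model and then held fixed for both models.
Letting $\lambda$ float separately in each candidate model allows
clade-level residual fluctuations to be absorbed twice — once by the grade
coefficients, once by $\lambda$ — and in our calibration simulations (200
null replicates, 64 tips) that inflates the nominal 5% test to roughly 15%
rejections; profiling on the null restores approximately nominal behaviour
(7.5%). `lambda_mode = "per-model"` restores the floating variant for
comparison.

## Fold changes

Grade lines need not be parallel, so intercept differences understate or
overstate their separation. `fold_change()` evaluates the vertical
difference between two grade lines at the observed log10 predictor values
of all species in the two grades, averages it, and reports
$F = 10^{\bar\Delta}$. $F$ is antisymmetric ($F(A,B) = 1/F(B,A)$) and for
parallel lines reduces exactly to $10^{\Delta\text{intercept}}$. Evaluation
points can be overridden.

## Ancestral states and rates

`ancestral_states_bm()` returns ML ancestral states under Brownian motion
(via `phytools::fastAnc`, the two-pass pruning estimator), checked in the
suite against a dense GLS oracle. `ancestral_relative_brain_size()`
reconstructs brain and body independently and expresses node states as
residuals from the tip-level PGLS line.

Rates of *residual* evolution measure the looseness of allometric
integration. `multirate_bm_fit()` fits group-specific Brownian rates by ML
with a fixed branch grouping — a deliberate approximation of branch-wise
multiple-variance Brownian models, justified because only group-level rates
are interpreted downstream. `compare_group_rates()` tests rate
heterogeneity with the phylogenetically-corrected per-group estimator and a
simulation null (single fitted rate, empirical root state, seeded);
`compare_trait_rates()` compares distinct- versus common-rate models across
traits by likelihood ratio with a simulated null, treating traits as
independent given the tree. Simulation p-values use the add-one convention
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{sim})$ so they are
never exactly zero. Which regression's residuals enter a rate analysis is
an explicit argument, never a hidden default.

## The synthetic-data generator

`simulate_tree()` draws pure-birth trees rescaled to 300 My depth (the age
scale of crown amniotes). `simulate_grade_dataset()` layers on: log10 body
masses from Brownian motion spanning roughly five orders of magnitude
(span/4 tip SD around a centre of 2.5); brain masses from a fixed
brain–body allometry (intercept −1.3, slope 0.75, residual SD 0.2); and
log10 neuron counts from clade-specific regime lines with either
λ-structured residuals (default λ = 0.8, SD 0.15 — what the PGLS/grade
machinery assumes) or OU-structured residuals with regime-weighted means
(what the shift sampler assumes). Ground truth — painting, parameters, λ,
residual SD, seed — is stored with every dataset.

`simulate_amniote_dataset()` is a preset with an ancestral regime, one
large derived clade (elevated intercept and slope), and two smaller
unrelated sub-clades planted with an *identical* further-elevated regime,
mimicking the reptile / bird–mammal / anthropoid-primate–core-landbird
structure of empirical grade analyses. Its attraction corresponds to a
phylogenetic half-life of 50 My, and planted clades are chosen on long stem
branches within a size window — shifts in nature are detected on exactly
such branches, and shifts planted on very short stems are unidentifiable by
any method (posterior mass splits between the stem and its neighbours).

Recovery scenarios used by the tests state their conditions explicitly: the
two-shift sampler benchmark plants two disjoint clades of ~15% of 128 tips
with $\Delta\theta = 0.6$, $\Delta\beta = 0.15$, $\alpha T = 2$ and a
stationary residual SD of 0.1, typical of within-grade allometric scatter
on the log10 scale.

What the generator does **not** emulate: measurement error and
within-species variation, sampling biases in species coverage, fossil or
non-ultrametric tips, trait-dependent diversification, and correlated
evolution of the predictor. Passing recovery tests therefore demonstrate
correctness of the inference machinery under its own assumptions, not
robustness to the full messiness of empirical datasets.

## Data assembly

`assemble_dataset()` takes long-format individual measurements with units,
converts endocranial volumes to masses at the density of brain tissue
(1.036 g/cm³), averages individuals per species *before* the log10
transform (the order is an argument), and cross-checks any provided neuron
densities against neurons-per-gram recomputed from counts and masses.
`impute_ob_striatum()` harmonizes mammalian brain divisions: missing
olfactory-bulb values are filled from clade-level allometries, striatal
mass is estimated as a group-level proportion of brain mass, striatal
neurons from the species' own telencephalic neuron density, and the
striatum is reassigned from the rest-of-brain to the telencephalon — every
change is recorded in an audit table, never applied silently.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale by
choice: trees of 32–200 tips, 2–4 chains of $10^4$–$6.5\times10^5$
iterations, 50–200 simulation replicates per calibration check, and a
Monte-Carlo covariance oracle of $10^6$ paths. Every stochastic component
is seeded; identical seeds give bit-identical chains, tables and reports.

## Known limitations

- Shift locations are restricted to the rootward end of branches;
  mid-branch positions are not represented.
- Model comparison across OU/BM/early-burst families (marginal
  likelihoods) is out of scope; the sampler assumes the multi-regime OU
  regression throughout.
- For deep shifts subtending large clades, the posterior can spread over a
  parent–child neighbourhood of the true branch; per-branch posterior
  probabilities should then be read clade-wise, and nested configurations
  may need far longer chains than the desk-scale defaults.
- Under OU-structured residuals, sizeable clades accumulate genuine shared
  drift offsets; the model correctly reports these as small shifts, which
  is a feature of the model family, not a false-positive defect of the
  sampler.
- The multi-rate machinery fixes the grouping in advance; it does not
  search for rate shifts.
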