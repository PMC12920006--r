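---
title: "Threshold-region discovery and targeted policy-effect estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-region discovery and targeted policy-effect estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimand

`aretree` works with the observational data structure `O = (W, A, Y)`:
baseline covariates `W` (p columns), a multivariate exposure `A`
(m columns) and a scalar outcome `Y`. For an axis-aligned region
`𝒜` of exposure space — a conjunction of threshold rules `A_j ≤ τ` or
`A_j > τ` — define the binary indicator `T = 1{A ∈ 𝒜}` and the
restricted conditional mean `Q(1, w) = E[Y | T = 1, W = w]`. The
**attributable regional effect** is

$$\psi_{\mathcal{A}} = E[Q(1, W)] - E[Y],$$

the change in population mean outcome if everyone were forced to keep
their exposures inside `𝒜` while preserving their *relative*
within-region selection probabilities, conditional on covariates. Under
the usual identification conditions (consistency, no unmeasured
confounding given `W`, and positivity `P(A ∈ 𝒜 | W = w) > 0`) this
observable quantity equals the causal effect of that hypothetical
policy. The package computes the observable quantity; the causal reading
is the analyst's responsibility and the identification assumptions are
not testable from the data.

Because a sensible region is rarely known in advance, `𝒜` itself is
estimated: the package searches the family of axis-aligned
hyper-rectangles (up to a depth limit) for the region that maximizes or
minimizes `E[Q(1, W)]`. Estimating a parameter whose *definition* was
learned from the same data invalidates naive inference, which is why
estimation is wrapped in K-fold cross-estimation (below).

## Targeted estimation

For a fixed region, estimation follows the standard targeted-learning
recipe for a binary "treatment" `T`:

1. fit the outcome regression `Q̂(T, W)` and propensity
   `ĝ(W) = P(T = 1 | W)` with a cross-validated convex ensemble (a super
   learner) whose default menu is an intercept-only mean, a main-terms
   GLM, an elastic net (`glmnet`, alpha 0.5), a random forest (`ranger`)
   and gradient boosting (`xgboost`); the meta-learner is non-negative
   least squares on out-of-fold predictions normalized to a convex
   combination, with a fallback to the single best learner when
   normalization degrades the cross-validated risk;
2. update `Q̂` by a one-dimensional logistic fluctuation with clever
   covariate `H = T/ĝ(W)`, solving the efficient-score equation
   `(1/n) Σ H_i (Y_i − Q*(T_i, W_i)) = 0`;
3. report the plug-in `ψ̂ = (1/n) Σ (Q*(1, W_i) − Y_i)` with a standard
   error from the empirical variance of the efficient influence function
   `D_i = (T_i/ĝ_i)(Y_i − Q*(T_i, W_i)) + Q*(1, W_i) − Y_i − ψ̂`,
   normal-quantile 95% intervals and two-sided Wald p-values.

Numerical choices: the outcome is min–max scaled to `[0, 1]` so the
logistic fluctuation respects bounds (a constant outcome maps to 0.5 and
back-transforms exactly, with zero SE); `Q̂` values are clipped to
`[1e-4, 1 − 1e-4]` before the logit; the fluctuation coefficient is
found by monotone root-finding on `[−10, 10]` (a root at the boundary is
treated as non-convergence); propensities are truncated to
`[g_min, 1 − g_min]` with `g_min = 0.025` by default. Estimates are
always reported in original outcome units.

## The region search

The search is a greedy, significance-filtered recursive partitioning of
exposure space. At each node, for every exposure and candidate cutpoint
`s` (by default the unique values after rounding to 1 decimal; quantile
and raw-unique strategies are available; the maximum observed value is
excluded), the split `T = 1{A_j ≤ s}` is evaluated through three
filters:

* **minimum node size** — both children must contain at least
  `min_node` observations (default 10);
* **positivity** — the split propensity is estimated by a deliberately
  coarse covariate stratification (the leaves of a depth-2 regression
  tree of `A_j` on `W`, shared by all cutpoints of that exposure;
  stratum means of `T` are the estimates). The candidate is discarded
  when any stratum estimate leaves `[ε, 1 − ε]` (default `ε = 0.01`,
  sensible range 0.001–0.05) **or** any stratum-by-arm cell holds fewer
  than `min_cell` observations (default 5). The cell-count floor is the
  practical form of the positivity diagnostic: without it the influence
  function is blind to the noise contributed by near-empty cells and
  the split test becomes anti-conservative;
* **significance** — child means are targeted with the same fluctuation
  machinery, using the stratification estimator for both nuisances.
  Because the outcome fit is saturated on the propensity strata, the
  split-level TMLE reduces to the classic post-stratification estimator,
  the score equation is solved exactly and the influence-function
  variance matches the estimator's sampling variance to first order.
  The improving child (higher mean under `objective = "max"`, lower
  under `"min"`) must differ from the node's sample mean at level
  `alpha` (default 0.05) by a two-sided Wald test that treats the node
  mean as a fixed constant — a deliberate simplification (the node
  mean's own sampling error is ignored), conservative because child and
  node overlap.

Among valid candidates the chosen split is the one with the **most
significant** improvement (largest standardized deviation of the
improving child from the node mean), the convention of test-based
recursive partitioning. We prefer it to raw argmax over point estimates
for a structural reason: when the dose–response surface is flat over a
range of cutpoints (every threshold inside an active region induces the
same population child mean), argmax over noisy estimates systematically
selects small, noisy children deep inside the plateau, whereas the
standardized criterion has the same numerator across the plateau and
favours the well-supported boundary cutpoint. The two rules coincide
when candidate children are equally precise. Exact ties fall to
enumeration order (exposure column order, then smaller cutpoint).

Each child is recursed on until `d_max` (default 3; for mixtures of up
to ~10 exposures depth 2–3 normally exhausts the signal while keeping
rules readable) or until no candidate passes the filters. The child
test at deeper nodes is referenced to the child's *own* sample mean
rather than the targeted mean inherited from the parent split: the
inherited value carries a small adjustment offset that would otherwise
manufacture spurious "improvements" at depth. Each node's reported
estimate remains the targeted child mean from the split that created
it. The extracted region is the leaf with the extremal estimate, with
rules normalized (tightest bound per exposure and operator).

An exhaustive variant branches on *every* valid split, recurses each
branch, collects all terminal leaves, and selects a leaf by the same
standardized-deviation convention (relative to each leaf's parent node),
which makes it coincide with the greedy search at depth 1. Its cost
grows exponentially with depth and candidate count; it is intended for
few, coarsely binned exposures.

## Cross-estimation and pooling

`aretree()` splits the data into K folds (default 10 for data analysis;
2 is the conventional choice for simulation studies and is what the
bundled simulation harness uses). For fold k, the other folds discover
the region and train the full super-learner nuisances with `T` defined
by that region; the held-out fold receives the predictions and its own
targeted ARE estimate. Pooling stacks the held-out predictions from all
folds, runs a single fluctuation, and reports

$$\hat\Psi_{CV} = \frac{1}{K}\sum_k \frac{1}{n_k}
  \sum_{i \in \text{fold } k} \big(Q^*_{-k}(1, W_i) - Y_i\big)$$

with an influence-function SE over all n. If *any* fold returns the
full space, the result is "no consistent region found" — the all-folds
rule is what drives the familywise spurious-discovery rate toward
`α^K` under a null. Per region group (folds sharing the same set of
constrained exposures) the same pooled update runs on that group's
folds, with the selection proportion and per-rule cutpoint summaries
(mean and range across folds). Fold assignment, learner seeds and any
search randomness all derive from one user seed (fold k's nuisance
seed is `seed + 1009k`), so runs are exactly reproducible.

## Synthetic benchmarks and ground truth

Three data-generating processes are bundled as first-class, tested
code:

* **discrete grid** — two exposures on a 5×5 grid drawn from a
  multinomial logit over the 25 cells whose coefficients act on
  standardized covariates (`W1 ~ N(37, 3)`, `W2 ~ N(20, 1)`,
  `W3 ~ Bernoulli(0.5)`); the coefficients are drawn once from
  N(0, 0.5) under a fixed internal seed and re-drawn until every cell
  probability exceeds 1e-4 on a reference sample, so full-population
  positivity holds by construction (the magnitudes are the package's
  choice; only the distributional family is prescribed). The outcome is
  `Y = 0.2A₁² + 0.5A₁A₂ + 0.5A₂² + 0.2W₁ + 0.4W₃ + N(0, 0.1²)`; the
  maximizing admissible region is the (5, 5) corner.
* **continuous thresholds** — correlated continuous exposures
  (correlation 0.5) whose conditional means are small linear functions
  of the standardized covariates (coefficients 0.1, 0.1, 0.1 and 0.1,
  −0.1, 0; zero intercepts — values chosen so the marginals stay near
  standard normal and the generating thresholds stay interior),
  rounded to one decimal; outcome
  `Y = 3·1{A₁ > 0.5} + 2·1{A₂ < −0.2} + 0.2W₁ + 0.4W₂ + N(0, 0.1²)`.
  The indicators are evaluated on the *rounded* exposures so the
  generating thresholds lie exactly on the candidate grid; in grid
  terms the oracle region is `{A₁ > 0.5, A₂ ≤ −0.3}`.
* **strict null** — exposures confounded by covariates as above but an
  outcome `Y ~ N(0.2W₃, 5²)` that ignores them entirely; any discovered
  region is spurious.

Ground truth comes from Monte Carlo oracle integrators:
`true_regional_mean()` computes `E[Q_𝒜(1, W)]` by exact enumeration
over grid cells (discrete) or nested rejection sampling of `A | W`
(continuous), `true_are()` subtracts a Monte Carlo `E[Y]`, and
`oracle_region_discrete()` enumerates all 225 contiguous level
rectangles. These generators emulate confounded, correlated exposure
mixtures with threshold or null structure; they do *not* emulate
missing data, measurement error, survey weights, heavy-tailed outcomes
or more than two exposures, so green tests certify the machinery under
those stylized conditions rather than performance on arbitrary real
data.

The evaluation harness (`run_simulation_study()`) tracks two truths per
replicate: the fixed oracle-region ARE and the data-adaptive truth (the
true ARE of the replicate's own discovered rule, with the consensus
rule across folds defined by the largest region group's mean
cutpoints). Replicates without a discovery count toward the discovery
rate and are excluded, with a reported count, from bias/MSE. Sample
variances use the n−1 denominator; the MSE decomposition is
`(mean − ψ₀)² + Var`.

## Problem sizes used by the tests and the acceptance script

The test suite exercises the null design at n up to 5,000 with 15–25
replicates per size, the continuous design at n = 200–5,000 with 10–15
replicates, and the discrete design with 10–20 replicates, all with
K = 2 and the mean+GLM learner menu; `scripts/acceptance.R` re-runs the
same studies at 100 null replicates per sample size and 50/30
replicates for the signal designs (80 at the smallest continuous size for Monte Carlo precision). These sizes are the package's
default reduced-scale study; all quantities are recomputed from scratch
at run time from a single seed.

## Known limitations

* The split test ignores the sampling error of the node mean and
  applies no multiplicity correction across candidate cutpoints within
  a node; the cross-estimation layer provides the global error control,
  and the all-folds rule makes whole-procedure false discoveries rare,
  but individual fold-level regions under a null should not be
  over-interpreted.
* The coarse stratification propensity inside the search trades
  adjustment fidelity for speed and stability; fold-level inference
  always re-estimates both nuisances with the full ensemble, but the
  *search* can keep splits a finer confounding model would reject.
* Categorical exposures, oblique (non-axis-aligned) regions, unions of
  rectangles, missing data and survey weights are out of scope; rows
  with missing or non-finite values are rejected at load.
* The pooled estimate is an omnibus quantity: when folds disagree on
  the variable signature, the per-group tables are the interpretable
  unit and the omnibus value only certifies that "some region shifts
  the outcome".
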