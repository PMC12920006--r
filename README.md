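# aretree

Data-adaptive discovery of exposure threshold regions and targeted
estimation of their policy effect.

## The problem

Environmental-health studies rarely involve a single exposure: people are
exposed to mixtures of chemicals whose combined toxicity can differ
sharply from any component alone. Regulators, however, need *interpretable*
rules — cut points such as "molybdenum ≤ 104 and lead ≤ 1.2" — together
with an estimate of what enforcing those limits would do to the
population-average outcome.

`aretree` addresses both needs. Given observational data
`O = (W, A, Y)` (covariates, a multivariate exposure, an outcome), it

1. searches the exposure space for an axis-aligned threshold region
   `𝒜 = {A_j ≤ τ_j or A_j > τ_j, …}` in which the expected outcome is
   maximized (or minimized), using a recursive partitioning algorithm in
   which every candidate split must pass a minimum-node-size filter, a
   positivity filter on the estimated split propensity
   `π(w) = P(A ∈ 𝒜 | W = w)`, and a significance filter on the targeted
   (TMLE-updated) child-mean difference from the parent node; and
2. estimates the **attributable regional effect (ARE)**,

   `ψ_𝒜 = E[Q(1, W)] − E[Y]`,  with `Q(1, w) = E[Y | A ∈ 𝒜, W = w]`,

   the change in mean outcome if everyone were restricted to `𝒜` while
   keeping their relative exposure preferences inside it ("relative
   self-selection"). Estimation uses K-fold cross-estimation: each fold's
   training half discovers the region and fits super-learner nuisances
   (outcome regression `Q̂` and propensity `ĝ`), the held-out half
   supplies the targeted estimate, and a pooled TMLE fluctuation over the
   stacked held-out predictions yields the cross-validated ARE with an
   efficient-influence-function standard error. If any fold fails to find
   a region the procedure reports "no consistent region found", which
   drives the familywise false-discovery rate toward `α^K` under a null.

## Worked example

```r
library(aretree)

# two correlated continuous exposures; Y gains 3 units when A1 > 0.5 and
# 2 units when A2 < -0.2, confounded by W1 and W2
d <- generate_mixture(continuous_dgp_spec(), n = 2000, seed = 7)

fit <- aretree(d, K = 2,
               tree_cfg = tree_config(objective = "max"),
               ens_cfg  = ensemble_config(c("mean", "glm")),
               seed = 7)
print(fit)
```

```
aretree: 2-fold cross-estimated threshold region
fold-specific results:
 fold   are      se ci_low ci_high p_value                region
    1 3.298 0.05607  3.188   3.408       0 A1 > 0.5 & A2 <= -0.4
    2 3.304 0.04868  3.208   3.399       0 A1 > 0.5 & A2 <= -0.4

pooled CV-TMLE ARE = 3.301 (SE 0.03714, 95% CI [3.229, 3.374], p = 0)
region groups:
 signature      are         se   ci_low ci_high p_value proportion_folds
     A1&A2 3.301401 0.03713729 3.228612 3.37419       0                1
                                        region
 A1 > 0.5 (0.5, 0.5) & A2 <= -0.4 (-0.4, -0.4)
```

Both folds recover the A1 threshold exactly and the A2 threshold one
grid step inside the generating boundary (on the 0.1 rounding grid the
strict rule `A2 < -0.2` is `A2 <= -0.3`; at this moderate `n` the folds
settled on `-0.4`, a sub-region with the same population effect). The
pooled ARE of 3.30 estimates the true effect of restricting everyone to
the region — `3 + 2 − E[3·1{A1>0.5} + 2·1{A2<−0.2}] ≈ 3.32` — with a 95%
interval that covers it. Against the region each replicate actually
discovers (the data-adaptive parameter), the estimator's absolute bias
at `n = 200` is about 0.2 and vanishes by `n = 5000`.

Ground truth for any region under the bundled data-generating processes
comes from the Monte Carlo oracle integrators:

```r
true_are(continuous_dgp_spec(), continuous_oracle_region(), n_mc = 1e5)$are
#> 3.3226
oracle_region_discrete(discrete_dgp_spec())$region
#> A1 > 4 & A2 > 4
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/aretree` (subcommands `discover`, `simulate`, `evaluate`).

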