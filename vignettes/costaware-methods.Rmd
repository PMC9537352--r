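---
title: "Budgeted feature selection for risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budgeted feature selection for risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costaware)
```

## The problem

A risk model is only usable at the point of care if the data it needs can be
gathered within the time, money, or attention available there. Prehospital
providers have minutes, not the quarter hour a feature-rich score might
demand; an outpatient panel has a dollar cost; in intensive care the burden
is often counted simply as the number of inputs a score requires. The
question this package answers is: *given a trained model class, per-feature
acquisition costs $c_i$, and a budget $k$, which feature subset should a
deployed model use?*

## The procedure

The core idea is to decouple "how predictive is each feature" from "what can
we afford", and to solve the second question exactly.

1. **Fit once on everything.** The base model (logistic regression or
   gradient-boosted trees; any adapter implementing `fit`/`predict` works)
   is trained on all features of the train split.
2. **Attribute.** Per-sample additive (Shapley) attributions $\phi_{ij}$ are
   computed for that model on held-out samples and reduced to a global
   importance $\phi_i$, the mean absolute attribution across samples
   (`sum_abs` is available; the two differ by the constant sample count, so
   any budget selection is identical under either).
3. **Select.** The deployed feature set is
   $F = \arg\max_S \sum_{i \in S}\phi_i$ subject to
   $\sum_{i\in S} c_i \le k$ — a 0/1 knapsack problem, solved exactly by
   dynamic programming over integer-scaled costs.
4. **Retrain.** A fresh model of the *same class with the same
   hyperparameters* is fitted on $F$ alone. That retraining step is a
   heuristic, but an important one: the full model's parameters were
   estimated in the presence of the discarded features, and simply masking
   those features misweights whatever correlates with them.

Steps 1–2 are computed once; every additional budget costs exactly one more
fit. A single budgeted model therefore costs two trainings — the property
that makes direct budget targeting dramatically cheaper than tuning a
unitless cost penalty by trial and error (see the bisection harness below).

Shapley attributions are used because they are additive (they sum, with a
base value, to the model's output — so summing them over a candidate set is
a principled set-level importance), consistent, and model-agnostic. The
assumption the selection step inherits is that set importance is the *sum*
of member importances; feature interactions are not modeled at selection
time, and the retraining step is what absorbs most of the resulting slack.

## Attribution machinery

* **Masking semantics.** $f_x(S)$ is estimated interventionally: background
  samples have their coordinates in $S$ overwritten by $x$ and the model
  outputs are averaged. The background defaults to (a subsample of) the
  train split, collapsing to the train-mean vector for linear models, which
  matches the mean-imputation convention used in preprocessing. Conditional
  (observational) expectations are out of scope.
* **Exact mode** enumerates the $2^M$ subset values and applies the
  permutation weights $|S|!(M-|S|-1)!/M!$; it is capped at $M = 12$ and
  exists mainly as the oracle for everything else.
* **Sampling mode** draws feature orderings uniformly (default 200 per
  sample, seeded) and averages marginal contributions; it is the portable
  path for arbitrary adapters and carries a per-feature Monte-Carlo
  standard error.
* **Fast paths.** Linear models use the closed form
  $\phi_i = w_i(x_i - \bar x_i)$; tree ensembles delegate to the boosting
  library's built-in per-prediction attribution. The test suite checks the
  closed form against exact enumeration on random linear models, and the
  sampler against the exact values within three standard errors.
* **Evaluation split.** Global importances are computed on the validation
  split by default: train-split attributions can reflect overfit structure,
  and the test split must stay untouched. This is a genuine design choice —
  any held-out set would do — and it is exposed as a parameter.

## Costs, pseudocosts, groups

Cost tables are read from `feature,cost[,group]` text files; blank cells are
*missing*, not zero, and are mean-imputed over the known costs (idempotent).

Zero-cost features (dispatch information, already-recorded procedures) are
real and common, but break importance-per-cost ratios. Each zero-cost
feature receives a pseudocost $\varepsilon = g / (2(z+1))$, where $g$ is the
minimum gap between distinct nonzero costs and $z$ the number of zero-cost
features; the factor 2 makes the sum of pseudocosts *strictly* less than
$g$, so no feasible selection at any budget changes — the pseudocosts exist
only to rank free features. When fewer than two distinct nonzero costs
exist the gap is undefined and $g$ falls back to the minimum nonzero cost.
Realized model costs are always reported with original costs; pseudocosts
affect ranking and feasibility checks only.

Grouped acquisition (a lab panel, the indicator columns of one categorical)
is handled by optimizing over groups: group importance is the sum of member
importances, group cost is the single cost $c_g$ of the acquiring action,
and a selected group brings in all its members. A group's cost must be
supplied explicitly; deriving it as the maximum of member costs is opt-in,
and member costs are never silently summed, because grouped acquisition is
one action.

## The knapsack solver

Costs are real-valued (minutes, dollars), so the dynamic program runs on
integer-scaled costs $\lceil c_i/r \rceil$ with capacity
$\lfloor k/r \rfloor$. The default resolution $r$ is $10^{-3}$ of the
smallest nonzero *original* cost — original rather than effective, so that
the deliberately tiny pseudocosts do not inflate the DP table. The scaled
solution is never over budget and is exact whenever all costs are multiples
of $r$; with incommensurate costs it can be conservative at razor-tight
budgets, which is the standard behavior of scaling-based knapsack schemes.
Budgets beyond the total cost are clamped to it (they are unconstrained),
and a guard caps the DP table at $5\times 10^7$ cells.

Determinism matters for reproducibility, so ties are broken explicitly:
maximum total importance, then minimum realized cost, then earliest file
order (the cost file's row order is authoritative). Features with zero
importance are excluded before the DP — they cannot raise the objective.
The exhaustive-enumeration oracle implements the same ordering and is the
ground truth for the solver tests.

## Alternate strategies

* **Greedy**: rank by $\omega_i = \phi_i/c_i$, add from the top. The
  stopping text for such procedures is ambiguous between "stop at the first
  feature that does not fit" and "skip it and keep scanning"; the default
  here is skip-and-continue (it uses more of the budget), with
  `stop_at_first_failure` available.
* **Recursive elimination**: fit, attribute, drop the worst-$\omega$
  feature, repeat while the surviving set exceeds the budget. Attributions
  are recomputed every round, so the procedure tracks feature dependence;
  the price is one fit per removal. The stopping criterion is the cost
  constraint, with a survivor-count mode exposed, since descriptions of
  this family mix the two. The last within-budget fit *is* the final model:
  refitting the same feature set with the same hyperparameters and seed
  would duplicate it, so removals of $M-m$ features cost $M-m+1$ fits.
* **Knapsack without retraining**: same selection, but the full model is
  kept and unselected features are masked to train means at prediction
  time. One fit total; the test suite checks the directional claim that
  retraining does not hurt (and the synthetic design below shows where
  masking actively misleads).

A budget of zero (or one that affords nothing) yields a constant model
scoring the train-split base rate — AU-ROC 0.5 by construction. This is a
definition choice for the $k \to 0$ limit; it costs no base-model fit, so
sweep fit counts are one (full model) plus one per budget with a nonempty
selection.

## Evaluation toolkit

AU-ROC uses the rank formulation with ties counted one half. Recall at a
precision target scans thresholds and takes the best recall whose precision
meets the target; false-to-true alert ratios map to precision targets (4:1
tolerance = precision 0.2) on the caller's side. Deployment extrapolation
multiplies recall by the positive count in the target population and rounds
half away from zero.

Replicated cost-performance curves are aligned by previous-value (step)
interpolation onto a common grid of 100 linearly spaced costs: each cell
takes the most expensive model at or below the grid cost, a conservative
estimate. Grid points below a replicate's cheapest model are masked and
excluded from that replicate's mean by default (carrying the cheapest value
down is available); whether to mask or extend there is genuinely
underdetermined, and masking was chosen as the less flattering option.
Curve sets are compared by a two-sided paired t-test on per-replicate mean
AU-ROC, paired by train/test split; identical inputs give $t = 0, p = 1$,
and constant nonzero differences are flagged as degenerate rather than
silently producing an infinite statistic.

The bisection harness targets a budget for learners tuned by a unitless
tradeoff penalty $\lambda$ under the monotonicity assumption (cost and
accuracy both fall as $\lambda$ grows): train, test feasibility, move the
matching bound, continue at the midpoint, up to $T = 128$ trainings with
bounds $[0, 10^6]$ and $\lambda_0 = 1$. The implementation is deliberately textbook bisection
with explicit bound maintenance — shorthand update formulas for this kind
of search are easy to state ambiguously, and determinism of the search
path matters here. Every iteration is one training — the count the harness
exists to report against the two trainings of direct budget targeting.

## The synthetic cohort generator

Real cohorts of this kind (trauma registries, ICU stays, outpatient
surveys) are access-controlled, and none of them comes with a known optimal
feature set. The generator therefore produces class-conditional independent
Gaussians: label $y$ at a configurable prevalence, feature $j$ drawn as
$d_j y + \epsilon$, $\epsilon \sim N(0,1)$. Under independence everything
is closed-form: the Bayes score on subset $S$ is $d_S \cdot x_S$ and its
AU-ROC is $\Phi(\lVert d_S \rVert_2/\sqrt 2)$, so the budget-constrained
optimal subset can be found by enumeration and the end-to-end pipeline can
be scored on *recovering* it. Categorical features are emulated by
quantile-binning a latent Gaussian; the indicator columns inherit the
block's group and cost. A correlated mode (arbitrary noise correlation)
exists for stress tests and carries no closed-form claims.

Templates mirror the three deployment archetypes: `trauma_like_spec()` (45
features, 8 free dispatch-style features, minute costs, prevalence 0.06),
`icu_like_spec()` (43 unit-cost features, prevalence 0.09), and
`outpatient_like_spec()` (27 groups giving 35 features that one-hot expand
to 118 columns, dollar costs including free physical-exam groups,
prevalence 0.12). The prevalences and cost values are this package's
choices of a realistic rare-outcome regime, not estimates of any particular
cohort.

Two further specs define the validation conditions and were designed
analytically, before any pipeline run, so that their conclusions are not
artifacts of tuning:

* `recovery_spec()`: eight blocks with strictly decreasing effects
  (1.5 down to 0.05) and strictly increasing costs (1 to 8). At budget 6
  the optimum {f1, f2, f3} maximizes both the attribution sum and the
  squared effect norm with wide margins, so recovery is well-posed. The
  acceptance suite requires the pipeline (n = 5000, 50 seeded replicates)
  to recover it in at least 90% of replicates and to match the closed-form
  AU-ROC of that subset within 0.02. Note that the two objectives do *not*
  coincide in general — linear-model importances scale like $|d|$ while
  discrimination scales like $\lVert d\rVert_2$ — which is why the
  benchmark is constructed to align them; the package's own
  `true_best_subset()` documents the squared-norm objective.
* `strategy_spec()`: five blocks with effects (0.9, 0.8, 0.35, 0.1, 0.1),
  costs (4, 4, 1, 2, 2), and noise correlation 0.75 between the second and
  third. The greedy ratio ranking commits to the cheap third feature and at
  budget 8 cannot afford the two strong ones the knapsack takes; masking
  without retraining mis-weights the third feature whenever its correlated
  partner is masked (at budget 2 the full model's negative coefficient on
  it reverses the ranking outright). These mechanisms give the directional
  ordering — exact selection with retraining at or above greedy and
  no-retrain — real margins rather than coin-flip ties.

What passing these tests shows is that the machinery is correct under the
generator's assumptions: independent (or explicitly correlated) Gaussian
features, additive signal, no missingness mechanism, no temporal structure,
no label noise beyond class overlap. Real clinical data violate all of
these to some degree; the synthetic results bound implementation error, not
clinical performance.

## Problem sizes and seeds

The test suite and the acceptance script run on deliberately modest sizes —
cohorts of 1,500–5,000 samples, 5–8 blocks for the benchmarks, 100 random
instances for the solver and attribution oracles, 50 recovery replicates, 6
strategy-sweep replicates over 5 budgets — sizes at which every closed-form
margin above is orders of magnitude larger than the Monte-Carlo noise. One
pipeline seed deterministically derives the split, model and attribution
seeds, so every reported number is reproducible bit-for-bit for a given
seed.

## Known limitations

* Additive cost model: a feature set's cost is the sum of its members'
  (group) costs; settings with parallel acquisition need a different cost
  structure.
* Additive importance at selection time: interactions are only absorbed via
  retraining (and via re-attribution in the elimination strategy), not
  modeled in the objective.
* The scaled knapsack can be conservative at exactly budget-tight optima
  with incommensurate costs (see above).
* Per-sample adaptive acquisition — asking different features for different
  patients — is a different paradigm and out of scope; every model here
  requests one fixed feature set per budget.
* Deep-model attribution backends and observational SHAP variants are not
  provided.
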