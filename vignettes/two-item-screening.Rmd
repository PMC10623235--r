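---
title: "Selecting and validating two-item depression screening instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating two-item depression screening instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phqpairs)
```

## The problem

The PHQ-9 asks nine questions about depressive symptoms over the previous two
weeks, each answered on a 0--3 ordinal scale, and a total score of at least 10
is the conventional screen-positive criterion for depressive symptomatology.
Ultrabrief prescreening uses only two of the nine items to decide who should
receive the full questionnaire. The traditional instrument, the PHQ-2, sums
the first two items (anhedonia and depressed mood, the "cardinal" symptoms)
and applies an integer cutoff, usually 2 or 3. That choice of items is a
clinical convention, not an empirical optimum, and the unweighted sum is only
one of many possible decision rules on two ordinal items.

`phqpairs` implements the alternative: fit a small logistic classifier to
*every* one of the $\binom{9}{2} = 36$ item pairings, rank the pairings by
cross-validated AUC, pick each model's decision threshold by cross-validated
Youden index, and validate the frozen instruments on held-out data against the
PHQ-2 cutoffs.

## The model

For a pairing of items $i$ and $j$ with responses $a, b \in \{0,1,2,3\}$, the
classifier is plain logistic regression,

$$ z = w_1 a + w_2 b + c, \qquad
   \hat y = \sigma(z) = \frac{1}{1 + e^{-z}}, $$

fitted by minimizing the mean negative log-likelihood plus an L2 penalty
$(w_1^2 + w_2^2) / (2C)$ on the weights only. The intercept is unpenalized so
it can absorb the class prevalence; $C$ is an *inverse* penalty (larger $C$ =
weaker penalty), the convention of most ML toolkits. The objective is strictly
convex, so the optimum is unique; `pair_logit()` finds it by Newton--Raphson
on the 16 aggregated response patterns and refuses to return anything unless
the gradient norm falls below $10^{-8}$.

Because the input space is the finite $4 \times 4$ pattern lattice, the model
induces at most 16 distinct predicted probabilities, hence at most 16
achievable decision rules ("candidate thresholds"). An unweighted two-item
sum score induces only 7 (cutoffs 0--6); when $w_1 = w_2 > 0$ the two rule
families coincide exactly, which is both a sanity check and the precise sense
in which the logistic lattice generalizes the psychometric cutoff.

## The selection procedure

`pair_screen_study()` composes the stages, each of which is exported on its
own:

1. **Split** (`split_dataset`): stratified train/test split. The training
   size is `round(fraction * n)` apportioned across label strata by largest
   remainder, so a 4025-row table at fraction 0.6999 always gives 2817/1208.
   Stratification is a design choice (the source procedure does not state
   it); it keeps prevalence equal across splits and lowers the variance of
   every downstream estimate.
2. **CV plan** (`make_cv_folds`): stratified k-fold (default 5) with
   within-stratum remainders placed on the currently smallest folds, so
   overall fold sizes differ by at most one. If a class has fewer members
   than folds, stratification is impossible and the function falls back to
   balanced unstratified folds with a warning.
3. **Penalty tuning** (`tune_regularization`): mean out-of-fold AUC over a
   deterministic log-spaced ladder of $C$ values spanning `reg_range`
   (default $10^{-3}$--$10^{3}$), refined once between the incumbent's
   neighbours, at most `budget` evaluations. The contract is argmax over the
   evaluated set. With two items, AUC -- which sees only the score ordering
   -- often ties exactly across penalties; ties resolve to the weakest
   penalty so the frozen coefficients stay near the unpenalized MLE rather
   than collapsing toward a flat lattice.
4. **Ranking** (`rank_pairings`): all 36 pairings by tuned mean CV AUC,
   descending, exact ties broken lexicographically.
5. **Freezing** (`finalize_instrument`): final fit on the full training
   split; every candidate pattern rule of that model is scored on each CV
   validation fold (rules are pattern partitions, so they are evaluable
   out-of-fold without mixing fold-model probability scales -- the
   resolution of a genuine ambiguity in how a "CV Youden" for a final-model
   threshold should be computed); the rule with maximal mean CV Youden is
   frozen. Youden ties break toward sensitivity, because prescreening is a
   rule-out application.
6. **Validation** (`evaluate_instrument`, `compare_instruments`): frozen
   instruments -- no retraining, no threshold adjustment, parameter
   fingerprints checked before and after -- evaluated on held-out or
   external-style data next to the PHQ-2 cutoffs.

AUC is everywhere the tie-corrected rank (Mann--Whitney) statistic. With at
most 16 distinct scores ties are pervasive and interpolation conventions
diverge; the rank form is unambiguous and equals the trapezoid under the
closed ROC polygon, which the tests assert to $10^{-12}$.

## The synthetic-data generator

No survey data ship with the package. `sim_config()` + `simulate_responses()`
generate the structure the analysis assumes, via a Gaussian copula: a latent
multivariate normal with a one-factor correlation structure (a common
severity factor) discretized through per-item cut points that reproduce
configured marginals. This separates marginals from dependence cleanly and is
the standard simulation model for correlated Likert items.

Defaults, chosen once as a realistic community-screening profile:

* **Marginals**: skewed toward 0 with a mild severity gradient across items
  (late items, e.g. suicidal ideation, endorsed least). Real item-level
  marginals are not published for the motivating cohorts; these are a
  package decision, not a data fact.
* **Loadings**: 0.55--0.75 on the common factor, typical of reported PHQ-9
  factor analyses. The implied screen-positive prevalence is about 26%,
  inside the 8%--30% range spanned by published screening cohorts.
* **Prevalence** is tunable by `calibrate_prevalence()`: a single scalar
  severity offset shifts all cut points in lockstep, and monotone bisection
  (with a fixed internal Monte-Carlo seed, so the bisected function is
  deterministic) matches P(total >= 10) to any target in the achievable
  range. One degree of freedom keeps the calibration well-posed.
* **Planted ground truth**: `plant_informative_pair()` multiplies two items'
  factor loadings by a boost and rebuilds the one-factor correlation, making
  those items carry the most information about the severity that drives the
  sum score -- a known best pairing for recovery experiments. Recovery runs
  use uniform 0.55 loadings so a 1.5x boost stays below the loading bound
  of 1.

What the generator does *not* emulate: multidimensional symptom structure,
differential item functioning across demographics, mode-of-administration
effects, longitudinal drift. Passing recovery tests therefore show that the
pipeline finds planted univariate-severity structure, not that any particular
pairing is optimal in real populations.

## Numerical choices

* Missing data follow the standard screening rules: rows with more than two
  missing items are excluded; the rest are imputed with the item's mode,
  computed per data set. Mode ties break to the lower (less symptomatic)
  response -- deterministic and conservative. Labels are computed after
  imputation.
* Newton--Raphson uses step halving before the quadratic regime and a
  $10^{-8}$ gradient-norm stopping rule; non-convergence is an error.
* Candidate thresholds merge probabilities closer than $10^{-12}$.
* Classification is always `score >= threshold`.
* PPV/NPV are reported from exact confusion counts (flagged `NaN` on empty
  denominators) and match the Bayes formula at the empirical prevalence to
  machine precision; they are never optimized.
* All randomness flows through explicit integer seeds; every function
  restores the caller's RNG state.
* Serialization uses 17 significant digits so parameters round-trip exactly.

## Problem sizes used in the test suite

The suite regenerates everything in code: marginal-fidelity and copula
checks at $n = 10^5$ against a quadrature oracle; fit checks against a staged
convex grid search over $[-5,5]^3$ (final step $\sim 3\times10^{-4}$);
AUC checks against the all-pairs double loop on 200 instances; pairing
recovery over 50 seeds at $n = 4000$ with boost 1.5; prevalence calibration
to 8.5% and 30% at $n = 10^5$. These sizes were chosen so the whole suite
runs in about a minute while keeping Monte-Carlo noise an order of magnitude
below every asserted tolerance.

## Known limitations

* The reference standard is itself a questionnaire cutoff (total >= 10), not
  a clinical diagnosis; nothing here validates instruments against
  structured interviews.
* AUC differences between pairings on realistic one-factor data are small;
  ranking stability on real multidimensional data will be worse than on the
  simulator.
* Only plain CV plus one held-out split is provided (no nested CV), and no
  confidence intervals are attached to AUC or operating-point metrics.
* Survey weights and multiple imputation are out of scope.
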