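---
title: "Hybrid rule-augmented gradient boosting for binary clinical risk prediction"
author: "ruleboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid rule-augmented gradient boosting for binary clinical risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Risk stratification in acute care often starts from a small table of
binary findings: does the patient have a history of heart failure, was
the episode exertional, is the ECG abnormal, and so on. The prototype
setting for this package is 30-day prognosis after an emergency-department
evaluation for syncope: a few hundred patients, a few dozen sparse binary
predictors, an adverse-event prevalence near 17%, and scattered missing
values. Two things make this regime hard for off-the-shelf machine
learning. First, the events-per-variable ratio is very low, so flexible
models overfit unless they are kept severely small. Second, clinicians
hold reliable combinatorial knowledge — "syncope during exertion in a
patient with known heart failure is worrying even if each factor alone is
common" — that a tree ensemble trained on 200 patients cannot learn
dependably.

`ruleboost` implements a hybrid answer: a deliberately tiny
gradient-boosted tree classifier supplies a base event probability, and a
small curated knowledge base (KB) of conjunctive logical rules moves that
probability up or down for patients matching each rule.

## The model

The base classifier is an XGBoost binary ensemble over a chosen predictor
set. For a patient with feature row $x$ it outputs $p(x) \in (0,1)$.

Each KB rule has the form

> IF $\ell_1 \wedge \ell_2 \wedge \ldots$ THEN raise (or lower) the
> predicted probability,

where each literal $\ell_j$ requires one binary feature to equal 0 or 1
(a value-0 literal encodes "absence of" a factor) and a rule carries at
most three literals. A rule also carries a curated rank — low, medium, or
high — mapped to a positive log-odds offset $\delta_{\text{rank}}$. The
hybrid prediction is

$$\operatorname{logit} p^{*}(x) \;=\; \operatorname{logit} p(x) \;+\;
\sum_{r \,:\, x \models r} s_r\, \delta_{\text{rank}(r)},$$

with $s_r = +1$ for probability-increasing rules and $-1$ for
probability-decreasing rules, and $x \models r$ meaning every literal of
$r$ holds for $x$. Additive adjustment in log-odds space was a design
choice the source material left open: it keeps the output strictly inside
$(0,1)$ with no ad-hoc clipping, composes symmetrically (two equal-rank
rules in opposite directions cancel exactly), and makes the hybrid
reduce *exactly* to the base model when the KB is empty. Multiple fired
rules combine by summing their signed offsets; we chose not to take the
maximum or to short-circuit conflicts because the sum is the only
combination rule that is associative, order-free, and monotone in each
fired rule. Increase and decrease rules share the same magnitude scale;
nothing in the problem suggested an asymmetry, and the deltas are fully
configurable per KB file if a user wants one.

Base probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before the
logit so that a saturated tree score cannot produce an infinite
adjustment.

## The pipeline

`run_pipeline()` reproduces the full development procedure:

1. **Load and preprocess.** Cells are tri-state (0, 1, missing; the
   missing tokens default to `""`, `"NA"`, `"NaN"` and are configurable).
   Features constant among their observed values are removed — they
   cannot carry predictive signal, and a feature constant-except-missing
   becomes fully constant after imputation, so it is removed too.
   Missing values are imputed with the per-feature mode; exact 0/1 ties
   are broken toward 0, the majority value in a sparse table, and
   flagged.
2. **Predictor sweep.** Every feature is scored against the outcome with
   the uncorrected Pearson chi-squared statistic on the 2×2 table, and
   nested top-$k$ predictor sets are formed for every $k$. On 2×2 tables
   the statistic has one degree of freedom, so ranking by statistic and
   ranking by p-value coincide; we rank by the statistic. Tables with a
   zero margin score 0 rather than erroring, so degenerate features sink
   to the bottom of the ranking. Ties break by feature name to keep the
   ranking deterministic.
3. **Knowledge base.** Either supplied as a file (JSON or CSV; the
   curated artifact a domain expert would edit) or mined: all conjunctive
   antecedents up to arity 3 over both polarities are enumerated and
   scored on the full imputed data; survivors need support of at least
   `min_support` (default 10) and a subgroup-versus-baseline event-rate
   fold change of at least `min_effect_ratio` (default 1.5) in either
   direction. Expert review of clinical plausibility is inherently
   irreproducible, so the package replaces it with this quantitative
   screen plus an editable curation table that can override any rule's
   rank; automatic ranks are tertiles of the absolute log effect ratio.
   The KB is capped (default 20 rules) to keep the hybrid model simple
   and auditable.
4. **Hybrid predictor sets.** For each $k$, the hybrid model's predictor
   set is the base set united with every feature referenced by the KB,
   since the hybrid must evaluate its rules.
5. **Paired repeated evaluation.** For every $k$ and both models: 100
   random 80/20 splits (test size $\lfloor 0.2 n \rfloor$), modes
   refitted on each training part only, both parts imputed, the boosted
   model trained, and F1, AUC, MCC and ECE computed on the held-out
   rows. Base and hybrid use identical split seeds, so all comparisons
   are paired; per-iteration test-row hashes are kept so pairing can be
   audited. A split whose test part has only one outcome class would
   leave MCC and AUC undefined, so it is redrawn with an incremented
   sub-seed (logged, bounded retries) rather than silently accepted.
6. **Selection and reporting.** The operating $k$ per model is the
   argmax of mean MCC across splits, ties toward the smaller $k$
   (parsimony). The two selected models are compared with two-sided
   paired t-tests on the per-iteration metric vectors — the pairing is
   by split, which is what the identical seeds guarantee. ROC curves are
   vertically averaged: each iteration's empirical ROC staircase is
   evaluated on a fixed 101-point false-positive-rate grid and the mean
   and SD of the true-positive rate are reported per grid point.

### Selection leakage

The headline procedure ranks predictors and mines rules on the *full*
imputed dataset before splitting. With a cohort of a few hundred rows
there is no room for a third, held-out selection partition, and the
procedure accepts the resulting optimism in exchange for stability; the
repeated splits then measure variance honestly *given* that selection.
This is a faithful reproduction of the development setting, and it is the
default. A leakage-free alternative is available:
`repeated_evaluation(..., selection = "per_split")` re-ranks features by
chi-squared inside each training fold and takes the top-$k$ there, never
touching test rows during selection.

## Tunable parameters

* `positive_class_weight = 5.2` — the boosted model's positive:negative
  weight ratio, compensating the ~5:1 class imbalance. We use the
  stated operating value rather than recomputing it from any particular
  cohort's ratio.
* `n_trees = 7`, `max_tree_depth = 6` — a deliberately tiny ensemble;
  at $n$ in the low hundreds more rounds overfit quickly. All other
  booster settings stay at library defaults, and the resolved parameter
  list is recorded in the run manifest.
* `threshold = 0.5` — probability cutoff for F1/MCC (boundary
  inclusive). No operating threshold was prescribed; 0.5 is the neutral
  default and it is a config key.
* `fraction_test = 0.2`, `n_iterations = 100` — the repeated holdout
  design.
* `min_support = 10`, `min_effect_ratio = 1.5`, `max_arity = 3` —
  mining thresholds: roughly "at least ten patients and a half-again
  departure from the baseline rate". On sparse cohorts these admit many
  candidates; the rank tertiles and the 20-rule cap are the operative
  simplicity controls.
* `rank_deltas = (low 0.4, medium 0.8, high 1.2)` — log-odds offsets
  per rank. At a base probability of 0.2 these move the prediction to
  0.27, 0.36 and 0.45 respectively: noticeable but not dominating, and
  an evenly spaced ladder keeps the ranks interpretable. Configurable
  per KB.
* `ece_bins = 10` — expected calibration error bins; equal-width,
  right-closed except the first.

## Metrics

MCC, F1, AUC and ECE are implemented from first principles (and
cross-checked against independent brute-force implementations in the test
suite). Conventions worth stating:

* MCC returns 0 whenever a denominator factor is zero — an all-one-class
  prediction is "no better than random".
* AUC is the rank-based (Mann–Whitney) form with ties counted one half;
  it equals the trapezoidal area under the empirical ROC.
* ECE uses the event-probability (reliability-diagram) formulation:
  per-bin accuracy is the observed event fraction and confidence is the
  mean predicted probability, matching a reliability diagram for the
  positive class. The predicted-class-confidence variant is available via
  `ece(..., variant = "class")`.
* A paired t-test on zero-variance differences is flagged rather than
  computed: all-zero differences are reported as an exact tie.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical regime the pipeline assumes:
266 patients; 35 sparse, independent Bernoulli features with rates spread
evenly from 0.02 to 0.5 (mirroring the range of prevalences a clinical
risk-factor table typically spans, from rare ECG findings to common
comorbidities); 3 all-zero constant columns; ~17% outcome prevalence; 1%
missing cells, completely at random. Event probabilities follow a
logistic model whose terms are planted conjunctive rules (so mining
recovery is testable against ground truth), with the intercept calibrated
by bisection on the realized feature matrix so the *expected* prevalence
hits the target within $10^{-6}$; the realized prevalence then varies
with binomial noise. Everything is deterministic given the config seed.

What it does **not** emulate — and therefore what passing tests on it do
not establish about real data: correlated comorbidity structure (an
optional block-correlation stress mode aside, features are independent),
informative missingness (real missingness is rarely MCAR), measurement
error in the predictors, and any distribution shift between development
and deployment populations.

## Numerical choices and degenerate inputs

* Split seeds derive from the base seed by
  `seed_i = (base_seed * 48271 + i * 16807) mod (2^31 - 1) + 1`, keeping
  every derived seed a valid positive 32-bit integer; training seeds
  derive from split seeds the same way. One base seed reproduces an
  entire run bit-exactly.
* ECE bin assignment is `ceiling(p * n_bins)` clamped to `[1, n_bins]`:
  bins are right-closed, the first bin additionally contains 0, and
  empty bins contribute 0.
* Rule mining sorts survivors by effect strength
  ($\max(r, 1/r)$ of the rate ratio, with a zero subgroup rate counting
  as infinitely strong), then support, then the antecedent string, so
  candidate order — and hence the capped KB — is deterministic.
* An antecedent with zero support, or scored on a cohort with no events,
  is flagged unusable instead of producing NaN statistics.
* Chi-squared accumulates its 2×2 products in double precision
  (four counts of ~250 already overflow 32-bit integer multiplication).
* Degenerate splits: redraw with sub-seed increments, at most 100 times,
  then error — never a silent drop.

## Problem sizes in the shipped checks

The test suite and the acceptance script exercise the pipeline at the
sizes the package targets: the full 266×38 cohort with 100 iterations
across all 35 predictor counts for the end-to-end determinism check, a
2000-patient cohort for mining recovery, and a 500-patient benchmark in
which the features driving the planted rules are withheld from the base
model's predictor set — there the hybrid model's mean MCC exceeds the
base model's, reproducing the qualitative ordering that motivates the
hybrid design.

## Known limitations

* Binary predictors only; continuous or multi-level variables must be
  dichotomized upstream.
* The mined KB is learned from the same data the model sees; without
  external curation it inherits the dataset's quirks. The curation file
  is the intended correction mechanism, and externally authored KBs
  bypass mining entirely.
* Mean ± SD over repeated holdouts understates uncertainty about the
  single deployed model; no confidence intervals beyond that are
  provided by design.
* The generator's independence assumption makes mining *easier* than on
  correlated clinical data; recovery results there are upper bounds.
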