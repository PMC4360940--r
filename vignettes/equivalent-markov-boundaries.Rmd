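---
title: "Enumerating equivalent Markov boundaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating equivalent Markov boundaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

mbtie addresses a structural fact about clinical risk prediction: when
recorded features are partially redundant, the minimal maximally
predictive feature set of a binary outcome — its Markov boundary (MB) —
need not be unique. Two feature sets are *information-equivalent* when
they carry identical information about the outcome, making them
interchangeable as predictors. The package's job is to enumerate the whole
family of MBs whose predictive accuracy is statistically equivalent, and
to quantify each feature's robustness as the fraction of discovered
boundaries that contain it.

The pipeline composes four layers, each independently testable:

1. **Conditional-independence (CI) testing.** The default engine is the
   G² likelihood-ratio test on contingency tables, stratified over the
   conditioning set, with degrees of freedom summed from per-stratum
   *realized* level counts. A Fisher-z partial-correlation test serves
   continuous pipelines. Dependence is declared only on a *reliable* test
   (average samples per cell ≥ `min_avg_cell`) with p ≤ α.
2. **MB induction.** A HITON-PC-style semi-interleaved learner: candidates
   with reliable univariate association enter in rank order (p ascending,
   statistic descending, name ascending); after each admission, any member
   rendered independent of the outcome given a subset (size ≤ `max_k`) of
   the other members is eliminated; a final backward pass confirms
   minimality.
3. **Equivalence search.** Starting from the reference MB, exclusion sets
   are processed from a deterministic agenda (size ascending, then
   lexicographic). Each entry re-induces an MB with those features
   excluded; a candidate joins the pool iff its feature set is new and its
   score passes the equivalence criterion against the reference; each
   admission extends the agenda with every union of an already-processed
   exclusion set and one member of the new boundary. The agenda never
   revisits an exclusion set and is capped by a budget.
4. **Evaluation.** SVM decision scores (LibSVM via e1071), features
   standardised on the training partition only; AUC by the Mann–Whitney
   formulation with half credit for ties; repeated stratified k-fold
   cross-validation with the search confined to each training partition.

## Assumptions

- The outcome is a *sink*: features cause or correlate with it, but no
  feature is a consequence whose spouses would need recovery. On such
  problems the parents/children set returned by the learner *is* the
  Markov boundary. Spouse recovery is deliberately omitted (see
  Limitations).
- For the G² engine, all features are discrete; continuous measurements
  must pass through `discretize()` first.
- Equivalence of predictive accuracy is judged on the training partition's
  internal cross-validation scores, never on outer test data, so outer
  AUCs remain unbiased estimates.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | CI significance level (dimensionless) |
| `max_k` | 3 | maximum conditioning-set size; with ~10³ subjects and 3-level variables, strata beyond three conditioners rarely keep ≥ `min_avg_cell` samples per cell |
| `min_avg_cell` | 5 | average samples per contingency cell required for a reliable G² test |
| `bins` | 3 | equal-frequency discretization bins for continuous features, the standard coarseness for contingency tests on clinical scales |
| `kernel`, `cost_grid` | linear, {0.01, 0.1, 1, 10} | SVM family and soft-margin costs searched by internal CV |
| `internal_folds` | 5 | folds of the training-partition-only CV used for cost selection and boundary scoring |
| `class_weighting` | balanced | inverse-prevalence class weights; unweighted SVMs can degenerate at ~17% minority prevalence |
| criterion `margin` | 0.01 AUC | allowed shortfall in margin mode |
| criterion `alpha`, `n_permutations` | 0.05, 2000 | paired permutation test of ΔAUC |
| `budget` | 5000 | agenda entries processed before truncation; roughly an order of magnitude above the pool sizes reported for comparable clinical problems |
| `repeats`, `k` | 10, 10 | the standard 100-run repeated stratified design |

**Unreliable-test policy.** A sparse-stratum test is skipped rather than
acted on: insufficient data never removes a candidate. This is the
conservative reading standard in the generalized-local-learning family and
prevents sparse strata from fabricating independence.

**Two readings of equivalence.** "Statistically comparable accuracy" can
mean a tolerance on the AUC itself or a failed significance test of the
AUC difference. Both are implemented and selectable: `auc_margin`
(deterministic, the default, suited to exact unit-level analysis) and
`paired_permutation` (per-subject score swapping, two-sided). Neither is
privileged; the choice is a documented config point.

## The synthetic generator

`generate_dataset()` emulates the *structural* properties of early
clinical risk data — mixed continuous/ordinal/binary features, a
minority-class outcome, several information-equivalent predictor subsets,
irrelevant noise — with a process whose ground truth is known exactly:

- Latent sources are independent uniform 3-level discrete variables. This
  keeps every CI test exact on small tables and makes the Bayes-optimal
  AUC computable by enumeration over the finite source support.
- The outcome is Bernoulli with logit linear in the sources. The intercept
  is calibrated by bisection so the *population* prevalence equals the
  target (default 0.17, the minority rate typical of non-remitting
  post-traumatic courses); the realized rate is checked against the exact
  binomial 99% interval.
- Equivalence is implemented by *invertible transforms* of a shared source
  (copy, monotone relabel, level reversal), not by correlated draws:
  members are mutually deterministic, so the family of true MBs is the
  exact Cartesian product of one-member-per-group choices — certainty, not
  approximation. An optional corruption probability
  (`equivalence_noise`) degrades this cleanly when imperfect equivalence
  is wanted.
- The demo configuration (`demo_generator_config`) uses groups sized
  [2, 3] with log-odds weights 0.95 and 0.85. No effect-size information
  exists for real early-trauma features, so these are free parameters;
  they were fixed once, by closed-form calculation, to put the Bayes AUC
  at ≈ 0.752 — the moderate-accuracy regime (AUC ≈ 0.75) reported for
  early post-traumatic risk prediction, which is the interesting regime
  for equivalence detection: strong enough to find, weak enough that
  margins matter.

What the generator does **not** emulate: the marginal distributions,
inter-feature correlations, missingness patterns, or measurement
instruments of any real cohort. Passing tests therefore demonstrate that
the machinery is correct under exact equivalence and known structure —
they do not certify performance on real clinical tables, where
equivalence is approximate and confounding is real.

## Numerical choices

- **Determinism throughout.** Every stochastic step takes an explicit
  seed and restores the caller's RNG state; derived seeds (per repeat,
  per noise block) are fixed functions of the master seed. All ties —
  candidate ranking, agenda order, cost selection (smaller cost wins) —
  break lexicographically or towards the simpler model. Reruns are
  byte-identical, including written CSV (fixed 15-significant-digit
  formatting).
- **Degenerate tables.** A variable with a single realized level overall
  gives statistic 0, dof 0, p 1, unreliable. A variable deterministic
  *within every stratum* of the conditioning set (e.g. conditioning on an
  exact copy) gives dof 0 with reliability judged by cell counts — this
  is genuine conditional independence and is precisely what lets the
  learner discard duplicated features.
- **AUC.** Midrank computation, O(n log n), equal to the O(n²) pairwise
  count with half credit for ties; invariant under strictly increasing
  score transforms.
- **Fisher-z.** Partial correlation via the inverse correlation matrix
  (direct correlation when the conditioning set is empty); r clipped at
  ±(1 − 10⁻¹²); singular structures return p = 1, unreliable.
- **Margin comparisons** carry a 10⁻¹² slack so exact-arithmetic
  boundary cases are not decided by floating-point rounding.

## Problem sizes used in the test suite and acceptance script

Validation runs are sized to exercise the asymptotics the methods rely on
while staying desk-scale: n = 1000–2000 for induction-versus-exhaustive
comparisons (p ≤ 8, so the 2^p oracle with memoised tests is exact),
n = 2000 for pool-recovery runs, n = 5000 for Bayes-AUC recovery, 500
null replicates for type-I calibration, and 2 × 5 repeated CV in the
acceptance script (the full 10 × 10 schedule is itself constructed and
verified). The SVM cost grid collapses to a single cost in these runs;
cost selection has negligible effect on linear-kernel AUC in this regime
and is exercised separately.

## Known limitations

- No spouse recovery: on data where the outcome has children with other
  parents, the returned set is the parents/children set, a subset of the
  full boundary.
- No permutation-exact or kernel CI tests; contingency G² and Fisher-z
  only.
- Agenda generation grows exclusions by single features of admitted
  boundaries. This is complete for the generator's group structures
  (verified against the Cartesian-product ground truth) but is not a
  completeness proof for arbitrary equivalence structures; the budget
  guards against pathological growth.
- Single deterministic imputation (median/mode); no uncertainty
  propagation for missing data.
- SVM scores are rank-quality only; no probability calibration is
  attempted, as AUC requires none.
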