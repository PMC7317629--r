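---
title: "Methods: a machine-learned multimorbidity frailty index with automatic risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a machine-learned multimorbidity frailty index with automatic risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind it, the choices we made where the
design was genuinely open, and what the synthetic-data experiments can and
cannot show about real claims data.

## 1. The cumulative-deficit model and claims ascertainment

A frailty index under the cumulative-deficit model is a proportion: out of
a fixed catalog of candidate health deficits, the fraction a person has
accumulated. The model's central empirical claim is that the *count* of
deficits, not their identity, carries most of the prognostic signal, which
is why all deficits are weighted equally.

In administrative claims, a diagnosis code on a single encounter is a
noisy indicator of true disease. We therefore ascertain a binary deficit
per condition with the standard claims-validation rule: condition *c* is
present for subject *s* only if, inside the one-year baseline window, *s*
has **at least 3 outpatient claim records or at least 1 inpatient claim
record** whose ICD-9-CM code falls in *c*'s code family. Decisions
embedded in `ascertain_deficits()`:

* **Claim records are deduplicated rows.** We count distinct
  (subject, date, setting, code) rows, so an administrative duplicate of
  the same encounter cannot fabricate a deficit. A consequence users
  should know: three outpatient claims for the same condition *on the same
  day* collapse to one record and do not satisfy the rule.
* **ICD-9 normalization.** Codes are matched after stripping dots, so a
  catalog prefix `250` captures `250`, `250.01`, and the dotless `2500`
  (which is `250.0` in ICD-9's 3-digit-family structure). V and E codes
  match literally by prefix. Families in the shipped example catalog are
  non-nested; users supplying their own catalogs should keep prefixes at
  family boundaries.
* **Subjects without qualifying claims keep an all-zero row** — they are
  the "fit" candidates, not missing data.

## 2. Condition selection by random forest

The set of conditions entering the index is chosen by predictive value
rather than expert opinion. A classification forest (`randomForest`, 500
trees, `sqrt(p)` variables per split, fixed seed) is fit to a binary
outcome, and conditions are ranked by **permutation importance**: the mean
decrease in out-of-bag accuracy when the condition's column is permuted,
unscaled and averaged over trees. Exact ties are broken by condition id so
rankings are reproducible.

The index size *k* is then chosen by refitting the forest on the top-*k*
conditions for every *k* in a grid and selecting the *k* with the highest
out-of-bag accuracy, **smallest k on ties** (a parsimony rule: when two
sizes predict equally well, the shorter index is the better clinical
instrument). The full accuracy-versus-k trace is retained and can be drawn
with `plot_accuracy_trace()`.

Two open questions we had to decide:

* **Which outcome does the forest predict?** Nothing in the procedure
  forces a choice. We default to **death during the full follow-up**
  (mortality is the headline outcome of this literature and the criterion
  used for age-specific re-derivations), with 1-year death available via
  `target_outcome = "death_1y"`.
* **What does "model accuracy" mean?** We use out-of-bag classification
  accuracy: it is the natural forest-internal estimate, requires no
  hold-out split, and makes the accuracy-versus-k search cheap. No class
  reweighting is applied by default; the deficit-count score is meant to
  reflect raw prevalence structure.

The default k-grid is every `1..p` for catalogs up to 25 conditions and a
strided grid (`1..15`, then every 5th) for larger ones — the accuracy
trace is flat near its peak in practice, and the stride keeps the search
at O(20) forest fits.

The ML-mFI score is then exactly `count of selected conditions present / k`,
taking values on `{0, 1/k, ..., 1}`. `compute_reference_fi()` scores the
same deficit matrix under a user-supplied expert catalog (with its own
denominator) so the data-driven and conventional indices can be compared
on identical subjects.

## 3. Risk stratification: distance and coverage indices

Quartile cuts of a frailty score often yield survival curves that cross or
overlap. The package instead searches for cut points whose four groups
(*fit*, *mild*, *moderate*, *severe*; intervals lower-inclusive,
upper-exclusive, so a score equal to a cut point belongs to the upper
group) have Kaplan-Meier curves that are provably separated.

At each month *t* of the evaluation grid, with curves ordered
S₁ ≥ S₂ ≥ S₃ ≥ S₄:

* **Distance index** `D(t) = min(S₁−S₂, S₂−S₃, S₃−S₄)`. The minimum is
  large only when *all three* gaps are wide and balanced, which is what
  "wider and more stable distances" requires of a single scalar. A
  negative value flags an ordering violation.
* **Coverage index** `C(t) = L_error(t) / L_total(t)`, with `L_error` the
  summed 95% CI lengths of the four curves and `L_total = S₁ − S₄`.
  Small C means the within-group estimation error is small relative to
  the spread being claimed. C is undefined (`NA`) when the fit-severe gap
  is non-positive; such candidates are infeasible anyway.

Both formulas are isolated behind `distance_index()` / `coverage_index()`
so alternative definitions can be swapped without touching the search.

The **search** (`search_cutpoints()`) is exhaustive over ordered triples
of candidate thresholds — midpoints between consecutive distinct observed
score values, which enumerate every distinct partition without favoring
boundary conventions. A candidate is **feasible** when

1. every group has at least `max(30, 0.5% of n)` subjects (configurable);
2. all three adjacent gaps are strictly positive at every grid month; and
3. no adjacent pair of 95% Greenwood log-minus-log intervals overlaps at
   any grid month.

Among feasible candidates the objective is **max–min on D** (maximize the
worst-time separation), ties broken by **min–max on C** (minimize the
worst-time relative error), final ties by the lexicographically smallest
triple. This criteria mapping is the only assignment consistent with
"larger is better" for D and "smaller is better" for C. CI non-overlap is
a *hard constraint* rather than a by-product: the stratification's claim
is precisely that the groups are statistically distinct at every
post-first-year time point. When nothing is feasible the result names the
failed constraint and carries the best-scoring infeasible candidate, so a
pipeline run still produces a complete, honestly-flagged report.

The evaluation grid defaults to monthly points from month 12 to month 96:
dose-response is demanded *after the first year* (early follow-up is
dominated by small-sample noise in the severe tail) over an 8-year
horizon. The outcome driving the search is all-cause mortality by
convention.

Feasibility is demanding at small n: a group of ~25 subjects has a
Greenwood 95% half-width near 0.15, so non-overlap of adjacent intervals
effectively requires adjacent gaps above ~0.2. At a few hundred subjects
the search typically (and correctly) reports infeasibility; thousands of
subjects are needed for a fully separated four-group partition, matching
the national-registry scale at which this methodology is deployed.

## 4. Survival evaluation

* **Time unit:** months, converted from exact day counts at 30.4375
  days/month (365.25 / 12).
* **Censoring:** for hospitalization and ICU admission, death censors
  follow-up (`censor_at_death` is forced true exactly for non-fatal
  outcomes). Administrative censoring applies at loss-to-follow-up and at
  each horizon.
* **Horizons:** 1-, 5- and 8-year analyses are separate model fits with
  administrative censoring at 12/60/96 months — not one model with
  interval dropout — mirroring how such tables are reported.
* **KM intervals:** Greenwood variance with the log-minus-log transform,
  keeping bounds inside [0, 1] (required by the coverage index). Where
  the transform is undefined (S = 1 before the first event, or S = 0) the
  bound collapses onto the estimate.
* **Cox models:** Efron tie handling (reduces to Breslow without ties);
  Wald 95% CIs; reference group *fit*. Groups with zero events are
  flagged non-estimable instead of reporting a divergent coefficient. In
  sex-specific strata the sex covariate is constant and is dropped from
  the adjusted model (age-only adjustment), the standard convention for
  sex-stratified analyses.
* **Concordance:** Harrell's C over censoring-comparable pairs, ties
  counting 1/2, computed via `survival::concordance` with the risk-score
  orientation.

## 5. What the synthetic cohort generator emulates

The generator (`sim_config()` / `simulate_cohort()`) produces the minimal
statistical structure the analysis must detect:

* **Latent frailty** `z = N(0,1) + 0.04·(age − 65)`: a continuous
  vulnerability that rises with age.
* **Condition presence** via a logistic model,
  `logit P = logit(0.10) + 0.8·z`: prevalence climbs with frailty, which
  both creates realistic comorbidity clustering and makes *all*
  conditions weak mortality correlates (through z) while only the
  informative subset carries a direct effect — exactly the selection
  problem the forest must solve.
* **Claims given presence:** zero-truncated Poisson outpatient counts
  (mean 4) on distinct days, so the ≥3-outpatient rule passes most but
  not all true cases (~75% plus an independent 15% inpatient chance),
  exercising both branches of the ascertainment rule.
* **Event times** are exponential with rate
  `h₀ · exp(log-HR · #informative present + 0.07·(age−75) + 0.35·male)`
  for death (h₀ = 0.04/person-year), hospitalization (0.15) and ICU
  (0.04). These baselines and covariate effects are in the range reported
  for insured 65+ populations (mortality ~4%/year at 75, roughly doubling
  per decade of age) and yield an 8-year death fraction near one half at
  the default age mix.
* **Age mix** thins exponentially (`exp(−0.07·(age−65))`), approximating
  an insured older population's pyramid rather than a uniform spread.
* **Censoring:** 5% administrative loss uniform over follow-up; death and
  the non-fatal events are *independent* latent times — the generator
  deliberately does not impose censoring-at-death, because the analysis
  layer owns that semantic (and is tested on it).
* Draw order under the single root seed is fixed (ages, sex, frailty,
  informative ids, presence, claims, event times, censoring), so identical
  config + seed reproduces byte-identical tables.

What it does **not** emulate: realistic ICD-9 frequency distributions,
enrollment churn, multi-year re-ascertainment, code-entry error, or
dependence between death and hospitalization beyond the shared linear
predictor. Passing recovery tests on this generator therefore shows the
pipeline detects dose-response structure *when present in the stated
form*; it does not validate the index clinically.

The generator only emits subjects alive through the baseline year (events
start at follow-up); how deaths during the ascertainment year should be
handled in real data is a cohort-definition question the package leaves to
the user.

## 6. Problem sizes and numerical conventions in the test suite

The parameter-recovery experiments run at sizes chosen to make the signal
detectable yet keep a full suite run in minutes on one core: n = 4,000 for
importance recovery (5 informative conditions at hazard ratio 3 among 50),
n = 5,000 for the end-to-end dose-response recovery, n = 300 with ≤ 20
candidate triples for oracle-equivalence of the cut-point search, 200
replicates of n = 500 for null calibration of the adjusted hazard ratio,
and n = 600 for byte-identity of rerun artifacts. Deterministic primitives
are compared to brute-force oracles exactly or at 10⁻¹² (KM), 10⁻⁸
(log-rank) and 10⁻³ (Cox versus a grid-searched partial likelihood at
10⁻⁴ resolution).

## 7. Known limitations

* Four groups are hard-wired; a generalized g-group search is future work.
* The exhaustive search is O(#triples) KM fits; for scores with very many
  distinct values (large k and n) a user-supplied candidate grid bounds
  the cost.
* Permutation importance is biased toward correlated feature clusters;
  no debiasing is applied, matching standard practice in this literature.
* The proportional-hazards assumption is taken as given (as in the
  reporting convention this package mirrors); no diagnostics are run.
* The claims reader targets the documented CSV dialect only; other
  encodings should be converted upstream.
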