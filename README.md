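# mlfrailty

A data-driven **multimorbidity frailty index** (ML-mFI) for administrative
claims data, with automatic four-group risk stratification and full
survival evaluation.

## The problem

Under the cumulative-deficit model of aging, a frailty index is the
fraction of health deficits an older person has accumulated out of a fixed
set of candidate deficits. Claims-based indices traditionally pick that
set by expert opinion and cut the resulting score into quartiles — which
can miss informative conditions and produce risk groups whose survival
curves overlap. `mlfrailty` implements a fully data-driven alternative for
researchers working with outpatient/inpatient claims:

1. **Deficit ascertainment.** A diagnosis counts as a deficit only when
   the subject has ≥ 3 outpatient claim records or ≥ 1 inpatient claim
   record for that ICD-9-CM condition family inside a one-year baseline
   window (the standard claims-validation rule).
2. **Condition selection.** A random-forest classifier of a survival
   outcome (death during follow-up by default) ranks conditions by
   permutation importance — the mean decrease in out-of-bag accuracy —
   and the index size *k* is chosen where out-of-bag accuracy peaks over
   a grid of top-*k* refits.
3. **Scoring.** For each subject, ML-mFI = (number of selected conditions
   present) / *k*, so scores lie on {0, 1/k, …, 1}.
4. **Risk stratification.** An exhaustive cut-point search partitions the
   score into *fit*, *mild*, *moderate* and *severe* frailty using two
   per-time-point indices over the four Kaplan-Meier curves
   S_fit(t) ≥ S_mild(t) ≥ S_mod(t) ≥ S_sev(t):

   - **distance index** D(t) = min adjacent gap
     `min{S_fit − S_mild, S_mild − S_mod, S_mod − S_sev}` — larger means
     wider, more balanced separation (**max–min** criterion: maximize the
     worst-time D);
   - **coverage index** C(t) = L_error / L_total, where L_error is the
     summed 95% CI length of the four curves and
     L_total = S_fit − S_sev — smaller means less estimation error
     relative to the total spread (**min–max** criterion: used to break
     ties by minimizing the worst-time C).

   Candidates must keep all four curves strictly dose-ordered with
   non-overlapping 95% confidence intervals at every monthly grid point
   after the first follow-up year.
5. **Evaluation.** Kaplan-Meier curves with Greenwood variance and
   log-minus-log CIs, log-rank tests, Cox proportional-hazards ratios
   (Efron ties; unadjusted and age/sex-adjusted) at 1-, 5- and 8-year
   horizons with censoring at death for non-fatal outcomes, and Harrell's
   C-index.

Because real claims databases of this kind are access-restricted, the
package ships a **synthetic cohort generator**: a latent frailty
(standard normal plus an age trend) raises condition prevalence on the
log-odds scale, and a configurable subset of "informative" conditions
multiplies the death / hospitalization / ICU hazards log-linearly. The
ground truth it emits (latent frailty, informative set) powers
parameter-recovery tests of the whole pipeline.

## Worked example

```r
library(mlfrailty)

cfg <- pipeline_config(
  simulation = sim_config(n_subjects = 2000, seed = 1, n_conditions = 30,
                          n_informative = 5, informative_log_hr = log(3)),
  output_dir = "demo_run", strat_grid_times = 12:96, seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
mlfrailty run report: 2000 subjects
Frailty-index model: k = 20 conditions selected of 30 (OOB accuracy 0.7185 )
Forest: 500 trees, outcome = death_followup
Frailty cut points: fit [0, 0.125) | mild [0.125, 0.225) | moderate [0.225, 0.475) | severe [0.475, 1]
Feasible | min distance index 0.1375 | max coverage index 0.5697
Group sizes: fit=1117, mild=477, moderate=375, severe=31
C-index (ML-mFI): all_cause_mortality = 0.684, unplanned_hospitalization = 0.66, icu_admission = 0.662
```

Reading the output: the forest kept 20 of 30 candidate conditions (the 5
truly informative ones are all among them); the cut-point search found a
feasible partition whose four mortality curves stay strictly dose-ordered
with non-overlapping 95% CIs at every month from 12 to 96, with a
worst-time adjacent gap of 0.138; and the continuous score discriminates
8-year mortality with C = 0.68. The age/sex-adjusted 8-year mortality
hazard ratios in `report$hr_table` rise monotonically (mild 1.92,
moderate 3.27, severe 13.8 versus fit), the dose-response pattern the
stratification is designed to guarantee.

Per-stage artifacts (deficit matrix, model JSON, scores, groups, HR
table, Table-1-style descriptives by age band × sex, manifest) are left
in `output_dir`; `run_stratified()` reruns everything inside sex or age
strata, and `plot_accuracy_trace()` / `plot_curveset()` draw the
accuracy-versus-k curve and the four-group KM plot.

An example ICD-9-CM condition catalog ships in
`inst/extdata/example_catalog.csv` for use with external claims files via
`read_claims()` / `read_registry()` / `read_catalog()`.

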