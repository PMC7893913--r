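# mbcoud

Measurement-based care (MBC) decision support for office-based
buprenorphine treatment of opioid use disorder (OUD), for primary-care
informatics teams and researchers who need the algorithm as auditable,
testable code rather than prose: a deterministic rules engine over
standardized patient-reported measures, plus a seeded synthetic patient
simulator so every pathway can be exercised without patient data.

## What it implements

**Instruments.** The TAPS screening gate (any score > 0 on the heroin or
prescription-opioid item flags the patient for further OUD assessment); an
11-item yes/no symptom checklist derived from the DSM-5 OUD criteria (total
0–11, one point per yes) with a companion past-2-week opioid-use item; and
a two-item adherence questionnaire (adherent = missing ≤ 1 day in the past
week with no over-taking; eleven reason codes, with craving/withdrawal
triggering a consider-dose-increase hint).

**Response classifier.** Change from the immutable week-0 baseline total,
`d = (baseline − current) / baseline`, combined with the dichotomous use
flag:

- **full**: `d > 75%` and no use in the past 2 weeks
- **partial**: `25% ≤ d ≤ 75%` and no use, or `d > 75%` with use
- **minimal/nonresponse**: `d < 25%` (including worsening), or
  `25% ≤ d ≤ 75%` with use

Boundaries are decided with exact integer arithmetic; 25% and 75% land in
the partial band, and full response is never concurrent with reported use.

**Decision engine.** Seven critical decision points (weeks 0–12 every
2 weeks; off-schedule visits map to the floor CDP) driving a rules table
shipped as machine-readable YAML. The engine enforces: non-adherence is
addressed before any other change; dose increases are capped at 24 mg/day
(the increase branch is withdrawn at the ceiling); a BID split never changes
the total daily dose; 4 weeks of sustained full response transitions to a
4-weekly continuation phase; minimal response at weeks 10–12 mandates
specialty referral, with trial-cap alerts for minimal responders beyond
week 8 and partial responders beyond week 12. Options are emitted in printed
order as clinician "OR" choices — the engine recommends, it never
auto-applies.

**Simulator.** `generate_cohort()` draws seeded trajectories from three
latent response classes whose checklist totals are sampled exactly inside
the classifier's bands, with per-class adherence lapses and dropout;
`example_trajectory()` is the scripted worked scenario (partial → partial →
full with a week-2 dose increase to 12 mg).

## Worked example

```r
library(mbcoud)

ep <- replay_episode(example_trajectory())
tidy(ep)[, c("week", "category", "dose_mg", "options", "next_visit_weeks")]
#> # A tibble: 3 × 5
#>    week category dose_mg options                                                  next_visit_weeks
#>   <dbl> <chr>      <dbl> <chr>                                                               <dbl>
#> 1     2 partial        8 continue_dose | increase_dose->12mg                                     2
#> 2     4 partial       12 increase_dose->16mg+add_counseling | continue_dose+add_…               2
#> 3     6 full          12 continue_dose                                                           2
```

At week 2 the patient's checklist total has dropped more than 75% but heroin
use continues, so the response is *partial* and the engine offers continuing
or increasing the dose (the record shows the clinician chose 12 mg). At
week 6 the patient reports no use and achieves *full* response; two more
full-response visits would complete the 4-week streak and offer the
continuation phase. A single step looks like:

```r
st  <- new_episode(baseline_total = 8, dose_mg = 8)
out <- evaluate_visit(st, week = 2, total = 4, use_2wk = FALSE)
out$recommendation
#> <Recommendation> week 2 (CDP #2) | partial | adherent
#>   option: continue_dose
#>   option: increase_dose (to 12 mg)
#>   next visit in 2 weeks
```

`autoplot(ep)` plots the trajectory (totals, categories, dose);
`plot_response_bands(8)` visualises the classification bands;
`decision_rules()` returns the full rules grid as a tibble;
`export_visits_csv()` flattens replayed cohorts for spreadsheets.

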