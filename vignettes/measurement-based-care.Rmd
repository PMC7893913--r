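---
title: "Measurement-based care for buprenorphine treatment: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-based care for buprenorphine treatment: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcoud)
```

## The clinical problem

Office-based treatment of opioid use disorder (OUD) with buprenorphine is
constrained less by the medication than by primary-care capacity to apply it
systematically. Measurement-based care (MBC) addresses this by driving
treatment decisions from repeated standardized measures: a screening
instrument, a symptom-tracking instrument, a medication-adherence
questionnaire, and a rules table that converts scores plus time-in-treatment
into concrete recommendations. `mbcoud` implements that rules engine
deterministically: the same state and the same visit always yield the same
recommendation, and every recommendation cites the rule that fired (e.g.
`CDP5/minimal/branch1`).

The engine is decision *support*, not an autopilot: each rules-table row is
emitted as an ordered set of option branches — clinician "OR" choices, in
printed order — and the dose actually applied between visits is always read
from the patient record, never assumed.

## The instruments

**Screening gate.** Universal screening uses the TAPS tool's per-substance
risk scores. The engine does not rescore TAPS internals (those are published
elsewhere and consumed as given); it applies only the gate: any score above 0
on the heroin item or the prescription-opioid item flags the patient for
further OUD assessment. Other substances never affect the gate.

**Symptom checklist.** An 11-item yes/no checklist derived from the DSM-5
OUD criteria; each yes scores one point, totals run 0–11. A companion item
asks about use of any opioid *other than buprenorphine* in the past 2 weeks;
it is never counted in the total but enters the response classification as a
dichotomous flag. Incomplete administrations are rejected rather than
imputed: the total drives treatment decisions, and silent imputation of a
clinical instrument is unsafe. Whether the item probing felt opioid effects
should be reverse-scored under buprenorphine (which blocks those effects) is
an open measurement question; no reverse-scoring is applied here.

**Adherence questionnaire.** Two items: days in the past week the medication
was not taken (plus an over-taking flag), and the reasons for non-adherence.
Taking medication at least 80% of the time — missing no more than 1 day in
the past week — with no over-taking is *adherent*. Over-taking takes
precedence over under-taking when both are reported, so the more
safety-relevant status surfaces; both facts stay on the record. The reason
item enumerates eleven options; the instrument's item wordings are not
redistributed here, so this package uses eleven stable machine identifiers
(`adherence_reason_codes()`) — the count is normative, the wording is not. When non-adherence is attributed to craving or withdrawal,
the engine adds a consider-dose-increase alert.

## The response classifier

Treatment response is categorized as *change from baseline* rather than
current severity, matching harm-reduction goals of OUD care. With `d` the
decrease of the checklist total from the immutable week-0 baseline and `use`
the past-2-week use flag:

| category            | rule                                              |
|---------------------|---------------------------------------------------|
| full                | `d > 75%` AND no use                              |
| partial             | `25% ≤ d ≤ 75%` and no use, OR `d > 75%` with use |
| minimal/nonresponse | `d < 25%`, OR `25% ≤ d ≤ 75%` with use            |

Design choices that the printed rule leaves implicit:

* **Boundaries.** The bands are printed as `< 25%`, `25–75%`, `> 75%`: the
  strict inequalities bracket the middle band on both sides, so exactly 25%
  and exactly 75% are *partial*. `classify_response(4, 1, FALSE)` (a 75%
  decrease) is partial, not full.
* **Exact arithmetic.** Band membership is decided by integer comparisons
  (`4·(baseline − current)` against `baseline` and `3·baseline`), never on
  rounded percentages, so checklist totals can never straddle a boundary
  through floating-point error.
* **Worsening.** A negative decrease falls under `< 25%` and is
  minimal/nonresponse; no separate "worsened" category is invented.
* **Degenerate baseline.** A baseline total of 0 is rejected: such a patient
  is not symptomatic and change-from-baseline is undefined. Re-baselining
  after relapse is not supported.
* A full response is **never** returned concurrently with reported use.

## The decision-point state machine

Assessments are scheduled every 2 weeks from initiation: seven critical
decision points (CDPs) at weeks 0, 2, …, 12. Off-schedule visits map to the
*floor* CDP (the latest scheduled week at or before the elapsed time),
because escalation rules key on treatment time already completed; beyond
week 12 the week-12 rules persist. A follow-up before week 2 maps to the
initiation CDP, where no follow-up rules exist, and is rejected rather than
guessed at.

The rules table ships as a machine-readable YAML asset
(`inst/extdata/decision_rules.yaml`), which is what the engine executes;
`decision_rules()` renders it as a tibble. Around the table the engine
enforces:

* **Adherence precedence.** Any non-adherent visit yields a single option —
  explore and address the non-adherence — before any dose or frequency
  change, whatever the category or week. This also suppresses mandatory
  referral at that visit (adherence is addressed first); trial-cap alerts
  still attach as information. The response is still classified and the
  full-response streak still updated.
* **Dose ceiling.** Dose-increase payloads are capped at 24 mg/day total
  buprenorphine, and the increase branch is withdrawn once the current dose
  is at (or above) the cap, remaining branches keeping printed order. Where
  that empties a row — week 2, minimal response, whose only branch is a dose
  increase — the engine falls back to a continue-dose option, because
  decision support must always offer something actionable.
* **BID split.** "Divide daily dose in half, take medication BID" never
  changes the total daily dose; applied to an already twice-daily
  prescription it is a no-op, emitted with a note.
* **Continuation.** A full response sustained for at least 4 weeks (streak
  measured across the current uninterrupted run of full-response visits)
  yields the single option of entering the continuation phase; the cadence
  then drops to every 4 weeks. Losing full response during continuation is
  not covered by the published table: the engine raises a relapse alert,
  emits no options, and returns the episode to clinician judgment.
* **Trial caps and referral.** The table makes referral optional for
  minimal/non-responders at weeks 6–8 and mandatory at weeks 10–12, while a
  footnote advises that such trials "should not exceed 8 weeks". These are
  reconciled as: mandatory referral exactly where the table prints it
  (CDP #6–#7 minimal rows), plus a trial-cap *alert* whenever a
  minimal/non-responder is seen beyond week 8 (and, per the partial-response
  footnote, whenever a partial responder is seen beyond week 12). After
  referral the engine only reiterates continuing the current dose until the
  specialist evaluation.

Week-10/12 partial rows list dose increase, counseling and referral as three
separate OR branches where earlier weeks bundle counseling with the dose
action; they are emitted exactly as printed, not merged.

```{r}
ep <- replay_episode(example_trajectory())
tidy(ep)[, c("week", "category", "dose_mg", "options", "next_visit_weeks")]
```

## The synthetic cohort generator

No patient dataset exists for this algorithm (it is a published design, not
a trial), so the package generates seeded trajectories with the structure
the engine assumes. Each simulated patient draws a latent class —
full responder, partial responder, non-responder — and checklist totals are
sampled uniformly among the *integer totals whose exact change-from-baseline
fraction lies in the class's band*, with item-level responses sampled by
choosing which baseline-endorsed criteria remit (only totals and the use
flag are normative for the engine). Defaults, chosen once as clinically
plausible for an office-based cohort and stated here for transparency:

* baseline totals uniform on 6–11 (moderate-to-severe entrants);
* full responders cross the >75%/no-use threshold at week 6, sitting in the
  partial band without use before that; partial responders hold the 25–75%
  band without use; non-responders stay below a 25% decrease with ongoing
  use;
* uniform class probabilities (1/3 each);
* per-day dose-miss probabilities 0.02 / 0.05 / 0.10 for
  full / partial / non-responders, over-taking probability 0.02 per visit,
  dropout hazard 0.05 per visit (producing truncated, off-schedule
  trajectories that exercise gap handling);
* initiation at 8 mg/day (lower end of the therapeutic range) with 4 mg
  increase steps — the algorithm itself fixes only the 24 mg ceiling.

The simulated clinician takes the first-listed option branch (the table's
emphasis order), overridable through a choice-policy hook.

What the generator does **not** emulate: item-level symptom correlations,
quantity/frequency of use (the engine only sees the dichotomous flag),
re-escalation after improvement, measurement error in self-report, or
continuation-phase relapse. Passing tests therefore show that the engine
implements its rules exactly on data shaped like its assumptions — they are
not evidence about real-world measurement properties, which the instruments'
authors themselves list as unvalidated.

Because band sampling is exact, a lapse-free cohort's latent classes are
recovered by the classifier at week 12 essentially perfectly; the test suite
checks ≥ 99% recovery on 500 simulated patients, and exercises the engine's
full grid (7 CDPs × 3 categories × adherence states × starting doses
2–32 mg) against an independently hand-transcribed copy of the rules table.
These sizes run in seconds and are exhaustive for the discrete state space
involved; nothing is sampled where enumeration is possible (all 2^11
checklist vectors, all 264 classifier cases).

## File formats

Trajectories are canonical JSON (fixed key order, no rounding — round trips
are byte-stable), validated on read against the shipped schema with errors
naming the failing field and record index. All time is weeks since
initiation; calendar mapping is the caller's concern. CSV export is a lossy
flattening (option branches become `action+action | action` strings) meant
for spreadsheets, one row per follow-up visit. Engine constants can be
overridden from a YAML config with each override logged for provenance.

## Known limitations

The package implements treatment *tracking* from stabilization onward:
induction protocols, urine drug screening, comorbidity screening and any
outcome prediction are out of scope. Continuation-phase duration, taper
criteria and relapse pathways are not defined by the underlying algorithm
and are deliberately not invented here. The response categories themselves
are consensus-based cut-points; this package makes them exact and auditable
but cannot make them validated.
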