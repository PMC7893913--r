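# Clinical decision support rules for office-based buprenorphine treatment.
# One block per critical decision point (CDP), weeks 0-12 at a 2-week cadence.
# Each response category row lists its option branches in printed order; a
# branch is a bundle of actions offered together, alternative branches are
# clinician "OR" choices. The engine, not this table, applies the 24 mg dose
# cap, adherence precedence, streak accounting and footnote alerts.
schema_version: "1.0"
dose_cap_mg: 24
cadence:
  acute_weeks: 2
  continuation_weeks: 4
cdps:
- cdp: 1
  week: 0
  rows:
    symptomatic:
      branches:
      - actions: [initiate_treatment]
- cdp: 2
  week: 2
  rows:
    full:
      branches:
      - actions: [continue_dose]
    partial:
      branches:
      - actions: [continue_dose]
      - actions: [increase_dose]
    minimal:
      branches:
      - actions: [increase_dose]
- cdp: 3
  week: 4
  rows:
    full:
      branches:
      - actions: [enter_continuation]
        requires: sustained_full_4wk
      - actions: [continue_dose]
        requires: otherwise
    partial:
      branches:
      - actions: [increase_dose, add_counseling]
      - actions: [continue_dose, add_counseling]
    minimal:
      branches:
      - actions: [increase_dose, add_counseling]
      - actions: [continue_dose, add_counseling]
- cdp: 4
  week: 6
  rows:
    full:
      branches:
      - actions: [enter_continuation]
        requires: sustained_full_4wk
      - actions: [continue_dose]
        requires: otherwise
    partial:
      branches:
      - actions: [increase_dose, add_counseling]
      - actions: [split_dose_bid, add_counseling]
    minimal:
      branches:
      - actions: [increase_dose, add_counseling]
      - actions: [split_dose_bid, add_counseling]
      - actions: [refer_specialty, continue_dose]
- cdp: 5
  week: 8
  rows:
    full:
      branches:
      - actions: [enter_continuation]
        requires: sustained_full_4wk
      - actions: [continue_dose]
        requires: otherwise
    partial:
      branches:
      - actions: [increase_dose, add_counseling]
      - actions: [split_dose_bid, add_counseling]
    minimal:
      branches:
      - actions: [split_dose_bid, add_counseling]
      - actions: [refer_specialty, continue_dose]
- cdp: 6
  week: 10
  rows:
    full:
      branches:
      - actions: [enter_continuation]
        requires: sustained_full_4wk
      - actions: [continue_dose]
        requires: otherwise
    partial:
      branches:
      - actions: [increase_dose]
      - actions: [add_counseling]
      - actions: [refer_specialty, continue_dose]
    minimal:
      referral_mandatory: true
      branches:
      - actions: [refer_specialty, continue_dose]
- cdp: 7
  week: 12
  rows:
    full:
      branches:
      - actions: [enter_continuation]
        requires: sustained_full_4wk
      - actions: [continue_dose]
        requires: otherwise
    partial:
      branches:
      - actions: [increase_dose]
      - actions: [add_counseling]
      - actions: [refer_specialty, continue_dose]
    minimal:
      referral_mandatory: true
      branches:
      - actions: [refer_specialty, continue_dose]
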