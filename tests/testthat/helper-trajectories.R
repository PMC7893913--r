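# programmatic trajectory fixtures: totals are realised as items 1..total
# endorsed, which is all the engine reads
items_n <- function(n) c(rep(1L, n), rep(0L, 11 - n))

make_visit <- function(week, total, use, days_missed = 0L, over = FALSE,
                       reasons = character(), dose = 8, freq = "once_daily") {
  list(week = week, items = items_n(total), use_2wk = use,
       days_missed = as.integer(days_missed), over_taking = over,
       reasons = reasons, dose_mg = dose, frequency = freq)
}

make_traj <- function(baseline_total = 8, visits = list(), dose = 8,
                      patient_id = "T-001") {
  list(schema_version = "1.0", patient_id = patient_id,
       baseline = list(week = 0, items = items_n(baseline_total),
                       use_2wk = TRUE, dose_mg = dose,
                       frequency = "once_daily"),
       visits = visits)
}

# a patient who never improves: identical checklist, ongoing use, biweekly
flat_nonresponder <- function(weeks = seq(2, 12, by = 2), baseline_total = 8) {
  make_traj(baseline_total,
            visits = lapply(weeks, function(w) {
              make_visit(w, total = baseline_total, use = TRUE)
            }))
}
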