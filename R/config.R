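#' Engine configuration
#'
#' Bundles the tunable constants of the decision engine. Defaults encode the
#' published algorithm: a 24 mg/day buprenorphine ceiling, biweekly acute-phase
#' reassessment, 4-weekly continuation-phase reassessment, response-band
#' boundaries at 25% and 75% decrease from baseline, and a 4-week sustained
#' full response required to enter the continuation phase. The dose increment
#' and initiation dose are not fixed by the algorithm (which only caps the
#' total daily dose); the defaults of 4 mg and 8 mg are used by the simulator
#' and by dose-increase payload suggestions.
#'
#' @param dose_cap_mg Maximum total daily buprenorphine dose ever recommended
#'   (mg/day).
#' @param dose_increment_mg Step suggested by a dose-increase option (mg/day).
#' @param initiation_dose_mg Starting dose at treatment initiation, lower end
#'   of the therapeutic range (mg/day).
#' @param acute_interval_weeks Reassessment cadence during the acute phase.
#' @param continuation_interval_weeks Reassessment cadence after entering the
#'   continuation phase.
#' @param partial_band Lower and upper bounds (fractions of baseline) of the
#'   partial-response decrease band; both bounds belong to the band.
#' @param continuation_streak_weeks Weeks of sustained full response required
#'   before the continuation phase is offered.
#' @param minimal_trial_cap_weeks Treatment duration beyond which a minimal
#'   responder triggers a trial-length alert.
#' @param partial_trial_cap_weeks Treatment duration beyond which a partial
#'   responder triggers a consider-referral alert.
#'
#' @return A list with class `"mbc_config"`.
#' @export
#' @examples
#' cfg <- engine_config(dose_increment_mg = 2)
#' cfg$dose_cap_mg
engine_config <- function(dose_cap_mg = 24,
                          dose_increment_mg = 4,
                          initiation_dose_mg = 8,
                          acute_interval_weeks = 2,
                          continuation_interval_weeks = 4,
                          partial_band = c(0.25, 0.75),
                          continuation_streak_weeks = 4,
                          minimal_trial_cap_weeks = 8,
                          partial_trial_cap_weeks = 12) {
  stopifnot(dose_cap_mg > 0, dose_increment_mg > 0, initiation_dose_mg > 0,
            length(partial_band) == 2, partial_band[1] < partial_band[2])
  structure(
    list(dose_cap_mg = dose_cap_mg,
         dose_increment_mg = dose_increment_mg,
         initiation_dose_mg = initiation_dose_mg,
         acute_interval_weeks = acute_interval_weeks,
         continuation_interval_weeks = continuation_interval_weeks,
         partial_band = partial_band,
         continuation_streak_weeks = continuation_streak_weeks,
         minimal_trial_cap_weeks = minimal_trial_cap_weeks,
         partial_trial_cap_weeks = partial_trial_cap_weeks),
    class = "mbc_config"
  )
}

#' Read engine configuration overrides from a YAML file
#'
#' Reads a YAML mapping whose keys are [engine_config()] argument names and
#' returns the merged configuration. Unknown keys are an error so that typos
#' in a config file cannot silently fall back to defaults; every override is
#' reported with a message for provenance.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress the per-override provenance messages.
#' @return A list with class `"mbc_config"`.
#' @export
read_engine_config <- function(path, quiet = FALSE) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(engine_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown engine_config keys in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  if (!quiet && length(raw) > 0) {
    for (k in names(raw)) {
      message("config override from ", basename(path), ": ", k, " = ",
              paste(raw[[k]], collapse = ", "))
    }
  }
  do.call(engine_config, raw)
}
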