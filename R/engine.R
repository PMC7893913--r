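#' Map elapsed treatment time to a critical decision point
#'
#' Assessments are scheduled at weeks 0, 2, 4, 6, 8, 10, 12 (CDP #1-#7).
#' Clinicians may see patients off schedule; guidance keys on the treatment
#' time already completed, so an off-schedule visit maps to the latest
#' scheduled CDP week at or before the elapsed time. Beyond week 12 the
#' week-12 rules persist (index 7).
#'
#' @param weeks_since_init Non-negative weeks since buprenorphine initiation.
#' @return Integer CDP index 1-7 (vectorised).
#' @export
#' @examples
#' map_week_to_cdp(c(0, 2, 5, 12, 13))   # 1 2 3 7 7
map_week_to_cdp <- function(weeks_since_init) {
  if (any(is.na(weeks_since_init)) || any(weeks_since_init < 0)) {
    abort("weeks_since_init must be non-negative")
  }
  pmin(findInterval(weeks_since_init, seq(0, 12, by = 2)), 7L)
}

#' Cap a proposed buprenorphine dose at the recommended maximum
#'
#' Total daily buprenorphine in any engine recommendation never exceeds
#' 24 mg (no demonstrated benefit above that dose).
#'
#' @param proposed_mg Positive proposed total daily dose(s), mg.
#' @param cap_mg The ceiling; 24 mg by default.
#' @return `pmin(proposed_mg, cap_mg)`, vectorised.
#' @export
#' @examples
#' apply_dose_cap(c(16, 24, 28))   # 16 24 24
apply_dose_cap <- function(proposed_mg, cap_mg = 24) {
  if (any(is.na(proposed_mg)) || any(proposed_mg <= 0)) {
    abort("proposed dose must be positive")
  }
  pmin(proposed_mg, cap_mg)
}

#' Start a treatment episode
#'
#' Creates the longitudinal state threaded through [evaluate_visit()]:
#' the immutable week-0 baseline checklist total, the current prescription,
#' the phase (acute until continuation or referral), and the full-response
#' streak bookkeeping. Entry requires a symptomatic baseline (total >= 1);
#' the OUD diagnosis itself is the clinician's, not the engine's.
#'
#' @param baseline_total Week-0 symptom-checklist total, integer 1-11.
#' @param dose_mg Total daily buprenorphine dose at initiation, mg.
#' @param frequency `"once_daily"` or `"twice_daily"`.
#' @param config An [engine_config()].
#' @return A list with class `"mbc_state"`.
#' @export
#' @examples
#' st <- new_episode(baseline_total = 8)
#' st$phase
new_episode <- function(baseline_total,
                        dose_mg = config$initiation_dose_mg,
                        frequency = c("once_daily", "twice_daily"),
                        config = engine_config()) {
  frequency <- match.arg(frequency)
  if (is.na(baseline_total) || baseline_total < 1 || baseline_total > 11) {
    abort(paste0("Baseline checklist total must be 1-11 (a score of 0 is ",
                 "not symptomatic; >11 is impossible on an 11-item checklist)"))
  }
  if (dose_mg <= 0) abort("Initiation dose must be positive")
  structure(
    list(baseline_total = as.integer(baseline_total),
         weeks_since_init = 0,
         phase = "acute",
         dose_mg = dose_mg,
         frequency = frequency,
         full_since_week = NA_real_,
         full_response_streak_weeks = 0,
         last_cdp_index = 1L),
    class = "mbc_state"
  )
}

action_payload <- function(kind, state, config) {
  switch(kind,
    increase_dose = list(kind = kind,
                         target_dose_mg = apply_dose_cap(
                           state$dose_mg + config$dose_increment_mg,
                           config$dose_cap_mg)),
    split_dose_bid = {
      a <- list(kind = kind,
                total_daily_dose_mg = state$dose_mg,
                per_dose_mg = state$dose_mg / 2)
      if (state$frequency == "twice_daily") a$note <- "already_twice_daily"
      a
    },
    list(kind = kind)
  )
}

category_key <- function(category) {
  c(minimal_nonresponse = "minimal", partial = "partial", full = "full")[[
    as.character(category)]]
}

new_recommendation <- function(fields) {
  structure(fields, class = "mbc_recommendation")
}

log_decision <- function(rule_id, week) {
  if (isTRUE(getOption("mbcoud.verbose", FALSE))) {
    message(sprintf("[mbcoud] week %s: fired %s", format(week), rule_id))
  }
}

#' Evaluate one follow-up visit against the decision rules
#'
#' One step of the acute-phase state machine. The visit's checklist total and
#' past-2-week use flag are classified against the episode baseline, the
#' full-response streak is updated, and the rules-table row for (CDP,
#' category) is emitted as an ordered set of option branches -- clinician
#' "OR" choices, never auto-selected. Overrides and side rules:
#'
#' * **Adherence precedence**: on any non-adherent visit the only option is
#'   to explore and address the non-adherence before making other changes;
#'   a consider-dose-increase alert is added when the non-adherence is
#'   attributed to craving or withdrawal. The response is still classified
#'   and the streak still updated.
#' * **Continuation transition**: a full response sustained for at least
#'   4 weeks yields the single option of entering the continuation phase,
#'   with the next visit in 4 weeks.
#' * **Dose ceiling**: dose-increase payloads are capped at 24 mg/day and
#'   the increase branch is dropped entirely once the current dose is at the
#'   cap (remaining branches keep their printed order; if nothing remains, a
#'   continue-dose fallback is offered).
#' * **Trial caps**: a minimal/non-responder seen beyond week 8, or a
#'   partial responder beyond week 12, raises a trial-length alert.
#' * **Mandatory referral**: minimal/nonresponse at CDP #6 or #7 (weeks
#'   10-12) mandates referral to specialty care, continuing the current dose
#'   until the specialist evaluation; the episode leaves the acute phase.
#'
#' @param state An `mbc_state` in the acute phase.
#' @param week Weeks since initiation at this visit (> previous visit).
#' @param total Checklist total at this visit (0-11).
#' @param use_2wk Logical: opioid use (other than buprenorphine), past 2 weeks.
#' @param adherence_status `"adherent"`, `"nonadherent_under"` or
#'   `"nonadherent_over"` (see [classify_adherence()]).
#' @param dose_increase_hint Logical: craving/withdrawal endorsed among
#'   non-adherence reasons.
#' @param config An [engine_config()].
#' @return A list with elements `recommendation` (class
#'   `"mbc_recommendation"`: week, cdp_index, category, percent_decrease,
#'   adherence_status, options, alerts, referral_mandatory,
#'   next_visit_weeks) and `state` (the updated `mbc_state`).
#' @export
#' @examples
#' st <- new_episode(baseline_total = 8)
#' out <- evaluate_visit(st, week = 2, total = 4, use_2wk = FALSE)
#' out$recommendation$options
evaluate_visit <- function(state, week, total, use_2wk,
                           adherence_status = "adherent",
                           dose_increase_hint = FALSE,
                           config = engine_config()) {
  stopifnot(inherits(state, "mbc_state"))
  if (state$phase != "acute") {
    abort(paste0("evaluate_visit applies to the acute phase; episode is in ",
                 "phase '", state$phase, "'"))
  }
  if (week < state$weeks_since_init) {
    abort("Visit weeks must be non-decreasing within an episode")
  }
  adherence_status <- as.character(adherence_status)
  if (!adherence_status %in% adherence_levels()) {
    abort(paste0("Unknown adherence status '", adherence_status, "'"))
  }
  cdp <- map_week_to_cdp(week)
  if (cdp == 1L) {
    abort(paste0("A follow-up visit before week 2 maps to the initiation ",
                 "decision point; no follow-up rules exist there"))
  }
  category <- classify_response(state$baseline_total, total, use_2wk)
  pdec <- percent_decrease(state$baseline_total, total)

  # full-response streak over the current uninterrupted run of visits
  if (category == "full") {
    full_since <- if (is.na(state$full_since_week)) week else state$full_since_week
    streak <- week - full_since
  } else {
    full_since <- NA_real_
    streak <- 0
  }

  adherent <- adherence_status == "adherent"
  alerts <- character()
  if (!adherent) {
    alerts <- c(alerts, "nonadherence")
    if (isTRUE(dose_increase_hint)) {
      alerts <- c(alerts, "consider_dose_increase_for_craving_withdrawal")
    }
  }
  if (category == "minimal_nonresponse" && week > config$minimal_trial_cap_weeks) {
    alerts <- c(alerts, "minimal_response_trial_cap")
  }
  if (category == "partial" && week > config$partial_trial_cap_weeks) {
    alerts <- c(alerts, "partial_response_trial_cap")
  }

  phase <- state$phase
  referral_mandatory <- FALSE

  if (!adherent) {
    rule_id <- paste0("CDP", cdp, "/nonadherent")
    options <- list(list(id = rule_id,
                         actions = list(list(kind = "address_nonadherence"))))
  } else if (category == "full" && streak >= config$continuation_streak_weeks) {
    rule_id <- paste0("CDP", cdp, "/full/continuation")
    options <- list(list(id = rule_id,
                         actions = list(list(kind = "enter_continuation"))))
    phase <- "continuation"
  } else if (category == "full") {
    rule_id <- paste0("CDP", cdp, "/full/branch1")
    options <- list(list(id = rule_id,
                         actions = list(list(kind = "continue_dose"))))
  } else {
    key <- category_key(category)
    row <- rules_for(cdp, key)
    referral_mandatory <- isTRUE(row$referral_mandatory)
    keep <- purrr::imap(row$branches, function(br, i) {
      kinds <- unlist(br$actions)
      if ("increase_dose" %in% kinds && state$dose_mg >= config$dose_cap_mg) {
        return(NULL)   # at the ceiling: the increase branch is withdrawn
      }
      list(id = paste0("CDP", cdp, "/", key, "/branch", i),
           actions = lapply(kinds, action_payload, state = state,
                            config = config))
    })
    options <- purrr::compact(keep)
    if (length(options) == 0 && !referral_mandatory) {
      options <- list(list(
        id = paste0("CDP", cdp, "/", key, "/cap_fallback"),
        actions = list(list(kind = "continue_dose"))))
    }
    rule_id <- paste0("CDP", cdp, "/", key)
    if (referral_mandatory) phase <- "referred"
  }
  log_decision(rule_id, week)

  next_visit <- if (phase == "continuation") {
    config$continuation_interval_weeks
  } else {
    config$acute_interval_weeks
  }

  new_state <- state
  new_state$weeks_since_init <- week
  new_state$phase <- phase
  new_state$full_since_week <- full_since
  new_state$full_response_streak_weeks <- streak
  new_state$last_cdp_index <- as.integer(cdp)

  rec <- new_recommendation(list(
    week = week,
    cdp_index = as.integer(cdp),
    category = as.character(category),
    percent_decrease = pdec,
    adherence_status = adherence_status,
    options = options,
    alerts = alerts,
    referral_mandatory = referral_mandatory,
    next_visit_weeks = next_visit,
    rule_id = rule_id,
    dose_mg = state$dose_mg
  ))
  list(recommendation = rec, state = new_state)
}

#' Interval to the next scheduled visit
#'
#' Biweekly reassessment through the acute phase; every 4 weeks once a
#' sustained full response has moved the episode to the continuation phase.
#' A referred episode has no schedule from this engine -- the patient is
#' with specialty care.
#'
#' @param state An `mbc_state`, or a phase string.
#' @param config An [engine_config()].
#' @return 2 or 4 (weeks).
#' @export
#' @examples
#' schedule_next_visit("acute")         # 2
#' schedule_next_visit("continuation")  # 4
schedule_next_visit <- function(state, config = engine_config()) {
  phase <- if (inherits(state, "mbc_state")) state$phase else as.character(state)
  switch(phase,
    acute = config$acute_interval_weeks,
    continuation = config$continuation_interval_weeks,
    referred = abort(paste0("A referred episode is closed to this engine; ",
                            "scheduling belongs to specialty care")),
    abort(paste0("Unknown phase '", phase, "'"))
  )
}

#' @export
print.mbc_recommendation <- function(x, ...) {
  cat(sprintf("<Recommendation> week %s (CDP #%d) | %s | %s\n",
              format(x$week), x$cdp_index, x$category, x$adherence_status))
  for (br in x$options) {
    kinds <- vapply(br$actions, `[[`, "", "kind")
    extra <- vapply(br$actions, function(a) {
      if (!is.null(a$target_dose_mg)) sprintf(" (to %g mg)", a$target_dose_mg) else ""
    }, "")
    cat("  option:", paste0(kinds, extra, collapse = " + "), "\n")
  }
  if (length(x$alerts)) cat("  alerts:", paste(x$alerts, collapse = ", "), "\n")
  if (x$referral_mandatory) cat("  referral to specialty care is mandatory\n")
  cat("  next visit in", x$next_visit_weeks, "weeks\n")
  invisible(x)
}

#' @export
print.mbc_state <- function(x, ...) {
  cat(sprintf(
    "<Episode state> baseline %d | week %s | phase %s | %g mg %s | full streak %g wk\n",
    x$baseline_total, format(x$weeks_since_init), x$phase, x$dose_mg,
    x$frequency, x$full_response_streak_weeks))
  invisible(x)
}
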