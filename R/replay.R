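encode_actions <- function(actions) {
  vapply(actions, function(a) {
    if (!is.null(a$target_dose_mg)) {
      sprintf("%s->%gmg", a$kind, a$target_dose_mg)
    } else {
      a$kind
    }
  }, "")
}

encode_options <- function(options) {
  if (length(options) == 0) return("")
  paste(vapply(options, function(br) paste(encode_actions(br$actions),
                                           collapse = "+"), ""),
        collapse = " | ")
}

#' Replay a whole treatment episode through the decision engine
#'
#' Drives the longitudinal state machine across a full trajectory: the
#' week-0 record fixes the episode baseline and initial prescription; each
#' follow-up visit is scored, classified and evaluated in order, with the
#' prescription in effect at each visit taken from the trajectory record
#' (the clinician's actual choice among the offered options -- the engine
#' recommends, it never auto-applies). After the episode enters the
#' continuation phase, visits are still scored: a sustained full response
#' keeps a 4-weekly continue-dose recommendation, while loss of full
#' response raises a relapse alert and returns the episode to clinician
#' judgment (no further rules fire). After a mandatory referral the engine
#' only reiterates continuing the current dose until the specialist
#' evaluation.
#'
#' @param trajectory A trajectory list as produced by [read_trajectory()],
#'   [generate_cohort()] or [example_trajectory()]: `patient_id`, a
#'   `baseline` record (week 0, 11 checklist items, use flag, prescription)
#'   and `visits` with strictly increasing weeks.
#' @param config An [engine_config()].
#' @return An object of class `"mbc_episode"`: the per-visit recommendation
#'   list plus the final `mbc_state`. Use [tidy()] for a one-row-per-visit
#'   tibble, [glance()] for a one-row episode summary, and [autoplot()] to
#'   plot the trajectory.
#' @export
#' @examples
#' ep <- replay_episode(example_trajectory())
#' tidy(ep)
#' glance(ep)
replay_episode <- function(trajectory, config = engine_config()) {
  validate_trajectory(trajectory)
  b <- trajectory$baseline
  baseline_total <- sum(unlist(b$items))
  state <- new_episode(baseline_total, dose_mg = b$dose_mg,
                       frequency = b$frequency, config = config)
  recs <- vector("list", length(trajectory$visits))
  halted <- FALSE

  for (i in seq_along(trajectory$visits)) {
    v <- trajectory$visits[[i]]
    if (halted) break
    # prescription in effect at this visit: the clinician's applied choice
    state$dose_mg <- v$dose_mg
    state$frequency <- v$frequency
    total <- sum(unlist(v$items))
    adh <- classify_adherence(tibble(days_missed = v$days_missed,
                                     over_taking = v$over_taking,
                                     reasons = list(unlist(v$reasons) %||%
                                                      character())))

    if (state$phase == "acute") {
      out <- evaluate_visit(state, week = v$week, total = total,
                            use_2wk = v$use_2wk,
                            adherence_status = as.character(adh$adherence_status),
                            dose_increase_hint = adh$dose_increase_hint,
                            config = config)
      recs[[i]] <- out$recommendation
      state <- out$state
    } else if (state$phase == "continuation") {
      category <- classify_response(state$baseline_total, total, v$use_2wk)
      cdp <- map_week_to_cdp(v$week)
      if (category == "full") {
        recs[[i]] <- new_recommendation(list(
          week = v$week, cdp_index = as.integer(cdp),
          category = "full",
          percent_decrease = percent_decrease(state$baseline_total, total),
          adherence_status = as.character(adh$adherence_status),
          options = list(list(id = paste0("CDP", cdp, "/continuation"),
                              actions = list(list(kind = "continue_dose")))),
          alerts = character(), referral_mandatory = FALSE,
          next_visit_weeks = config$continuation_interval_weeks,
          rule_id = paste0("CDP", cdp, "/continuation"),
          dose_mg = state$dose_mg))
        state$weeks_since_init <- v$week
        state$full_response_streak_weeks <-
          v$week - state$full_since_week
      } else {
        # relapse during continuation: outside the published rules table
        recs[[i]] <- new_recommendation(list(
          week = v$week, cdp_index = as.integer(cdp),
          category = as.character(category),
          percent_decrease = percent_decrease(state$baseline_total, total),
          adherence_status = as.character(adh$adherence_status),
          options = list(), alerts = "relapse_clinician_judgment",
          referral_mandatory = FALSE, next_visit_weeks = NA_real_,
          rule_id = paste0("CDP", cdp, "/relapse"),
          dose_mg = state$dose_mg))
        state$weeks_since_init <- v$week
        halted <- TRUE
      }
    } else { # referred: episode closed to this engine
      category <- classify_response(state$baseline_total, total, v$use_2wk)
      cdp <- map_week_to_cdp(v$week)
      recs[[i]] <- new_recommendation(list(
        week = v$week, cdp_index = as.integer(cdp),
        category = as.character(category),
        percent_decrease = percent_decrease(state$baseline_total, total),
        adherence_status = as.character(adh$adherence_status),
        options = list(list(id = paste0("CDP", cdp, "/referred"),
                            actions = list(list(kind = "continue_dose")))),
        alerts = "awaiting_specialty_evaluation",
        referral_mandatory = TRUE, next_visit_weeks = NA_real_,
        rule_id = paste0("CDP", cdp, "/referred"),
        dose_mg = state$dose_mg))
      state$weeks_since_init <- v$week
    }
  }

  structure(
    list(patient_id = trajectory$patient_id,
         baseline_total = baseline_total,
         recommendations = purrr::compact(recs),
         final_state = state,
         trajectory = trajectory),
    class = "mbc_episode"
  )
}

#' @export
print.mbc_episode <- function(x, ...) {
  cat(sprintf("<mbc_episode> patient %s | baseline total %d | %d visit(s) | final phase %s\n",
              x$patient_id, x$baseline_total, length(x$recommendations),
              x$final_state$phase))
  invisible(x)
}

#' Tidy a replayed episode into one row per follow-up visit
#'
#' @param x An `mbc_episode` from [replay_episode()].
#' @param ... Unused.
#' @return A tibble: `patient_id`, `week`, `cdp_index`, `total`, `use_2wk`,
#'   `percent_decrease`, `category`, `adherence_status`, `dose_mg`,
#'   `options` (encoded `action+action | action` branches), `alerts`
#'   (semicolon-joined), `referral_mandatory`, `next_visit_weeks`.
#' @export
tidy.mbc_episode <- function(x, ...) {
  if (length(x$recommendations) == 0) {
    return(tibble(patient_id = character(), week = numeric(),
                  cdp_index = integer(), total = integer(),
                  use_2wk = logical(), days_missed = integer(),
                  over_taking = logical(), percent_decrease = numeric(),
                  category = character(), adherence_status = character(),
                  dose_mg = numeric(), options = character(),
                  alerts = character(), referral_mandatory = logical(),
                  next_visit_weeks = numeric()))
  }
  visits <- x$trajectory$visits[seq_along(x$recommendations)]
  purrr::map2_dfr(x$recommendations, visits, function(r, v) {
    tibble(patient_id = x$patient_id,
           week = r$week,
           cdp_index = r$cdp_index,
           total = sum(unlist(v$items)),
           use_2wk = v$use_2wk,
           days_missed = v$days_missed,
           over_taking = v$over_taking,
           percent_decrease = r$percent_decrease,
           category = r$category,
           adherence_status = r$adherence_status,
           dose_mg = r$dose_mg,
           options = encode_options(r$options),
           alerts = paste(r$alerts, collapse = ";"),
           referral_mandatory = r$referral_mandatory,
           next_visit_weeks = r$next_visit_weeks)
  })
}

#' One-row summary of a replayed episode
#'
#' @param x An `mbc_episode` from [replay_episode()].
#' @param ... Unused.
#' @return A one-row tibble: baseline total, number of follow-up visits,
#'   category at the last evaluated visit, final phase, week of continuation
#'   entry and of mandatory referral (NA when not reached), and the maximum
#'   prescribed dose seen on the trajectory.
#' @method glance mbc_episode
#' @export
glance.mbc_episode <- function(x, ...) {
  tt <- tidy(x)
  first_week <- function(flag) {
    w <- tt$week[flag]
    if (length(w)) min(w) else NA_real_
  }
  tibble(
    patient_id = x$patient_id,
    baseline_total = x$baseline_total,
    n_visits = nrow(tt),
    final_category = if (nrow(tt)) tt$category[nrow(tt)] else NA_character_,
    final_phase = x$final_state$phase,
    continuation_week = first_week(grepl("enter_continuation", tt$options,
                                         fixed = TRUE)),
    referral_week = first_week(tt$referral_mandatory &
                                 !grepl("awaiting", tt$alerts)),
    max_dose_mg = max(vapply(x$trajectory$visits, `[[`, 0, "dose_mg"),
                      x$trajectory$baseline$dose_mg)
  )
}

#' Plot a replayed episode trajectory
#'
#' Symptom-checklist total by week since initiation, coloured by the
#' engine's response category, with the week-0 baseline shown in grey, the
#' prescribed total daily dose as a dashed step line, and vertical markers
#' at continuation entry / mandatory referral.
#'
#' @param object An `mbc_episode`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mbc_episode
#' @export
autoplot.mbc_episode <- function(object, ...) {
  tt <- tidy(object)
  base <- tibble(week = 0, total = object$baseline_total,
                 category = "baseline",
                 dose_mg = object$trajectory$baseline$dose_mg)
  pts <- dplyr::bind_rows(base, tt[c("week", "total", "category", "dose_mg")])
  g <- glance(object)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$week, y = .data$total)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$dose_mg / 24 * 11),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 3) +
    ggplot2::scale_colour_manual(values = c(
      baseline = "grey40", minimal_nonresponse = "#d7301f",
      partial = "#fc8d59", full = "#1a9850")) +
    ggplot2::scale_y_continuous(
      "OUD symptom checklist total", limits = c(0, 11),
      sec.axis = ggplot2::sec_axis(~ . / 11 * 24,
                                   name = "buprenorphine (mg/day, dashed)")) +
    ggplot2::labs(x = "weeks since initiation", colour = "response",
                  title = paste("Treatment episode:", object$patient_id))
  if (!is.na(g$continuation_week)) {
    p <- p + ggplot2::geom_vline(xintercept = g$continuation_week,
                                 linetype = "dotted", colour = "#1a9850")
  }
  if (!is.na(g$referral_week)) {
    p <- p + ggplot2::geom_vline(xintercept = g$referral_week,
                                 linetype = "dotted", colour = "#d7301f")
  }
  p
}

#' Plot the treatment-response classification bands
#'
#' For a given baseline total, shows the category assigned to every
#' attainable follow-up total, with and without past-2-week opioid use --
#' a direct visual of the `< 25%` / `25-75%` / `> 75%` decrease bands and
#' of the rule that use in the past 2 weeks rules out a full response.
#'
#' @param baseline_total Baseline checklist total, integer 1-11.
#' @return A ggplot.
#' @export
#' @examples
#' plot_response_bands(8)
plot_response_bands <- function(baseline_total = 8) {
  grid <- tidyr::expand_grid(current = 0:11, use = c(FALSE, TRUE))
  grid$category <- as.character(
    classify_response(baseline_total, grid$current, grid$use))
  grid$decrease <- percent_decrease(baseline_total, grid$current)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$current,
                                     y = ifelse(.data$use, "use in past 2 wk",
                                                "no use"),
                                     fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      minimal_nonresponse = "#d7301f", partial = "#fc8d59",
      full = "#1a9850")) +
    ggplot2::labs(x = paste0("follow-up checklist total (baseline = ",
                             baseline_total, ")"),
                  y = NULL, fill = "category",
                  title = "Change-from-baseline response bands")
}
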