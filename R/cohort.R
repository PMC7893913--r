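#' Parameters for the synthetic trajectory generator
#'
#' The generator emulates the statistical structure the decision algorithm
#' assumes: a symptomatic baseline (checklist total 6-11 by default), three
#' latent response classes matching the classifier's bands, per-class
#' medication-adherence lapses, and visit dropout producing truncated,
#' off-schedule trajectories. It does not emulate item-level symptom
#' correlations, re-escalation after improvement, or quantity/frequency of
#' use -- only the total score, the dichotomous use flag, and adherence
#' counts, which are all the algorithm consumes.
#'
#' @param n_patients Number of trajectories.
#' @param seed Integer seed; same parameters and seed give byte-identical
#'   trajectories.
#' @param class_probs Probabilities of the latent classes
#'   (full_responder, partial_responder, nonresponder); must sum to 1.
#' @param baseline_score_range Inclusive integer range of baseline checklist
#'   totals.
#' @param full_response_week Week by which full responders cross the >75%
#'   decrease / no-use threshold (they sit in the partial band before it).
#' @param p_missed_day Named per-day probability of missing a dose, by class.
#' @param p_overtake Probability of an over-taking report at a visit.
#' @param dropout_hazard Per-visit probability that the patient drops out
#'   (trajectory truncated from that visit on).
#' @return A list with class `"cohort_params"`.
#' @export
cohort_params <- function(n_patients = 100,
                          seed = 1,
                          class_probs = c(full_responder = 1/3,
                                          partial_responder = 1/3,
                                          nonresponder = 1/3),
                          baseline_score_range = c(6, 11),
                          full_response_week = 6,
                          p_missed_day = c(full_responder = 0.02,
                                           partial_responder = 0.05,
                                           nonresponder = 0.10),
                          p_overtake = 0.02,
                          dropout_hazard = 0.05) {
  if (length(class_probs) != 3 || any(class_probs < 0) || any(class_probs > 1)) {
    abort("class_probs must be three probabilities in [0, 1]")
  }
  if (abs(sum(class_probs) - 1) > 1e-9) {
    abort("class_probs must sum to 1")
  }
  stopifnot(n_patients >= 1,
            baseline_score_range[1] >= 1, baseline_score_range[2] <= 11,
            baseline_score_range[1] <= baseline_score_range[2],
            full_response_week >= 2,
            all(p_missed_day >= 0 & p_missed_day <= 1),
            p_overtake >= 0, p_overtake <= 1,
            dropout_hazard >= 0, dropout_hazard <= 1)
  classes <- c("full_responder", "partial_responder", "nonresponder")
  names(class_probs) <- classes
  if (is.null(names(p_missed_day))) names(p_missed_day) <- classes
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         class_probs = class_probs,
         baseline_score_range = baseline_score_range,
         full_response_week = full_response_week,
         p_missed_day = p_missed_day, p_overtake = p_overtake,
         dropout_hazard = dropout_hazard),
    class = "cohort_params"
  )
}

# integer checklist totals that land exactly in each band for a baseline b
# (band membership is decided on exact fractions, so sampling within these
# ranges recovers the latent class by construction)
band_totals <- function(b, band) {
  switch(band,
    full = 0:((b - 1) %/% 4),                      # decrease > 75%
    partial = ceiling(b / 4):floor(3 * b / 4),     # 25% <= decrease <= 75%
    minimal = ceiling(0.8 * b):b                   # decrease <= 20%
  )
}

sample1 <- function(x) x[sample.int(length(x), 1)]

make_items <- function(endorsed_idx, total) {
  on_idx <- if (total > 0) sample(endorsed_idx, total) else integer()
  items <- integer(11)
  items[on_idx] <- 1L
  items
}

#' Generate a seeded synthetic cohort of patient trajectories
#'
#' Simulates `n_patients` treatment episodes in the trajectory format
#' consumed by [replay_episode()]. Each patient draws a latent response
#' class; checklist totals at each biweekly visit (weeks 2-12) are sampled
#' uniformly among the integer totals whose exact change-from-baseline
#' fraction lies in the class's band, and item-level responses are sampled
#' by choosing which baseline-endorsed criteria remit. Full responders sit
#' in the partial band (no use) before `full_response_week` and above the
#' 75% threshold with no use from then on; partial responders stay in the
#' 25-75% band with no use; non-responders stay below a 25% decrease with
#' ongoing use. Adherence lapses are drawn per class; dropout truncates
#' trajectories. Prescribed doses follow the engine's own recommendations
#' under a simulated clinician who takes the first-listed option branch
#' (overridable via `choice_policy`).
#'
#' @param params A [cohort_params()].
#' @param choice_policy Function `(options, state) -> branch index` choosing
#'   among a recommendation's "OR" branches; defaults to the first listed.
#' @return A list of trajectory lists, each carrying its `latent_class`
#'   label.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_params(n_patients = 3, seed = 42))
#' coh[[1]]$latent_class
generate_cohort <- function(params = cohort_params(), choice_policy = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(choice_policy)) choice_policy <- function(options, state) 1L
  set.seed(params$seed)
  classes <- names(params$class_probs)
  config <- engine_config()

  lapply(seq_len(params$n_patients), function(i) {
    cls <- sample(classes, 1, prob = params$class_probs)
    b <- sample1(seq(params$baseline_score_range[1],
                     params$baseline_score_range[2]))
    endorsed <- sample(11, b)
    baseline <- list(week = 0, items = make_items(endorsed, b),
                     use_2wk = TRUE,
                     dose_mg = config$initiation_dose_mg,
                     frequency = "once_daily")
    state <- new_episode(b, dose_mg = baseline$dose_mg, config = config)
    p_miss <- params$p_missed_day[[cls]]

    visits <- list()
    dose <- baseline$dose_mg
    freq <- baseline$frequency
    applied <- NA_character_
    for (w in seq(2, 12, by = 2)) {
      if (stats::runif(1) < params$dropout_hazard) break
      band <- switch(cls,
        full_responder = if (w >= params$full_response_week) "full" else "partial",
        partial_responder = "partial",
        nonresponder = "minimal")
      total <- sample1(band_totals(b, band))
      use <- switch(cls,
        full_responder = FALSE,
        partial_responder = FALSE,
        nonresponder = TRUE)
      days_missed <- stats::rbinom(1, 7, p_miss)
      over <- stats::runif(1) < params$p_overtake
      reasons <- if (days_missed > 0 || over) {
        sample(adherence_reason_codes(), sample1(1:2))
      } else {
        character()
      }
      v <- list(week = w, items = make_items(endorsed, total), use_2wk = use,
                days_missed = as.integer(days_missed), over_taking = over,
                reasons = reasons, dose_mg = dose, frequency = freq)
      if (!is.na(applied)) v$applied_action <- applied
      visits[[length(visits) + 1]] <- v

      # simulated clinician: evaluate and apply the chosen branch's dose
      # actions before the next visit
      applied <- NA_character_
      if (state$phase == "acute") {
        state$dose_mg <- dose
        state$frequency <- freq
        adh <- classify_adherence(tibble(days_missed = days_missed,
                                         over_taking = over,
                                         reasons = list(reasons)))
        out <- evaluate_visit(state, week = w, total = total, use_2wk = use,
                              adherence_status = as.character(adh$adherence_status),
                              dose_increase_hint = adh$dose_increase_hint,
                              config = config)
        state <- out$state
        opts <- out$recommendation$options
        if (length(opts) > 0) {
          br <- opts[[min(choice_policy(opts, state), length(opts))]]
          kinds <- vapply(br$actions, `[[`, "", "kind")
          applied <- paste(kinds, collapse = "+")
          for (a in br$actions) {
            if (a$kind == "increase_dose") dose <- a$target_dose_mg
            if (a$kind == "split_dose_bid") freq <- "twice_daily"
          }
        }
      }
    }

    list(schema_version = trajectory_schema_version,
         patient_id = sprintf("SYN-%04d", i),
         latent_class = cls,
         baseline = baseline,
         visits = visits)
  })
}

#' Summarise a generated cohort after replay
#'
#' Replays every trajectory and binds the one-row [glance()] summaries,
#' alongside the generator's latent class labels.
#'
#' @param cohort A list of trajectories from [generate_cohort()].
#' @param config An [engine_config()].
#' @return A tibble, one row per patient, with `latent_class` prepended to
#'   the [glance.mbc_episode()] columns.
#' @export
summarize_cohort <- function(cohort, config = engine_config()) {
  purrr::map_dfr(cohort, function(tr) {
    dplyr::bind_cols(tibble(latent_class = tr$latent_class %||% NA_character_),
                     glance(replay_episode(tr, config = config)))
  })
}

#' The scripted worked-example trajectory
#'
#' A hand-constructed episode reproducing the canonical worked scenario for
#' this algorithm: a patient using heroin daily at intake is stabilised on
#' 8 mg buprenorphine; at week 2 use has decreased but continues, the
#' response is partial, and the clinician increases the dose to 12 mg; at
#' week 4 the patient reports 2 days of small use with broad symptom
#' improvement, remains a partial responder, and the dose is continued; at
#' week 6 the patient reports no use since the last visit and achieves a
#' full response. The scenario fixes doses, use flags and response bands;
#' the checklist totals are constructed to land in those bands (synthetic
#' values -- the bands, not the totals, are normative).
#'
#' @return A trajectory list suitable for [replay_episode()].
#' @export
#' @examples
#' tidy(replay_episode(example_trajectory()))[, c("week", "category", "dose_mg")]
example_trajectory <- function() {
  items_n <- function(n) c(rep(1L, n), rep(0L, 11 - n))
  follow <- function(week, total, use, dose, applied = NULL) {
    v <- list(week = week, items = items_n(total), use_2wk = use,
              days_missed = 0L, over_taking = FALSE, reasons = character(),
              dose_mg = dose, frequency = "once_daily")
    if (!is.null(applied)) v$applied_action <- applied
    v
  }
  list(
    schema_version = trajectory_schema_version,
    patient_id = "worked-example-2",
    baseline = list(week = 0, items = items_n(8), use_2wk = TRUE,
                    dose_mg = 8, frequency = "once_daily"),
    visits = list(
      follow(2, total = 1, use = TRUE, dose = 8),
      follow(4, total = 1, use = TRUE, dose = 12, applied = "increase_dose"),
      follow(6, total = 1, use = FALSE, dose = 12, applied = "continue_dose")
    )
  )
}
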