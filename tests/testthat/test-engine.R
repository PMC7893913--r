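test_that("elapsed weeks map to the floor critical decision point", {
  expect_equal(map_week_to_cdp(c(0, 2, 4, 6, 8, 10, 12)), 1:7)
  expect_equal(map_week_to_cdp(5), 3L)     # off-schedule: week-4 rules
  expect_equal(map_week_to_cdp(13), 7L)    # week-12 rules persist
  expect_equal(map_week_to_cdp(40), 7L)
  expect_error(map_week_to_cdp(-1), "non-negative")
})

test_that("dose proposals are capped at 24 mg", {
  expect_equal(apply_dose_cap(c(28, 16, 24)), c(24, 16, 24))
  expect_error(apply_dose_cap(0), "positive")
  expect_error(apply_dose_cap(-4), "positive")
})

test_that("visit cadence is 2 weeks acute, 4 weeks continuation, none once referred", {
  expect_equal(schedule_next_visit("acute"), 2)
  expect_equal(schedule_next_visit("continuation"), 4)
  expect_error(schedule_next_visit("referred"), "specialty")
  st <- new_episode(8)
  expect_equal(schedule_next_visit(st), 2)
})

test_that("episode entry requires a symptomatic baseline", {
  expect_error(new_episode(0), "not symptomatic")
  expect_error(new_episode(12), "1-11")
  st <- new_episode(8)
  expect_equal(st$phase, "acute")
  expect_equal(st$dose_mg, 8)
})

test_that("week-2 rows match the printed grid", {
  st <- new_episode(8)
  full <- evaluate_visit(st, 2, total = 1, use_2wk = FALSE)
  expect_equal(emitted_branches(full$recommendation), list("continue_dose"))
  expect_equal(full$recommendation$next_visit_weeks, 2)

  partial <- evaluate_visit(st, 2, total = 4, use_2wk = FALSE)
  expect_equal(emitted_branches(partial$recommendation),
               list("continue_dose", "increase_dose"))

  minimal <- evaluate_visit(st, 2, total = 8, use_2wk = FALSE)
  expect_equal(emitted_branches(minimal$recommendation),
               list("increase_dose"))
  # the increase payload carries the capped target dose
  expect_equal(minimal$recommendation$options[[1]]$actions[[1]]$target_dose_mg,
               12)
})

test_that("minimal response at weeks 10-12 mandates specialty referral", {
  st <- new_episode(8)
  out <- evaluate_visit(st, 10, total = 8, use_2wk = FALSE)
  expect_true(out$recommendation$referral_mandatory)
  expect_equal(emitted_branches(out$recommendation),
               list(c("refer_specialty", "continue_dose")))
  expect_equal(out$state$phase, "referred")
  expect_true("minimal_response_trial_cap" %in% out$recommendation$alerts)
  # once referred, the acute-phase machine refuses further visits
  expect_error(evaluate_visit(out$state, 12, 8, FALSE), "phase")
})

test_that("non-adherence pre-empts every other change", {
  st <- new_episode(8)
  out <- evaluate_visit(st, 4, total = 4, use_2wk = FALSE,
                        adherence_status = "nonadherent_under",
                        dose_increase_hint = FALSE)
  expect_equal(emitted_branches(out$recommendation),
               list("address_nonadherence"))
  expect_true("nonadherence" %in% out$recommendation$alerts)
  expect_false(out$recommendation$referral_mandatory)

  hint <- evaluate_visit(st, 4, total = 4, use_2wk = FALSE,
                         adherence_status = "nonadherent_under",
                         dose_increase_hint = TRUE)
  expect_true("consider_dose_increase_for_craving_withdrawal" %in%
                hint$recommendation$alerts)

  # nonadherent minimal response at week 10: adherence still comes first
  ref <- evaluate_visit(st, 10, total = 8, use_2wk = FALSE,
                        adherence_status = "nonadherent_over")
  expect_equal(emitted_branches(ref$recommendation),
               list("address_nonadherence"))
  expect_false(ref$recommendation$referral_mandatory)
  expect_equal(ref$state$phase, "acute")
})

test_that("continuation requires 4 weeks of sustained full response", {
  st <- new_episode(8)
  w2 <- evaluate_visit(st, 2, total = 1, use_2wk = FALSE)
  expect_equal(emitted_branches(w2$recommendation), list("continue_dose"))
  w4 <- evaluate_visit(w2$state, 4, total = 1, use_2wk = FALSE)
  expect_equal(emitted_branches(w4$recommendation), list("continue_dose"))
  w6 <- evaluate_visit(w4$state, 6, total = 1, use_2wk = FALSE)
  expect_equal(emitted_branches(w6$recommendation), list("enter_continuation"))
  expect_equal(w6$recommendation$next_visit_weeks, 4)
  expect_equal(w6$state$phase, "continuation")

  # a lapse out of full response resets the streak
  st2 <- new_episode(8)
  a <- evaluate_visit(st2, 2, total = 1, use_2wk = FALSE)
  b <- evaluate_visit(a$state, 4, total = 5, use_2wk = FALSE)  # partial
  c_ <- evaluate_visit(b$state, 6, total = 1, use_2wk = FALSE)
  d <- evaluate_visit(c_$state, 8, total = 1, use_2wk = FALSE)
  expect_equal(emitted_branches(d$recommendation), list("continue_dose"))
  e <- evaluate_visit(d$state, 10, total = 1, use_2wk = FALSE)
  expect_equal(emitted_branches(e$recommendation), list("enter_continuation"))
})

test_that("at the 24 mg ceiling the increase branch is withdrawn in printed order", {
  st <- new_episode(8, dose_mg = 24)
  w8 <- evaluate_visit(st, 8, total = 8, use_2wk = FALSE)
  expect_equal(emitted_branches(w8$recommendation),
               list(c("split_dose_bid", "add_counseling"),
                    c("refer_specialty", "continue_dose")))
  # week-2 minimal has only the increase branch: fall back to continue
  w2 <- evaluate_visit(st, 2, total = 8, use_2wk = FALSE)
  expect_equal(emitted_branches(w2$recommendation), list("continue_dose"))
})

test_that("engine output matches the hand-transcribed rules grid for every cell", {
  for (cdp in 2:7) {
    week <- 2 * (cdp - 1)
    for (category in c("full", "partial", "minimal_nonresponse")) {
      for (dose in c(8, 24)) {
        st <- new_episode(8, dose_mg = dose)
        inp <- cell_inputs(category)
        out <- evaluate_visit(st, week, total = inp$total, use_2wk = inp$use)
        exp <- oracle_cell(cdp, category, dose_mg = dose, streak = 0)
        info <- sprintf("CDP %d / %s / %d mg", cdp, category, dose)
        expect_equal(emitted_branches(out$recommendation), exp$branches,
                     info = info)
        expect_equal(out$recommendation$referral_mandatory, exp$referral,
                     info = info)
      }
    }
  }
})

test_that("trial-cap alerts follow the footnotes", {
  st <- new_episode(8)
  # minimal responder beyond week 8
  expect_true("minimal_response_trial_cap" %in%
    evaluate_visit(st, 10, 8, FALSE)$recommendation$alerts)
  expect_false("minimal_response_trial_cap" %in%
    evaluate_visit(st, 8, 8, FALSE)$recommendation$alerts)
  # partial responder beyond week 12
  expect_true("partial_response_trial_cap" %in%
    evaluate_visit(st, 13, 4, FALSE)$recommendation$alerts)
  expect_false("partial_response_trial_cap" %in%
    evaluate_visit(st, 12, 4, FALSE)$recommendation$alerts)
})

test_that("identical state and inputs give identical recommendations", {
  st <- new_episode(9, dose_mg = 12)
  a <- evaluate_visit(st, 6, total = 4, use_2wk = FALSE)
  b <- evaluate_visit(st, 6, total = 4, use_2wk = FALSE)
  expect_identical(a, b)
  expect_identical(jsonlite::toJSON(a$recommendation, auto_unbox = TRUE,
                                    digits = NA, force = TRUE),
                   jsonlite::toJSON(b$recommendation, auto_unbox = TRUE,
                                    digits = NA, force = TRUE))
})

test_that("the shipped rules table tidies to the printed grid", {
  tab <- decision_rules()
  expect_equal(sort(unique(tab$cdp)), 1:7)
  expect_equal(unique(tab$week), seq(0, 12, by = 2))
  # the only mandatory-referral rows are minimal response at weeks 10 and 12
  mand <- dplyr::distinct(tab[tab$referral_mandatory,
                              c("cdp", "category")])
  expect_equal(mand$cdp, c(6, 7))
  expect_equal(unique(mand$category), "minimal")
})
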