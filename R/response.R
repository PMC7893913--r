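response_levels <- function() c("minimal_nonresponse", "partial", "full")

#' Percent decrease of the symptom-checklist total from baseline
#'
#' Change from baseline as a signed fraction: `(baseline - current) /
#' baseline`, so 1 is a 100% decrease and negative values mean worsening.
#' A baseline total of 0 is degenerate -- a patient entering treatment with
#' no endorsed criteria is not symptomatic and cannot be tracked by change
#' from baseline -- and is rejected.
#'
#' @param baseline_total Baseline checklist total(s), integer >= 1.
#' @param current_total Current checklist total(s), integer 0-11.
#' @return Numeric vector of signed fractions.
#' @export
#' @examples
#' percent_decrease(10, c(2, 10))   # 0.80, 0.00
#' percent_decrease(8, 10)          # -0.25: worsening
percent_decrease <- function(baseline_total, current_total) {
  if (any(is.na(baseline_total)) || any(baseline_total < 1)) {
    abort(paste0("Degenerate baseline: change from baseline is undefined for ",
                 "a baseline checklist total of 0"))
  }
  (baseline_total - current_total) / baseline_total
}

#' Classify treatment response from change in checklist total and opioid use
#'
#' The three-band change-from-baseline classifier that drives the decision
#' engine. With `d` the decrease from baseline as a fraction and `use` the
#' self-reported use of any opioid other than buprenorphine in the past
#' 2 weeks:
#'
#' * **full** response: `d > 75%` AND no use;
#' * **partial** response: `25% <= d <= 75%` with no use, OR `d > 75%` with use;
#' * **minimal_nonresponse**: `d < 25%` (including any worsening), OR
#'   `25% <= d <= 75%` with use.
#'
#' The 25% and 75% boundaries belong to the partial band (the bands are
#' printed as `< 25%`, `25-75%`, `> 75%`). Band membership is decided on
#' exact rational comparisons (`4 * (baseline - current)` against `baseline`
#' and `3 * baseline`), so integer checklist totals never suffer floating-
#' point boundary errors. A full response is never returned when use is
#' reported.
#'
#' @param baseline_total Baseline checklist total(s), integer >= 1.
#' @param current_total Current checklist total(s).
#' @param used_opioid_past_2wk Logical: any opioid use (other than
#'   buprenorphine) in the past 2 weeks.
#' @return Factor with levels minimal_nonresponse < partial < full.
#' @export
#' @examples
#' classify_response(10, 2, FALSE)   # full
#' classify_response(10, 2, TRUE)    # partial: >75% decrease but ongoing use
#' classify_response(10, 5, TRUE)    # minimal_nonresponse: in-band with use
#' classify_response(4, 3, FALSE)    # partial: exactly 25% sits in the band
classify_response <- function(baseline_total, current_total,
                              used_opioid_past_2wk) {
  if (any(is.na(baseline_total)) || any(baseline_total < 1)) {
    abort(paste0("Degenerate baseline: a baseline checklist total of 0 ",
                 "cannot be classified by change from baseline"))
  }
  if (any(is.na(used_opioid_past_2wk))) {
    abort("used_opioid_past_2wk must be TRUE/FALSE")
  }
  use <- as.logical(used_opioid_past_2wk)
  drop4 <- 4 * (baseline_total - current_total)  # 4*b*d, exact for integers
  gt75 <- drop4 > 3 * baseline_total
  ge25 <- drop4 >= baseline_total
  le75 <- !gt75
  cat <- dplyr::case_when(
    gt75 & !use ~ "full",
    (ge25 & le75 & !use) | (gt75 & use) ~ "partial",
    .default = "minimal_nonresponse"
  )
  factor(cat, levels = response_levels(), ordered = TRUE)
}

#' Assess treatment response for a table of visits
#'
#' Data-frame front end to [percent_decrease()] and [classify_response()]:
#' takes scored visits (see [score_checklist()]) and appends the signed
#' percent decrease from baseline and the response category.
#'
#' @param visits A data frame with integer `total` and logical `use_2wk`
#'   columns (one row per follow-up visit).
#' @param baseline_total The immutable week-0 baseline checklist total for
#'   the episode (integer >= 1).
#' @return The input as a tibble with `percent_decrease` and `category`
#'   columns appended.
#' @export
#' @examples
#' v <- tibble::tibble(total = c(6, 3, 1), use_2wk = c(TRUE, FALSE, FALSE))
#' assess_response(v, baseline_total = 8)
assess_response <- function(visits, baseline_total) {
  visits <- as_tibble(visits)
  stopifnot(all(c("total", "use_2wk") %in% names(visits)))
  dplyr::mutate(visits,
                percent_decrease = percent_decrease(baseline_total, .data$total),
                category = classify_response(baseline_total, .data$total,
                                             .data$use_2wk))
}
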