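#' Opioid screening gate on TAPS substance scores
#'
#' Applies the universal-screening rule for office-based OUD care: any
#' patient scoring above zero on the heroin item or the prescription-opioid
#' item of the TAPS tool needs further assessment for opioid use disorder.
#' Scores for other substances (tobacco, alcohol, ...) never affect the
#' result. TAPS internals are not rescored here; the gate consumes the
#' per-substance risk scores as given.
#'
#' @param scores A data frame with one row per screened patient and
#'   non-negative integer score columns named by substance. Columns `heroin`
#'   and `rx_opioid` are required (0 when not endorsed); any other columns
#'   are carried through untouched.
#' @return The input as a tibble with a logical `needs_oud_assessment`
#'   column appended.
#' @export
#' @examples
#' taps_opioid_gate(tibble::tibble(heroin = c(0, 1, 0), rx_opioid = c(0, 0, 2),
#'                                 alcohol = c(3, 0, 0)))
taps_opioid_gate <- function(scores) {
  scores <- as_tibble(scores)
  missing_cols <- setdiff(c("heroin", "rx_opioid"), names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("Malformed TAPS record: missing required score column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- dplyr::select(scores, dplyr::where(is.numeric))
  if (any(is.na(scores$heroin)) || any(is.na(scores$rx_opioid))) {
    abort("Malformed TAPS record: heroin/rx_opioid score is NA")
  }
  if (any(unlist(num) < 0, na.rm = TRUE)) {
    abort("TAPS scores must be non-negative")
  }
  dplyr::mutate(scores,
                needs_oud_assessment = .data$heroin > 0 | .data$rx_opioid > 0)
}

item_cols <- function() paste0("item_", 1:11)

check_items <- function(items_mat, where = "checklist") {
  if (ncol(items_mat) != 11) {
    abort(paste0("A ", where, " administration needs exactly 11 criterion ",
                 "items; got ", ncol(items_mat)))
  }
  if (any(is.na(items_mat))) {
    abort(paste0("Missing ", where, " item response: items are rejected, ",
                 "never imputed, because the total drives treatment decisions"))
  }
  if (!all(items_mat %in% c(0, 1))) {
    abort(paste0(where, " items must be yes/no coded as 1/0"))
  }
  invisible(items_mat)
}

#' Score the OUD symptom checklist
#'
#' Scores administrations of the 11-item symptom checklist derived from the
#' DSM-5 OUD criteria. Each item is a yes/no question; each yes scores one
#' point and points are summed to a total of 0-11. The companion item asking
#' about use of any opioid other than buprenorphine in the past 2 weeks is
#' validated and passed through unchanged -- it is never counted in the
#' total; it enters the response classification separately (see
#' [classify_response()]). Missing items are rejected, not imputed.
#'
#' @param visits A data frame with one row per administration: columns
#'   `item_1` ... `item_11` coded 1 = yes / 0 = no, and a logical (or 0/1)
#'   `use_2wk` column for the past-2-week opioid-use item.
#' @return The input as a tibble with an integer `total` column appended.
#' @export
#' @examples
#' v <- tibble::tibble(!!!stats::setNames(as.list(c(1, 1, 0, 1, 0, 0, 0, 1, 0, 0, 0)),
#'                                        paste0("item_", 1:11)),
#'                     use_2wk = TRUE)
#' score_checklist(v)$total
score_checklist <- function(visits) {
  visits <- as_tibble(visits)
  missing_cols <- setdiff(c(item_cols(), "use_2wk"), names(visits))
  if (length(missing_cols) > 0) {
    abort(paste0("Checklist record is missing field(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  items <- as.matrix(visits[item_cols()])
  check_items(items)
  if (any(is.na(visits$use_2wk))) {
    abort("Missing past-2-week opioid use response")
  }
  dplyr::mutate(visits,
                use_2wk = as.logical(.data$use_2wk),
                total = as.integer(rowSums(items)))
}

#' Classify medication adherence from the adherence questionnaire
#'
#' Applies the adherence rule for buprenorphine treatment: taking medication
#' at least 80% of the time -- missing no more than 1 day in the past week --
#' with no over-taking is `adherent`. Taking more than prescribed is
#' `nonadherent_over` and takes precedence over under-taking when both are
#' reported (the more safety-relevant status surfaces; both facts stay on the
#' record). Missing more than 1 day without over-taking is
#' `nonadherent_under`. When a non-adherent patient endorses ongoing craving
#' or opioid withdrawal among the reasons for non-adherence, the
#' `dose_increase_hint` flag is set: clinicians are advised to consider a
#' buprenorphine dose increase in that situation.
#'
#' @param reports A data frame with one row per report: integer
#'   `days_missed` (0-7), logical `over_taking`, and `reasons` -- either a
#'   list-column of character vectors or a semicolon-delimited string drawn
#'   from [adherence_reason_codes()]. Reasons may be endorsed only when some
#'   non-adherence is reported.
#' @return The input as a tibble with `adherence_status` (factor:
#'   adherent / nonadherent_under / nonadherent_over) and logical
#'   `dose_increase_hint` columns appended, and `reasons` normalised to a
#'   list-column.
#' @export
#' @examples
#' classify_adherence(tibble::tibble(days_missed = c(1, 2, 0),
#'                                   over_taking = c(FALSE, FALSE, TRUE),
#'                                   reasons = list(character(), "craving", "other")))
classify_adherence <- function(reports) {
  reports <- as_tibble(reports)
  missing_cols <- setdiff(c("days_missed", "over_taking", "reasons"),
                          names(reports))
  if (length(missing_cols) > 0) {
    abort(paste0("Adherence report is missing field(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dm <- reports$days_missed
  if (any(is.na(dm)) || any(dm < 0 | dm > 7) || any(dm != trunc(dm))) {
    abort("days_missed must be an integer between 0 and 7")
  }
  if (any(is.na(reports$over_taking))) {
    abort("over_taking must be TRUE/FALSE")
  }
  reasons <- reports$reasons
  if (!is.list(reasons)) {
    reasons <- lapply(as.character(reasons), function(x) {
      if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  }
  reasons <- lapply(reasons, function(r) as.character(r[nzchar(r)]))
  bad <- unique(unlist(reasons))
  bad <- setdiff(bad, adherence_reason_codes())
  if (length(bad) > 0) {
    abort(paste0("Unknown non-adherence reason code(s): ",
                 paste(bad, collapse = ", ")))
  }
  over <- as.logical(reports$over_taking)
  nonadherent <- over | dm > 1
  has_reasons <- lengths(reasons) > 0
  if (any(has_reasons & !(over | dm > 0))) {
    abort(paste0("Non-adherence reasons endorsed on a report with no missed ",
                 "days and no over-taking"))
  }
  status <- dplyr::case_when(
    over ~ "nonadherent_over",
    dm > 1 ~ "nonadherent_under",
    .default = "adherent"
  )
  hint <- nonadherent &
    purrr::map_lgl(reasons, ~ any(.x %in% c("craving", "withdrawal")))
  reports$reasons <- reasons
  reports$adherence_status <- factor(status, levels = adherence_levels())
  reports$dose_increase_hint <- hint
  reports
}

adherence_levels <- function() {
  c("adherent", "nonadherent_under", "nonadherent_over")
}
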