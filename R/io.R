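trajectory_schema_version <- "1.0"

#' Path to the shipped trajectory JSON schema
#'
#' The JSON Schema document describing the trajectory file format; shipped
#' as the format contract. Validation inside the package is performed by
#' [validate_trajectory()], which enforces the same constraints and reports
#' the failing field and record index.
#'
#' @return File path.
#' @export
trajectory_schema_path <- function() {
  system.file("extdata", "trajectory-schema.json", package = "mbcoud",
              mustWork = TRUE)
}

fail_field <- function(field, index, msg) {
  where <- if (is.na(index)) "baseline" else paste0("visit ", index)
  abort(paste0("Invalid trajectory: ", where, ", field '", field, "': ", msg))
}

check_visit_record <- function(v, index, baseline = FALSE) {
  need <- if (baseline) {
    c("week", "items", "use_2wk", "dose_mg", "frequency")
  } else {
    c("week", "items", "use_2wk", "days_missed", "over_taking", "reasons",
      "dose_mg", "frequency")
  }
  for (f in need) {
    if (is.null(v[[f]])) fail_field(f, index, "missing")
  }
  items <- unlist(v$items)
  if (length(items) != 11) {
    fail_field("items", index,
               paste0("length ", length(items), "; exactly 11 checklist ",
                      "items are required"))
  }
  if (any(is.na(items)) || !all(items %in% c(0, 1))) {
    fail_field("items", index, "items must be 0/1 with none missing")
  }
  if (!is.logical(v$use_2wk) || is.na(v$use_2wk)) {
    fail_field("use_2wk", index, "must be TRUE/FALSE")
  }
  if (!is.numeric(v$dose_mg) || v$dose_mg <= 0) {
    fail_field("dose_mg", index, "must be a positive dose in mg")
  }
  if (!v$frequency %in% c("once_daily", "twice_daily")) {
    fail_field("frequency", index, "must be once_daily or twice_daily")
  }
  if (baseline) {
    if (v$week != 0) fail_field("week", index, "baseline must be week 0")
  } else {
    if (!is.numeric(v$week) || v$week <= 0) {
      fail_field("week", index, "follow-up weeks must be > 0")
    }
    dm <- v$days_missed
    if (!is.numeric(dm) || is.na(dm) || dm < 0 || dm > 7 || dm != trunc(dm)) {
      fail_field("days_missed", index, "must be an integer 0-7")
    }
    if (!is.logical(v$over_taking) || is.na(v$over_taking)) {
      fail_field("over_taking", index, "must be TRUE/FALSE")
    }
    reasons <- unlist(v$reasons) %||% character()
    bad <- setdiff(reasons, adherence_reason_codes())
    if (length(bad) > 0) {
      fail_field("reasons", index,
                 paste0("unknown code(s) ", paste(bad, collapse = ", ")))
    }
  }
  invisible(v)
}

#' Validate a trajectory against the shipped schema constraints
#'
#' Field-by-field validation of a trajectory list: schema version, patient
#' id, a week-0 baseline with exactly 11 complete checklist items and a
#' positive prescription, follow-up visits with complete checklist,
#' adherence fields and prescription, and strictly increasing visit weeks.
#' Errors name the failing field and record index.
#'
#' @param trajectory A trajectory list (see [read_trajectory()]).
#' @return The trajectory, invisibly, when valid.
#' @export
validate_trajectory <- function(trajectory) {
  if (!is.list(trajectory)) abort("Invalid trajectory: not a record")
  if (is.null(trajectory$schema_version) ||
      trajectory$schema_version != trajectory_schema_version) {
    abort(paste0("Invalid trajectory: schema_version must be '",
                 trajectory_schema_version, "'"))
  }
  if (is.null(trajectory$patient_id) || !nzchar(trajectory$patient_id)) {
    abort("Invalid trajectory: patient_id is missing or empty")
  }
  if (is.null(trajectory$baseline)) abort("Invalid trajectory: no baseline record")
  check_visit_record(trajectory$baseline, NA, baseline = TRUE)
  weeks <- vapply(trajectory$visits, `[[`, 0, "week")
  if (length(weeks) > 0 && any(diff(c(0, weeks)) <= 0)) {
    abort("Invalid trajectory: visit weeks must be strictly increasing")
  }
  for (i in seq_along(trajectory$visits)) {
    check_visit_record(trajectory$visits[[i]], i)
  }
  invisible(trajectory)
}

canonical_trajectory <- function(trajectory) {
  canon_visit <- function(v, baseline = FALSE) {
    out <- list(week = as.numeric(v$week),
                items = as.integer(unlist(v$items)),
                use_2wk = v$use_2wk)
    if (!baseline) {
      out$days_missed <- as.integer(v$days_missed)
      out$over_taking <- v$over_taking
      out$reasons <- as.character(unlist(v$reasons) %||% character())
    }
    out$dose_mg <- as.numeric(v$dose_mg)
    out$frequency <- v$frequency
    if (!baseline && !is.null(v$applied_action)) {
      out$applied_action <- v$applied_action
    }
    out
  }
  out <- list(schema_version = trajectory$schema_version,
              patient_id = trajectory$patient_id)
  if (!is.null(trajectory$latent_class)) {
    out$latent_class <- trajectory$latent_class
  }
  out$baseline <- canon_visit(trajectory$baseline, baseline = TRUE)
  out$visits <- lapply(trajectory$visits, canon_visit)
  out
}

#' Read a trajectory JSON file
#'
#' Reads and validates one patient trajectory. Files are canonical JSON:
#' fixed key order, checklist items as an 11-element 0/1 array, weeks as
#' weeks-since-initiation numbers.
#'
#' @param path Path to a trajectory `.json` file.
#' @return A validated trajectory list in canonical form.
#' @export
read_trajectory <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw$visits <- raw$visits %||% list()
  traj <- canonical_trajectory(raw)
  validate_trajectory(traj)
  traj
}

#' Write a trajectory to canonical JSON
#'
#' Serialisation is canonical -- fixed key order, no rounding -- so that
#' writing the same trajectory twice (or a read/write round trip) is
#' byte-stable.
#'
#' @param trajectory A trajectory list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  traj <- canonical_trajectory(trajectory)
  validate_trajectory(traj)
  json <- jsonlite::toJSON(traj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Export replayed visits as a flat CSV table
#'
#' Replays each trajectory through the decision engine and flattens the
#' results to one row per follow-up visit. The nested option branches are
#' encoded as `action+action | action` strings (the JSON trajectory format
#' remains the canonical, lossless representation).
#'
#' @param trajectories A single trajectory or a list of trajectories.
#' @param path Optional output path; when given, the table is written as
#'   CSV (header-only for an empty cohort).
#' @param config An [engine_config()].
#' @return A tibble with columns `patient_id`, `week`, `total`, `use_2wk`,
#'   `days_missed`, `over_taking`, `category`, `cdp_index`, `options`,
#'   `alerts`, `referral_mandatory`, `next_visit_weeks`.
#' @export
#' @examples
#' export_visits_csv(example_trajectory())
export_visits_csv <- function(trajectories, path = NULL,
                              config = engine_config()) {
  if (!is.null(trajectories$baseline)) trajectories <- list(trajectories)
  cols <- c("patient_id", "week", "total", "use_2wk", "days_missed",
            "over_taking", "category", "cdp_index", "options", "alerts",
            "referral_mandatory", "next_visit_weeks")
  tab <- purrr::map_dfr(trajectories,
                        ~ tidy(replay_episode(.x, config = config)))
  if (nrow(tab) == 0) {
    tab <- tibble(patient_id = character(), week = numeric(),
                  total = integer(), use_2wk = logical(),
                  days_missed = integer(), over_taking = logical(),
                  category = character(), cdp_index = integer(),
                  options = character(), alerts = character(),
                  referral_mandatory = logical(),
                  next_visit_weeks = numeric())
  }
  tab <- tab[cols]
  if (!is.null(path)) readr::write_csv(tab, path)
  tab
}
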