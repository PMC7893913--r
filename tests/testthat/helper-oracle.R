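# Hand-transcribed oracle of the published decision-rules grid (7 CDPs x 3
# response categories), written directly from the printed table and kept
# independent of the YAML asset the engine executes. Each branch is a
# character vector of action kinds, branches in printed order.
oracle_grid <- list(
  `2` = list(
    partial = list(c("continue_dose"), c("increase_dose")),
    minimal = list(c("increase_dose"))
  ),
  `3` = list(
    partial = list(c("increase_dose", "add_counseling"),
                   c("continue_dose", "add_counseling")),
    minimal = list(c("increase_dose", "add_counseling"),
                   c("continue_dose", "add_counseling"))
  ),
  `4` = list(
    partial = list(c("increase_dose", "add_counseling"),
                   c("split_dose_bid", "add_counseling")),
    minimal = list(c("increase_dose", "add_counseling"),
                   c("split_dose_bid", "add_counseling"),
                   c("refer_specialty", "continue_dose"))
  ),
  `5` = list(
    partial = list(c("increase_dose", "add_counseling"),
                   c("split_dose_bid", "add_counseling")),
    minimal = list(c("split_dose_bid", "add_counseling"),
                   c("refer_specialty", "continue_dose"))
  ),
  `6` = list(
    partial = list(c("increase_dose"), c("add_counseling"),
                   c("refer_specialty", "continue_dose")),
    minimal = list(c("refer_specialty", "continue_dose"))
  ),
  `7` = list(
    partial = list(c("increase_dose"), c("add_counseling"),
                   c("refer_specialty", "continue_dose")),
    minimal = list(c("refer_specialty", "continue_dose"))
  )
)

# expected branches for one engine cell, after applying the side rules the
# engine is responsible for (continuation streak, 24 mg cap + fallback,
# mandatory referral); referral flag returned alongside
oracle_cell <- function(cdp, category, dose_mg = 8, streak = 0, cap = 24) {
  if (category == "full") {
    branches <- if (streak >= 4) list("enter_continuation") else list("continue_dose")
    return(list(branches = branches, referral = FALSE))
  }
  key <- if (category == "minimal_nonresponse") "minimal" else "partial"
  branches <- oracle_grid[[as.character(cdp)]][[key]]
  referral <- cdp >= 6 && key == "minimal"
  if (dose_mg >= cap) {
    branches <- Filter(function(br) !"increase_dose" %in% br, branches)
  }
  if (length(branches) == 0 && !referral) branches <- list("continue_dose")
  list(branches = branches, referral = referral)
}

# action kinds actually emitted by the engine for a cell, as a list of
# character vectors
emitted_branches <- function(rec) {
  lapply(rec$options, function(br) vapply(br$actions, `[[`, "", "kind"))
}

# (total, use) pairs that land in each category for a baseline of 8
cell_inputs <- function(category) {
  switch(category,
    full = list(total = 1, use = FALSE),
    partial = list(total = 4, use = FALSE),
    minimal_nonresponse = list(total = 8, use = FALSE))
}
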