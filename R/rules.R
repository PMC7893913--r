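# The decision rules ship as a machine-readable YAML asset; the engine
# executes that asset rather than hard-coded branches, so the rules a reader
# audits are the rules that run. Loaded once per session.
rules_cache <- new.env(parent = emptyenv())

load_rules <- function() {
  if (is.null(rules_cache$rules)) {
    path <- system.file("extdata", "decision_rules.yaml", package = "mbcoud",
                        mustWork = TRUE)
    rules_cache$rules <- yaml::read_yaml(path)
  }
  rules_cache$rules
}

rules_for <- function(cdp_index, category_key) {
  rules <- load_rules()
  blk <- purrr::detect(rules$cdps, ~ .x$cdp == cdp_index)
  if (is.null(blk)) {
    abort(paste0("No decision rules defined for CDP #", cdp_index))
  }
  row <- blk$rows[[category_key]]
  if (is.null(row)) {
    abort(paste0("No decision rule row for CDP #", cdp_index,
                 " / ", category_key))
  }
  row
}

#' The clinical decision support rules table
#'
#' Returns the shipped rules table -- seven critical decision points (CDPs)
#' covering weeks 0 through 12 at a 2-week cadence, with the option branches
#' offered for each treatment-response category in printed order -- as a
#' tidy tibble, one row per option branch. This is the asset the engine
#' executes; rendering it groups naturally by `cdp`/`category`.
#'
#' @return A tibble with columns `cdp`, `week`, `category`, `branch`
#'   (1-based position within the row), `actions` (list-column of action
#'   kinds), `requires` (`"sustained_full_4wk"`, `"otherwise"`, or `NA` for
#'   unconditional branches) and `referral_mandatory`.
#' @export
#' @examples
#' decision_rules()
decision_rules <- function() {
  rules <- load_rules()
  purrr::map_dfr(rules$cdps, function(blk) {
    purrr::imap_dfr(blk$rows, function(row, key) {
      tibble(cdp = blk$cdp,
             week = blk$week,
             category = key,
             branch = seq_along(row$branches),
             actions = purrr::map(row$branches, ~ unlist(.x$actions)),
             requires = purrr::map_chr(row$branches,
                                       ~ .x$requires %||% NA_character_),
             referral_mandatory = isTRUE(row$referral_mandatory))
    })
  })
}
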