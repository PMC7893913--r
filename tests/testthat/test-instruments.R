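test_that("opioid screening gate fires on heroin or rx-opioid score > 0 only", {
  scores <- tibble::tibble(
    heroin    = c(0, 1, 0, 0, 3),
    rx_opioid = c(0, 0, 2, 0, 1),
    alcohol   = c(3, 0, 0, 9, 0),
    tobacco   = c(0, 0, 0, 5, 0))
  out <- taps_opioid_gate(scores)
  expect_equal(out$needs_oud_assessment, c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("gate is monotone in the opioid scores and blind to other substances", {
  grid <- tidyr::expand_grid(heroin = 0:3, rx_opioid = 0:3, alcohol = 0:3)
  out <- taps_opioid_gate(grid)
  expect_equal(out$needs_oud_assessment, grid$heroin > 0 | grid$rx_opioid > 0)
  # raising either opioid score never flips TRUE -> FALSE
  bumped_h <- taps_opioid_gate(dplyr::mutate(grid, heroin = heroin + 1))
  bumped_r <- taps_opioid_gate(dplyr::mutate(grid, rx_opioid = rx_opioid + 1))
  expect_true(all(bumped_h$needs_oud_assessment >= out$needs_oud_assessment))
  expect_true(all(bumped_r$needs_oud_assessment >= out$needs_oud_assessment))
})

test_that("malformed TAPS records are rejected", {
  expect_error(taps_opioid_gate(tibble::tibble(heroin = 1)), "rx_opioid")
  expect_error(taps_opioid_gate(tibble::tibble(heroin = NA, rx_opioid = 0)),
               "NA")
  expect_error(taps_opioid_gate(tibble::tibble(heroin = -1, rx_opioid = 0)),
               "non-negative")
})

test_that("checklist total equals the yes count for all 2^11 response vectors", {
  vecs <- as.matrix(expand.grid(rep(list(0:1), 11)))
  colnames(vecs) <- paste0("item_", 1:11)
  df <- tibble::as_tibble(vecs)
  df$use_2wk <- rep(c(TRUE, FALSE), length.out = nrow(df))
  scored <- score_checklist(df)
  # brute-force oracle: count yes items one row at a time
  oracle <- apply(vecs, 1, function(r) sum(r == 1))
  expect_equal(scored$total, as.integer(oracle))
  expect_true(all(scored$total >= 0 & scored$total <= 11))
  # the past-2-week use item passes through and is never counted
  expect_equal(scored$use_2wk, df$use_2wk)
})

test_that("incomplete checklist administrations are rejected, not imputed", {
  row <- tibble::as_tibble(as.list(stats::setNames(rep(1, 11),
                                                   paste0("item_", 1:11))))
  row$use_2wk <- TRUE
  expect_error(score_checklist(dplyr::select(row, -item_7)), "item_7")
  row_na <- row; row_na$item_3 <- NA
  expect_error(score_checklist(row_na), "never imputed")
  row_bad <- row; row_bad$item_3 <- 2
  expect_error(score_checklist(row_bad), "yes/no")
  row_nouse <- row; row_nouse$use_2wk <- NA
  expect_error(score_checklist(row_nouse), "use")
})

test_that("adherence rule: at most 1 missed day and no over-taking is adherent", {
  reports <- tibble::tibble(
    days_missed = c(1, 2, 0, 0),
    over_taking = c(FALSE, FALSE, TRUE, FALSE),
    reasons = list(character(), "craving", "other", character()))
  out <- classify_adherence(reports)
  expect_equal(as.character(out$adherence_status),
               c("adherent", "nonadherent_under", "nonadherent_over",
                 "adherent"))
  expect_equal(out$dose_increase_hint, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("every (days_missed, over_taking) pair maps to exactly one status", {
  grid <- tidyr::expand_grid(days_missed = 0:7, over_taking = c(TRUE, FALSE))
  grid$reasons <- list(character())
  out <- classify_adherence(grid)
  expect_false(any(is.na(out$adherence_status)))
  # exactly 2 of the 16 combinations are adherent: missed 0 or 1, no over-taking
  expect_equal(sum(out$adherence_status == "adherent"), 2L)
  expect_true(all(out$adherence_status[out$over_taking] == "nonadherent_over"))
})

test_that("over-taking takes precedence and craving/withdrawal set the dose hint", {
  both <- classify_adherence(tibble::tibble(
    days_missed = 5, over_taking = TRUE, reasons = list("withdrawal")))
  expect_equal(as.character(both$adherence_status), "nonadherent_over")
  expect_true(both$dose_increase_hint)
  # the hint never fires for an adherent report
  adh <- classify_adherence(tibble::tibble(
    days_missed = 1, over_taking = FALSE, reasons = list("forgot")))
  expect_false(adh$dose_increase_hint)
})

test_that("adherence reports are validated", {
  expect_error(classify_adherence(tibble::tibble(
    days_missed = 9, over_taking = FALSE, reasons = list(character()))),
    "0 and 7")
  expect_error(classify_adherence(tibble::tibble(
    days_missed = 2, over_taking = FALSE, reasons = list("boredom"))),
    "Unknown non-adherence reason")
  expect_error(classify_adherence(tibble::tibble(
    days_missed = 0, over_taking = FALSE, reasons = list("cost"))),
    "no missed days")
  # semicolon-delimited reason strings are accepted (CSV form)
  out <- classify_adherence(tibble::tibble(
    days_missed = 3, over_taking = FALSE, reasons = "craving;cost"))
  expect_true(out$dose_increase_hint)
  expect_equal(out$reasons[[1]], c("craving", "cost"))
})
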