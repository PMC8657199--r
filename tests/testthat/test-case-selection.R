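# Eligibility filters, duplicate detection, analysis windows, case selection.

test_that("exclusion reasons follow the fixed filter order", {
  x <- mk_set(
    mk_report("E1", reporter = "non_health_professional", age = NA, sex = NA),
    mk_report("E2", age = NA),
    mk_report("E3", sex = NA_character_),
    mk_report("E4")
  )
  res <- apply_eligibility(x, eligibility_criteria(dedup = FALSE))
  expect_equal(res$exclusions$reason[match(c("E1", "E2", "E3"),
                                           res$exclusions$report_id)],
               c("non_health_professional", "unknown_age", "unknown_sex"))
  expect_equal(res$eligible$reports$report_id, "E4")
  expect_equal(n_reports(res$eligible) + nrow(res$exclusions), n_reports(x))
})

test_that("with all filters disabled the input passes through unchanged", {
  x <- mk_set(mk_report("E1", reporter = "non_health_professional", age = NA, sex = NA))
  res <- apply_eligibility(x, eligibility_criteria(FALSE, FALSE, FALSE, dedup = FALSE))
  expect_equal(res$eligible$reports, x$reports)
  expect_equal(nrow(res$exclusions), 0L)
})

test_that("the eligible set equals the intersection of the individual filters", {
  db <- generate_database(quick_config(n = 3000, seed = 3, duplicate_rate = 0.03))
  res <- apply_eligibility(db, eligibility_criteria())
  r <- db$reports
  local_pass <- r$report_id[r$reporter_qualification == "health_professional" &
                              !is.na(r$age_years) & !is.na(r$sex)]
  dd <- deduplicate(filter_reports(db, local_pass))
  expect_setequal(res$eligible$reports$report_id, dd$kept$reports$report_id)
})

test_that("duplicates within 30 days collapse to the earliest report", {
  a <- mk_report("D2", report_date = "2015-06-06")
  b <- mk_report("D1", report_date = "2015-06-01")
  dd <- deduplicate(mk_set(a, b))
  expect_equal(dd$kept$reports$report_id, "D1")
  expect_equal(dd$removed_ids, "D2")
})

test_that("identical reports 60 days apart are kept as distinct", {
  a <- mk_report("D1", report_date = "2015-06-01")
  b <- mk_report("D2", report_date = "2015-07-31")
  dd <- deduplicate(mk_set(a, b))
  expect_equal(length(dd$removed_ids), 0L)
  expect_equal(n_reports(dd$kept), 2L)
})

test_that("deduplicate on an empty collection is a no-op and is idempotent", {
  dd <- deduplicate(empty_icsr_set())
  expect_equal(n_reports(dd$kept), 0L)
  db <- generate_database(quick_config(n = 2000, seed = 5, duplicate_rate = 0.05))
  once <- deduplicate(db)
  twice <- deduplicate(once$kept)
  expect_equal(length(twice$removed_ids), 0L)
  expect_equal(twice$kept$reports, once$kept$reports)
})

test_that("any key difference (sex, drug set, PT set) blocks deduplication", {
  a <- mk_report("D1", report_date = "2015-06-01")
  b <- mk_report("D2", report_date = "2015-06-02", sex = "female")
  c <- mk_report("D3", report_date = "2015-06-03",
                 reactions = reaction_entry(pt_name = "Renal failure"))
  expect_equal(length(deduplicate(mk_set(a, b, c))$removed_ids), 0L)
})

test_that("analysis windows are closed intervals on earliest-consistent dates", {
  crit <- eligibility_criteria(
    window_start_by_drug = c(erlotinib = "2005-09-19", afatinib = "2013-09-25"),
    window_end = "2020-12-01")
  x <- mk_set(
    mk_report("W1", report_date = "2020-12-01"),  # boundary: still in
    mk_report("W2", report_date = "2005-01-01"),  # before erlotinib authorisation
    mk_report("W3", report_date = "2016"),        # coerces to 2016-01-01
    mk_report("W4", report_date = "2020-12-02")   # one day past the end
  )
  expect_equal(in_window(x, "erlotinib", crit), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(in_window(x, "gefitinib", crit), class = "vigisignal_config_error")
})

test_that("select_cases requires role of interest, event PT and window", {
  crit <- eligibility_criteria(
    window_start_by_drug = c(erlotinib = "2005-09-19"), window_end = "2020-12-01")
  fix <- mk_set(
    mk_report("S1"),  # qualifies
    mk_report("S2", drugs = drug_entry(role = "concomitant")),     # wrong role
    mk_report("S3", reactions = reaction_entry(pt_name = "Diarrhoea")), # no event PT
    mk_report("S4", report_date = "2004-01-01"),                   # out of window
    mk_report("S5", drugs = drug_entry(role = "interacting")),     # qualifies
    mk_report("S6", drugs = drug_entry(drug_name = "afatinib")),   # other drug
    mk_report("S7", report_date = "2016",
              reactions = dplyr::bind_rows(reaction_entry(pt_name = "Diarrhoea"),
                                           reaction_entry())),     # qualifies
    mk_report("S8", sex = NA_character_),                          # eligibility is upstream: still a case here
    mk_report("S9", drugs = drug_entry(drug_name = "ERLOTINIB")),  # normalisation
    mk_report("S10", reactions = reaction_entry(pt_name = "Renal failure"))
  )
  cases <- select_cases(fix, "erlotinib", "Acute kidney injury", crit)
  expect_setequal(cases$reports$report_id, c("S1", "S5", "S7", "S8", "S9"))
  expect_error(select_cases(fix, "erlotinib", character(), crit),
               class = "vigisignal_usage_error")
})

test_that("case sets are subsets of input and monotone in the event-PT set", {
  db <- generate_database(quick_config(n = 3000, seed = 9))
  crit <- eligibility_criteria(dedup = FALSE)
  small <- select_cases(db, "erlotinib", "Acute kidney injury", crit)
  big <- select_cases(db, "erlotinib", c("Acute kidney injury", "Renal failure"), crit)
  expect_true(all(small$reports$report_id %in% big$reports$report_id))
  expect_true(all(big$reports$report_id %in% db$reports$report_id))
})
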