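# 2x2 construction, ROR estimation, and screening.

# independent oracle, written before the implementation was exercised:
# plain cross-product ratio and Woolf interval computed directly
oracle_ror <- function(a, b, c, d, z = 1.96) {
  ror <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, lo = exp(log(ror) - z * se), hi = exp(log(ror) + z * se))
}

test_that("build_contingency classifies a six-report fixture as (2,1,1,2)", {
  fix <- mk_set(
    mk_report("T1"), mk_report("T2"),                                  # exposed + event
    mk_report("T3", reactions = reaction_entry(pt_name = "Diarrhoea")),# exposed only
    mk_report("T4", drugs = drug_entry(drug_name = "cisplatin")),      # event only
    mk_report("T5", drugs = drug_entry(drug_name = "cisplatin"),
              reactions = reaction_entry(pt_name = "Diarrhoea")),      # neither
    mk_report("T6", drugs = drug_entry(drug_name = "cisplatin"),
              reactions = reaction_entry(pt_name = "Nausea"))          # neither
  )
  tab <- build_contingency(fix, "erlotinib", "Acute kidney injury")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 2))
})

test_that("a report never enters a table twice, and concomitant is unexposed", {
  fix <- mk_set(
    mk_report("U1", reactions = dplyr::bind_rows(
      reaction_entry(), reaction_entry(onset_date = NA))),   # PT listed twice
    mk_report("U2", drugs = drug_entry(role = "concomitant"))
  )
  tab <- build_contingency(fix, "erlotinib", "Acute kidney injury")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 0, 1, 0))
})

test_that("a report with two study drugs is exposed for one table, unexposed for the other", {
  fix <- mk_set(
    mk_report("V1", drugs = dplyr::bind_rows(drug_entry(),
                                             drug_entry(drug_name = "afatinib"))),
    mk_report("V2", drugs = drug_entry(drug_name = "cisplatin"),
              reactions = reaction_entry(pt_name = "Diarrhoea"))
  )
  tab_erl <- build_contingency(fix, "erlotinib", "Acute kidney injury")
  tab_osi <- build_contingency(fix, "osimertinib", "Acute kidney injury")
  expect_equal(tab_erl$a, 1)
  expect_equal(tab_osi$a, 0)
  expect_equal(tab_osi$c, 1)
})

test_that("ROR point estimates and intervals match frozen oracle values", {
  # perfect balance
  expect_equal(ror_with_ci(contingency_table(10, 10, 10, 10))$ror, 1)
  # frozen from the independent formula: ad/bc = 8.166667, CI [4.437423, 15.029995]
  r <- ror_with_ci(contingency_table(12, 288, 100, 19600))
  expect_equal(r$ror, 8.1666667, tolerance = 1e-6)
  expect_equal(r$ci_low, 4.437423, tolerance = 1e-6)
  expect_equal(r$ci_high, 15.029995, tolerance = 1e-6)
  expect_true(r$is_sdr)
  # equal reporting proportions
  expect_equal(ror_with_ci(contingency_table(5, 995, 500, 99500))$ror, 1)
})

test_that("zero cells leave the estimate undefined with no continuity correction", {
  r <- ror_with_ci(contingency_table(5, 0, 10, 1000))
  expect_true(is.na(r$ror) && is.na(r$ci_low))
  expect_false(r$is_sdr)
  expect_true(r$meets_threshold)
  expect_error(contingency_table(-1, 2, 3, 4), class = "vigisignal_validation_error")
})

test_that("estimates agree with the oracle and satisfy the algebraic invariants", {
  set.seed(202)
  for (i in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    c <- sample(1:500, 1); d <- sample(1:50000, 1)
    r <- ror_with_ci(contingency_table(a, b, c, d))
    o <- oracle_ror(a, b, c, d)
    expect_equal(r$ror, o$ror, tolerance = 1e-12)
    expect_equal(r$ci_low, o$lo, tolerance = 1e-12)
    expect_equal(r$ci_high, o$hi, tolerance = 1e-12)
    # CI brackets the point estimate
    expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
    # inversion: swapping exposed and unexposed rows inverts the OR
    expect_equal(ror_with_ci(contingency_table(c, d, a, b))$ror, 1 / o$ror,
                 tolerance = 1e-12)
    # transpose invariance: drug-within-event gives the same OR
    expect_equal(ror_with_ci(contingency_table(a, c, b, d))$ror, o$ror,
                 tolerance = 1e-12)
  }
})

test_that("scaling all counts up narrows the interval around a fixed estimate", {
  base <- ror_with_ci(contingency_table(8, 200, 100, 10000))
  scaled <- ror_with_ci(contingency_table(32, 800, 400, 40000))
  expect_equal(scaled$ror, base$ror)
  expect_lt(scaled$ci_high / scaled$ci_low, base$ci_high / base$ci_low)
})

test_that("screening suppresses pairs below the case threshold", {
  # 4 exposed+event reports for afatinib, 5 for erlotinib, shared comparator
  reports <- c(
    lapply(1:4, function(i) mk_report(paste0("A", i),
                                      drugs = drug_entry(drug_name = "afatinib"))),
    lapply(1:5, function(i) mk_report(paste0("B", i))),
    lapply(1:20, function(i) mk_report(paste0("C", i),
                                       drugs = drug_entry(drug_name = "cisplatin"),
                                       reactions = reaction_entry(pt_name = "Diarrhoea"))),
    lapply(1:3, function(i) mk_report(paste0("D", i),
                                      drugs = drug_entry(drug_name = "cisplatin")))
  )
  fix <- do.call(mk_set, reports)
  res <- screen(fix, c("afatinib", "erlotinib"), "Acute kidney injury",
                min_cases = 5)
  expect_equal(res$signals$drug, "erlotinib")
  expect_equal(res$signals$a, 5)
  expect_equal(res$suppressed$drug, "afatinib")
  expect_equal(res$suppressed$a, 4)
  # the suppressed pair has no estimate anywhere in the signal table
  expect_false("afatinib" %in% res$signals$drug)
})

test_that("screening an empty drug list yields an empty result", {
  fix <- mk_set(mk_report("A1"))
  res <- screen(fix, character(), "Acute kidney injury")
  expect_equal(nrow(res$signals), 0L)
  expect_equal(nrow(res$suppressed), 0L)
})

test_that("signals are ordered by drug then descending case count", {
  db <- generate_database(quick_config(
    n = 8000, seed = 13,
    planted_or = tibble::tibble(drug = "erlotinib", pt = "Acute kidney injury",
                                theta = 10)))
  res <- screen(db, c("erlotinib", "cetuximab"),
                c("Acute kidney injury", "Renal failure", "Renal impairment"),
                min_cases = 1)
  for (dg in unique(res$signals$drug)) {
    a <- res$signals$a[res$signals$drug == dg]
    expect_true(all(diff(a) <= 0))
  }
})
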