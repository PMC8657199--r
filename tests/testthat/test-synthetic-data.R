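# Synthetic database generator: reproducibility, calibration, bookkeeping.

test_that("the same config yields an identical database, without touching the caller's RNG", {
  cfg <- quick_config(n = 1500, seed = 123, duplicate_rate = 0.03)
  set.seed(1); before <- runif(1)
  db1 <- generate_database(cfg)
  db2 <- generate_database(cfg)
  expect_identical(serialize(db1, NULL), serialize(db2, NULL))
  set.seed(1)
  expect_identical(runif(1), before)
  # a different seed changes the draw
  db3 <- generate_database(quick_config(n = 1500, seed = 124, duplicate_rate = 0.03))
  expect_false(identical(db1$reports, db3$reports))
})

test_that("generated collections always satisfy the ICSR invariants", {
  db <- generate_database(quick_config(n = 4000, seed = 8, duplicate_rate = 0.05,
                                       p_missing_age = 0.2, p_missing_sex = 0.2,
                                       p_partial_date = 0.4))
  expect_silent(validate_icsr_set(db))
  # every report has >= 1 drug and >= 1 reaction by construction
  expect_equal(length(setdiff(db$reports$report_id, db$drugs$report_id)), 0L)
  expect_equal(length(setdiff(db$reports$report_id, db$reactions$report_id)), 0L)
})

test_that("planted truth defaults to the null and returns configured multipliers", {
  cfg <- quick_config(planted_or = tibble::tibble(
    drug = c("erlotinib", "afatinib"),
    pt = c("Thrombotic microangiopathy", "Acute kidney injury"),
    theta = c(4.94, 0.5)))
  expect_equal(planted_truth(cfg, "erlotinib", "Thrombotic microangiopathy"), 4.94)
  expect_equal(planted_truth(cfg, "afatinib", "Acute kidney injury"), 0.5)
  expect_equal(planted_truth(cfg, "gefitinib", "Renal failure"), 1)
  expect_error(synth_config(planted_or = tibble::tibble(
    drug = "erlotinib", pt = "Acute kidney injury", theta = -1)),
    class = "vigisignal_config_error")
})

test_that("empirical exposure and event frequencies match their configured probabilities", {
  n <- 100000
  db <- generate_database(quick_config(n = n, seed = 17, duplicate_rate = 0))
  cfg <- quick_config(n = n, seed = 17, duplicate_rate = 0)
  # exposure marginals, all six drugs (any role)
  for (i in seq_len(nrow(cfg$drugs))) {
    p <- cfg$drugs$exposure_prob[i]
    obs <- length(unique(db$drugs$report_id[db$drugs$drug_name == cfg$drugs$name[i]])) / n
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
  # baseline event frequency for the two commonest renal PTs (no planted OR)
  for (pt in c("Acute kidney injury", "Renal failure")) {
    p <- cfg$event_pts$baseline_prob[cfg$event_pts$pt_name == pt]
    obs <- length(unique(db$reactions$report_id[db$reactions$pt_name == pt])) / n
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("planted duplicates are found by deduplication at the expected rate", {
  n <- 10000
  # clone counts are binomial(n, 0.05): check the rate on the mean of
  # several independent seeds rather than a single draw
  counts <- vapply(1:10, function(s) {
    nrow(attr(generate_database(quick_config(n = n, seed = s,
                                             duplicate_rate = 0.05)),
              "synth_truth")$duplicates)
  }, numeric(1))
  expect_lt(abs(mean(counts) - n * 0.05),
            3 * sqrt(n * 0.05 * 0.95 / length(counts)))
  # on one database, deduplication recovers the planted clones exactly
  db <- generate_database(quick_config(n = n, seed = 29, duplicate_rate = 0.05))
  truth <- attr(db, "synth_truth")$duplicates
  dd <- deduplicate(db)
  expect_setequal(dd$removed_ids, truth$duplicate)
})

test_that("a planted odds ratio is recovered by the full pipeline across replicates", {
  # theta in {0.5, 1, 2, 5}, sized so the expected case count is ~500
  # (>= 200): SE of the 25-replicate mean is then well under the 2% band
  crit <- eligibility_criteria(FALSE, FALSE, FALSE, dedup = FALSE)
  for (theta in c(0.5, 1, 2, 5)) {
    p0 <- 0.02
    p1 <- plogis(qlogis(p0) + log(theta))
    n_exp <- ceiling(500 / p1)
    n <- n_exp * 11
    rors <- vapply(1:25, function(rep) {
      cfg <- synth_config(
        n_reports = n, seed = 5000 + 100 * theta + rep,
        drugs = tibble::tibble(name = "drug x", exposure_prob = n_exp / n,
                               authorisation_date = "2005-01-01"),
        event_pts = tibble::tibble(pt_name = "Acute kidney injury",
                                   baseline_prob = p0),
        background_pts = tibble::tibble(pt_name = "Diarrhoea", baseline_prob = 0.4),
        planted_or = tibble::tibble(drug = "drug x", pt = "Acute kidney injury",
                                    theta = theta),
        role_probs = c(suspected = 0.95, interacting = 0.05, concomitant = 0),
        p_missing_age = 0, p_missing_sex = 0, p_partial_date = 0,
        duplicate_rate = 0)
      db <- generate_database(cfg)
      screen(db, "drug x", "Acute kidney injury", crit, min_cases = 1)$signals$ror
    }, numeric(1))
    expect_lt(abs(mean(rors) - theta) / theta, 0.02)
  }
})
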