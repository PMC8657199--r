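# End-to-end study runs from a config file.

# set up a self-contained copy of the demo study in a temp dir, scaled down
demo_dir <- function(n_reports = 15000, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  file.copy(renal_dict_path(), file.path(dir, "renal_hierarchy_synthetic.csv"))
  raw <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                     package = "vigisignal"))
  raw$synth$n_reports <- n_reports
  yaml::write_yaml(raw, file.path(dir, "config.yaml"))
  dir
}

test_that("generate -> screen runs end to end and is byte-identical on rerun", {
  dir <- demo_dir()
  cfg <- study_config(file.path(dir, "config.yaml"))
  suppressMessages(run_generate(cfg))
  expect_true(file.exists(cfg$reports))
  out1 <- suppressMessages(run_screen(cfg))
  expect_true(all(file.exists(out1$paths)))
  sig <- readr::read_csv(out1$paths["signals"], show_col_types = FALSE)
  expect_true(all(sig$a >= cfg$min_cases))
  expect_true(all(sig$ci_low <= sig$ror & sig$ror <= sig$ci_high, na.rm = TRUE))
  # every screened-or-suppressed pair is accounted for, none twice
  sup <- readr::read_csv(out1$paths["suppressed"], show_col_types = FALSE)
  expect_equal(anyDuplicated(rbind(sig[, c("drug", "pt")], sup[, c("drug", "pt")])), 0L)
  # rerun determinism
  bytes1 <- readBin(out1$paths["signals"], "raw", file.size(out1$paths["signals"]))
  out2 <- suppressMessages(run_screen(cfg))
  bytes2 <- readBin(out2$paths["signals"], "raw", file.size(out2$paths["signals"]))
  expect_identical(bytes1, bytes2)
})

test_that("stage counts are conserved: read = eligible + excluded", {
  dir <- demo_dir(n_reports = 5000)
  cfg <- study_config(file.path(dir, "config.yaml"))
  suppressMessages(run_generate(cfg))
  msgs <- capture.output(out <- run_screen(cfg), type = "message")
  read_n <- as.integer(sub(".*read (\\d+) reports.*", "\\1", grep("read \\d+ reports", msgs, value = TRUE)))
  elig_n <- as.integer(sub(".*\\] (\\d+) eligible.*", "\\1", grep("eligible of", msgs, value = TRUE)))
  excl <- readr::read_csv(out$paths["exclusions"], show_col_types = FALSE)
  expect_equal(elig_n + nrow(excl), read_n)
})

test_that("an unknown HLT aborts naming the term", {
  dir <- demo_dir(n_reports = 2000)
  path <- file.path(dir, "config.yaml")
  raw <- yaml::read_yaml(path)
  raw$hlts <- c(raw$hlts, "cardiac arrhythmias NEC")
  yaml::write_yaml(raw, path)
  cfg <- study_config(path)
  suppressMessages(run_generate(cfg))
  expect_error(suppressMessages(run_screen(cfg)), "cardiac arrhythmias NEC",
               class = "vigisignal_dict_error")
})

test_that("describe emits cohort blocks whose percentages sum to their denominators", {
  dir <- demo_dir()
  cfg <- study_config(file.path(dir, "config.yaml"))
  suppressMessages(run_generate(cfg))
  out <- suppressMessages(run_describe(cfg))
  expect_true(all(file.exists(out$paths)))
  cohort <- out$cohort
  for (b in c("sex", "seriousness", "outcome", "drug_mentions")) {
    block <- cohort[cohort$block == b, ]
    covered <- sum(block$n) / block$denominator[1]
    expect_equal(sum(block$pct), 100 * covered, tolerance = 0.1 * max(nrow(block), 1))
  }
  # reporting-year percentages are per drug
  for (dg in unique(out$years$drug)) {
    expect_equal(sum(out$years$pct[out$years$drug == dg]), 100, tolerance = 0.1 *
                   sum(out$years$drug == dg))
  }
  # co-reported counts never exceed their index-case denominators
  expect_true(all(out$co_reported$n <= out$co_reported$n_index_cases))
})

test_that("an empty cohort produces an explicit empty report, not a crash", {
  dir <- demo_dir(n_reports = 2000)
  path <- file.path(dir, "config.yaml")
  raw <- yaml::read_yaml(path)
  # restrict to an HLT whose PTs the generator essentially never emits
  raw$hlts <- "renal hypertension and related conditions"
  raw$synth$n_reports <- 50
  yaml::write_yaml(raw, path)
  cfg <- study_config(path)
  suppressMessages(run_generate(cfg))
  expect_warning(out <- suppressMessages(run_describe(cfg)),
                 class = "vigisignal_empty_cohort")
  expect_true(file.exists(out$paths[["cohort"]]))
  expect_equal(out$cohort$n[out$cohort$value == "n_cases"], 0)
})

test_that("tto run exports per-pair summaries and a valid ECDF", {
  dir <- demo_dir()
  cfg <- study_config(file.path(dir, "config.yaml"))
  suppressMessages(run_generate(cfg))
  # unmodelled pairs can draw onsets before start: those TTOs are
  # discarded with a warning, which is expected on this data
  out <- suppressWarnings(suppressMessages(run_tto(cfg)))
  expect_true(all(file.exists(out$paths)))
  s <- out$summary
  ok <- !is.na(s$median_days)
  expect_true(all(s$q1_days[ok] <= s$median_days[ok] &
                    s$median_days[ok] <= s$q3_days[ok]))
  # each pair's ECDF is non-decreasing and ends at 1
  for (key in unique(paste(out$ecdf$drug, out$ecdf$pt))) {
    e <- out$ecdf[paste(out$ecdf$drug, out$ecdf$pt) == key, ]
    expect_true(all(diff(e$cum_fraction) > 0))
    expect_equal(e$cum_fraction[nrow(e)], 1)
  }
})

test_that("a planted log-normal onset model is recovered from the pipeline's cases", {
  # dedicated high-incidence config so ~5000 cases carry a modelled TTO
  dir <- withr::local_tempdir()
  db <- generate_database(synth_config(
    n_reports = 50000, seed = 61,
    drugs = tibble::tibble(name = "drug x", exposure_prob = 0.5,
                           authorisation_date = "2005-01-01"),
    event_pts = tibble::tibble(pt_name = "Acute kidney injury", baseline_prob = 0.2),
    background_pts = tibble::tibble(pt_name = "Diarrhoea", baseline_prob = 0.3),
    tto_model = tibble::tibble(drug = "drug x", pt = "Acute kidney injury",
                               median_days = 24.5, sigma = 0.5),
    role_probs = c(suspected = 1, interacting = 0, concomitant = 0),
    p_missing_age = 0, p_missing_sex = 0, p_partial_date = 0, duplicate_rate = 0))
  crit <- eligibility_criteria(FALSE, FALSE, FALSE, dedup = FALSE)
  cases <- select_cases(db, "drug x", "Acute kidney injury", crit)
  expect_gt(n_reports(cases), 4000)
  tto <- suppressWarnings(compute_tto(cases, "drug x", "Acute kidney injury"))
  s <- tto_summary(tto$tto_days)
  expect_lt(abs(s$median_days - 24.5) / 24.5, 0.05)
})
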