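# Study configuration and deterministic end-to-end runs.
#
# One YAML file describes a whole study: file paths, drugs of interest
# with their marketing-authorisation dates, the selected HLT names,
# eligibility flags, the screening threshold, and (optionally) a `synth`
# block parameterising the synthetic generator. The run_* functions are
# thin deterministic pipelines over the package's building blocks; they
# log stage counts and write plot-ready CSV exports. A command-line
# wrapper over these functions ships in `inst/cli/vigisignal.R`.

#' Load and validate a study configuration
#'
#' @param path YAML configuration file, or a named list with the same
#'   structure. Relative paths inside the file are resolved against the
#'   file's directory. Keys: `reports`, `reports_format`
#'   (`jsonl`/`delimited`), `dictionary`, `output_dir`, `drugs` (list of
#'   `name` + `authorisation_date`), `window_end`, `hlts`, `eligibility`
#'   (flags for [eligibility_criteria()]), `min_cases`, `z`, `era_cut`,
#'   `co_report_index_pts`, `co_report_k`, `seed`, and optional `synth`
#'   (arguments of [synth_config()]).
#' @return an object of class `study_config`.
#' @export
study_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) {
      vs_abort(paste0("no such config file: ", path), class = "vigisignal_io_error")
    }
    raw <- yaml::read_yaml(path)
    base_dir <- dirname(normalizePath(path))
  } else {
    raw <- path
    base_dir <- raw$base_dir %||% getwd()
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  drugs <- dplyr::bind_rows(lapply(raw$drugs, tibble::as_tibble))
  if (!nrow(drugs) || !all(c("name", "authorisation_date") %in% names(drugs))) {
    vs_abort("config must list drugs with name and authorisation_date",
             class = "vigisignal_config_error")
  }
  drugs$name <- normalise_drug_name(drugs$name)
  elig <- raw$eligibility %||% list()
  criteria <- eligibility_criteria(
    require_health_professional = elig$require_health_professional %||% TRUE,
    require_known_age = elig$require_known_age %||% TRUE,
    require_known_sex = elig$require_known_sex %||% TRUE,
    dedup = elig$dedup %||% TRUE,
    dedup_window_days = elig$dedup_window_days %||% 30,
    window_start_by_drug = stats::setNames(as.character(drugs$authorisation_date),
                                           drugs$name),
    window_end = raw$window_end %||% NULL
  )
  cfg <- structure(list(
    reports = resolve(raw$reports),
    reports_format = raw$reports_format %||% "jsonl",
    dictionary = resolve(raw$dictionary),
    output_dir = resolve(raw$output_dir %||% "."),
    drugs = drugs,
    hlts = as.character(raw$hlts %||% character()),
    criteria = criteria,
    min_cases = raw$min_cases %||% 5,
    z = raw$z %||% 1.96,
    era_cut = raw$era_cut %||% 2010,
    co_report_index_pts = as.character(raw$co_report_index_pts %||%
                                         c("Acute kidney injury", "Renal failure")),
    co_report_k = raw$co_report_k %||% 5,
    seed = raw$seed %||% 1,
    synth = raw$synth %||% NULL
  ), class = "study_config")
  if (cfg$min_cases < 1) {
    vs_abort("min_cases must be >= 1", class = "vigisignal_config_error")
  }
  cfg
}

run_log <- function(...) message("[vigisignal] ", sprintf(...))

ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  cfg$output_dir
}

# shared pipeline front end: read -> dictionary expand -> eligibility
load_and_filter <- function(cfg) {
  x <- read_reports(cfg$reports, format = cfg$reports_format)
  run_log("read %d reports from %s", n_reports(x), cfg$reports)
  dict <- load_dictionary(cfg$dictionary)
  event_pts <- pts_for_hlts(dict, cfg$hlts)
  run_log("%d selected HLT(s) expand to %d event PT(s)", length(cfg$hlts),
          length(event_pts))
  res <- apply_eligibility(x, cfg$criteria)
  for (i in seq_len(nrow(res$counts))) {
    run_log("excluded %d report(s): %s", res$counts$n[i], res$counts$reason[i])
  }
  run_log("%d eligible of %d read", n_reports(res$eligible), n_reports(x))
  stopifnot(n_reports(res$eligible) + nrow(res$exclusions) == n_reports(x))
  list(eligible = res$eligible, exclusions = res$exclusions, event_pts = event_pts)
}

#' Generate a synthetic database described by the config's `synth` block
#'
#' @param cfg a [study_config()] whose `synth` entry parameterises
#'   [synth_config()]; the result is written to the config's `reports`
#'   path in `reports_format`.
#' @return the output path, invisibly.
#' @export
run_generate <- function(cfg) {
  if (is.null(cfg$synth)) {
    vs_abort("config has no synth block", class = "vigisignal_config_error")
  }
  args <- cfg$synth
  for (fld in c("drugs", "event_pts", "background_pts", "planted_or", "tto_model")) {
    if (!is.null(args[[fld]]) && !is.data.frame(args[[fld]])) {
      args[[fld]] <- dplyr::bind_rows(lapply(args[[fld]], tibble::as_tibble))
    }
  }
  for (fld in c("role_probs", "reporter_mix", "sex_probs", "seriousness_probs",
                "outcome_probs", "countries")) {
    if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
  }
  if (is.null(args$seed)) args$seed <- cfg$seed
  if (!is.null(args$date_range)) args$date_range <- as.character(args$date_range)
  scfg <- do.call(synth_config, args)
  db <- generate_database(scfg)
  write_reports(db, cfg$reports, format = cfg$reports_format)
  run_log("generated %d reports -> %s", n_reports(db), cfg$reports)
  invisible(cfg$reports)
}

#' Run the disproportionality screen end to end
#'
#' Deterministic pipeline: read reports, expand HLTs to the event-PT set,
#' apply eligibility, apply each drug's analysis window, screen every
#' (drug, PT) pair, and export `signals.csv` (the machine-readable twin
#' of a forest plot, with `log_ror`, `log_ci_low`, `log_ci_high` columns
#' for log-scale plotting), `suppressed.csv` (below-threshold pairs with
#' their case counts) and `exclusion_log.csv`.
#'
#' @param cfg a [study_config()].
#' @return list with `signals`, `suppressed`, `paths`, invisibly.
#' @export
run_screen <- function(cfg) {
  dir <- ensure_outdir(cfg)
  st <- load_and_filter(cfg)
  res <- screen(st$eligible, cfg$drugs$name, st$event_pts, cfg$criteria,
                min_cases = cfg$min_cases, z = cfg$z)
  run_log("screened %d pair(s) at a >= %d; %d suppressed", nrow(res$signals),
          cfg$min_cases, nrow(res$suppressed))
  sig <- res$signals
  sig$log_ror <- log(sig$ror)
  sig$log_ci_low <- log(sig$ci_low)
  sig$log_ci_high <- log(sig$ci_high)
  paths <- c(signals = file.path(dir, "signals.csv"),
             suppressed = file.path(dir, "suppressed.csv"),
             exclusions = file.path(dir, "exclusion_log.csv"))
  readr::write_csv(sig, paths["signals"], na = "", progress = FALSE)
  readr::write_csv(res$suppressed, paths["suppressed"], na = "", progress = FALSE)
  readr::write_csv(st$exclusions, paths["exclusions"], na = "", progress = FALSE)
  invisible(list(signals = sig, suppressed = res$suppressed, paths = paths))
}

#' Run the descriptive tables end to end
#'
#' Emits the cohort overview (`cohort_summary.csv`, long block format with
#' explicit denominators), per-drug reporting years
#' (`reporting_years.csv`) and co-reported ADR tables
#' (`co_reported.csv`). With zero eligible cases an empty-cohort marker
#' is written and the function returns (does not crash) with a warning.
#'
#' @param cfg a [study_config()].
#' @return list with the tables and `paths`, invisibly.
#' @export
run_describe <- function(cfg) {
  dir <- ensure_outdir(cfg)
  st <- load_and_filter(cfg)
  case_ids <- character()
  for (dg in cfg$drugs$name) {
    cs <- select_cases(st$eligible, dg, st$event_pts, cfg$criteria)
    case_ids <- union(case_ids, cs$reports$report_id)
  }
  cases <- filter_reports(st$eligible, case_ids)
  run_log("%d case(s) across %d drug(s)", n_reports(cases), nrow(cfg$drugs))
  paths <- c(cohort = file.path(dir, "cohort_summary.csv"),
             years = file.path(dir, "reporting_years.csv"),
             co = file.path(dir, "co_reported.csv"))
  if (!n_reports(cases)) {
    vs_warn("no eligible cases: writing empty-cohort report",
            class = "vigisignal_empty_cohort")
    empty <- tibble::tibble(block = "cohort", value = "n_cases", n = 0, pct = NA_real_,
                            denominator = 0)
    readr::write_csv(empty, paths["cohort"], na = "", progress = FALSE)
    return(invisible(list(cohort = empty, years = NULL, co_reported = NULL,
                          paths = paths["cohort"])))
  }
  cs <- cohort_summary(cases, cfg$drugs$name, st$event_pts, k = 10)
  blocks <- list(sex = cs$sex, seriousness = cs$seriousness, outcome = cs$outcome,
                 countries = cs$countries, drug_mentions = cs$drug_mentions,
                 top_events = cs$top_events)
  cohort_tbl <- dplyr::bind_rows(lapply(names(blocks), function(b) {
    tibble::tibble(block = b, value = blocks[[b]]$value, n = blocks[[b]]$n,
                   pct = blocks[[b]]$pct, denominator = blocks[[b]]$denominator)
  }))
  header <- tibble::tibble(
    block = "cohort",
    value = c("n_cases", "n_drug_mentions", "n_event_mentions",
              "age_median", "age_q1", "age_q3"),
    n = c(cs$n_cases, cs$n_drug_mentions, cs$n_event_mentions,
          cs$age$median, cs$age$q1, cs$age$q3),
    pct = NA_real_, denominator = NA_real_)
  cohort_tbl <- dplyr::bind_rows(header, cohort_tbl)

  years <- dplyr::bind_rows(lapply(cfg$drugs$name, function(dg) {
    yr <- reporting_years(cases, dg, era_cut = cfg$era_cut,
                          roles = cfg$criteria$drug_roles_of_interest)
    if (nrow(yr)) tibble::tibble(drug = dg, yr) else NULL
  }))
  co <- dplyr::bind_rows(lapply(cfg$drugs$name, function(dg) {
    dplyr::bind_rows(lapply(cfg$co_report_index_pts, function(pt) {
      tb <- co_reported(cases, dg, pt, k = cfg$co_report_k, event_pts = st$event_pts,
                        roles = cfg$criteria$drug_roles_of_interest)
      if (nrow(tb)) tibble::tibble(drug = dg, index_pt = pt,
                                   n_index_cases = attr(tb, "n_index_cases"), tb)
      else NULL
    }))
  }))
  readr::write_csv(cohort_tbl, paths["cohort"], na = "", progress = FALSE)
  readr::write_csv(years, paths["years"], na = "", progress = FALSE)
  readr::write_csv(co, paths["co"], na = "", progress = FALSE)
  invisible(list(cohort = cohort_tbl, years = years, co_reported = co, paths = paths))
}

#' Run the time-to-onset analysis end to end
#'
#' For every (drug, event PT) pair with at least one case, computes times
#' to onset, writes the per-pair summary (`tto_summary.csv`: n available,
#' n missing, median, quartiles) and the ECDF export (`tto_ecdf.csv`:
#' `drug`, `pt`, `days`, `cum_fraction`), the plot-ready twin of a
#' cumulative-distribution figure. Pairs with no day-complete dates get a
#' summary row but no ECDF rows (with a warning when nothing at all is
#' available).
#'
#' @param cfg a [study_config()].
#' @return list with `summary`, `ecdf`, `paths`, invisibly.
#' @export
run_tto <- function(cfg) {
  dir <- ensure_outdir(cfg)
  st <- load_and_filter(cfg)
  summaries <- list()
  ecdfs <- list()
  for (dg in cfg$drugs$name) {
    for (pt in st$event_pts) {
      cases <- select_cases(st$eligible, dg, pt, cfg$criteria)
      if (!n_reports(cases)) next
      tto <- compute_tto(cases, dg, pt, roles = cfg$criteria$drug_roles_of_interest)
      ts <- tto_summary(tto$tto_days)
      summaries[[paste(dg, pt)]] <- tibble::tibble(
        drug = dg, pt = pt, n_available = ts$n_available, n_missing = ts$n_missing,
        median_days = ts$median_days, q1_days = ts$q1_days, q3_days = ts$q3_days)
      if (ts$n_available > 0) {
        ecdfs[[paste(dg, pt)]] <- tibble::tibble(drug = dg, pt = pt, ts$ecdf)
      }
    }
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  ecdf_tbl <- dplyr::bind_rows(ecdfs)
  if (!nrow(ecdf_tbl)) {
    vs_warn("no day-complete date pairs: ECDF export is empty",
            class = "vigisignal_no_tto")
    ecdf_tbl <- tibble::tibble(drug = character(), pt = character(),
                               days = numeric(), cum_fraction = numeric())
  }
  paths <- c(summary = file.path(dir, "tto_summary.csv"),
             ecdf = file.path(dir, "tto_ecdf.csv"))
  readr::write_csv(summary_tbl, paths["summary"], na = "", progress = FALSE)
  readr::write_csv(ecdf_tbl, paths["ecdf"], na = "", progress = FALSE)
  invisible(list(summary = summary_tbl, ecdf = ecdf_tbl, paths = paths))
}
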