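# Synthetic ICSR database generator.
#
# Emulates the statistical structure of a large spontaneous-reporting
# database so that every pipeline stage is testable without access to a
# restricted source: report-level records with several drugs and several
# reaction PTs, a reporter-type mix, missing demographics, partial dates,
# exact-clone duplicates with shifted dates, and — the part that matters
# for validation — configurable true reporting odds ratios between drug
# exposure and event reporting.
#
# Event model: per report, exposure to each drug is drawn independently;
# a drug mention receives a reporter-assigned role. For each PT with
# baseline reporting probability p0, a report's probability satisfies
#   odds(p) = odds(p0) * prod(theta[drug, pt])
# over the drugs the report carries with a suspected/interacting role and
# a planted theta — multiplicative odds, the simplest composable choice.
# Every report is guaranteed >= 1 drug (a comparator drug is added when no
# study drug was drawn) and >= 1 reaction (a filler PT is added when no
# PT was drawn), so generated collections always satisfy ICSR invariants.

.default_drugs <- function() {
  tibble::tibble(
    name = c("erlotinib", "gefitinib", "afatinib", "osimertinib",
             "cetuximab", "panitumumab"),
    exposure_prob = c(0.020, 0.008, 0.012, 0.006, 0.018, 0.008),
    authorisation_date = c("2005-09-19", "2009-06-24", "2013-09-25",
                           "2016-02-02", "2004-06-29", "2007-12-03")
  )
}

.default_event_pts <- function() {
  tibble::tibble(
    pt_name = c("Acute kidney injury", "Renal failure", "Renal impairment",
                "Renal disorder", "Chronic kidney disease", "Prerenal failure",
                "Thrombotic microangiopathy", "Haemolytic uraemic syndrome",
                "Nephrotic syndrome", "Renal tubular necrosis"),
    baseline_prob = c(0.0045, 0.0025, 0.0012, 0.0004, 0.0002, 0.00015,
                      0.00015, 0.0001, 0.00014, 0.0001)
  )
}

.default_background_pts <- function() {
  tibble::tibble(
    pt_name = c("Diarrhoea", "Nausea", "Vomiting", "Rash", "Dehydration",
                "Fatigue", "Dyspnoea", "Anaemia", "Decreased appetite",
                "Pyrexia", "Asthenia", "Cough", "Constipation", "Headache",
                "Pruritus", "Oedema peripheral", "Pain", "Dizziness",
                "Malignant neoplasm progression", "Drug ineffective",
                "Paronychia", "Stomatitis", "Dry skin",
                "Interstitial lung disease", "Thrombocytopenia",
                "Neutropenia", "Hepatic function abnormal", "Insomnia"),
    baseline_prob = c(0.10, 0.07, 0.06, 0.08, 0.03, 0.08, 0.06, 0.05, 0.05,
                      0.06, 0.06, 0.04, 0.04, 0.05, 0.04, 0.04, 0.05, 0.04,
                      0.08, 0.09, 0.03, 0.05, 0.03, 0.03, 0.03, 0.04, 0.03,
                      0.03)
  )
}

#' Configuration of a synthetic ICSR database
#'
#' All probabilities are per report. Defaults emulate a large oncology
#' pharmacovigilance slice: six anti-EGFR drugs with their real
#' marketing-authorisation dates, renal event PTs at low baseline
#' reporting rates, common background PTs, a health-professional-dominated
#' reporter mix, mostly-complete demographics and a small exact-duplicate
#' rate. No association is planted by default (all theta = 1).
#'
#' @param n_reports number of primary reports (duplicates come on top).
#' @param drugs tibble `name`, `exposure_prob`, `authorisation_date`.
#' @param comparator_drugs names of non-study drugs used to guarantee
#'   every report carries a drug.
#' @param event_pts,background_pts tibbles `pt_name`, `baseline_prob`.
#' @param planted_or tibble `drug`, `pt`, `theta` of true odds-ratio
#'   multipliers (`theta > 0`); absent pairs default to 1.
#' @param tto_model tibble `drug`, `pt`, `median_days`, `sigma`:
#'   log-normal time-to-onset (in days) planted for exposed cases of the
#'   pair; `median_days` is the distribution median, `sigma` the log-scale
#'   standard deviation.
#' @param role_probs probabilities of the suspected/interacting/concomitant
#'   roles for a drug mention.
#' @param reporter_mix probabilities over reporter qualifications.
#' @param sex_probs,seriousness_probs,outcome_probs categorical
#'   distributions for the corresponding report fields.
#' @param age_mean,age_sd normal age model (years), truncated to
#'   \[18, 100\].
#' @param countries named probability vector of ISO alpha-2 codes.
#' @param p_missing_age,p_missing_sex missingness probabilities.
#' @param p_partial_date probability a drug start / reaction onset date is
#'   degraded to month or year precision (report dates are degraded at a
#'   third of this rate).
#' @param duplicate_rate probability a report is cloned with a report date
#'   shifted by up to 14 days and a fresh report id.
#' @param date_range character vector `c(start, end)` of report dates.
#' @param filler_pt PT used when a report draws no reaction; `NULL` (the
#'   default) samples one uniformly from the background PTs, keeping
#'   reaction profiles diverse across reports.
#' @param seed integer seed; generation is fully reproducible from it and
#'   does not disturb the caller's RNG state.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_reports = 20000,
                         drugs = .default_drugs(),
                         comparator_drugs = c("cisplatin", "carboplatin",
                                              "pembrolizumab", "docetaxel",
                                              "gemcitabine", "paclitaxel",
                                              "bevacizumab", "capecitabine",
                                              "oxaliplatin", "irinotecan",
                                              "fluorouracil", "nivolumab",
                                              "pemetrexed", "vinorelbine",
                                              "etoposide", "crizotinib",
                                              "trastuzumab", "ramucirumab",
                                              "atezolizumab", "durvalumab"),
                         event_pts = .default_event_pts(),
                         background_pts = .default_background_pts(),
                         planted_or = NULL,
                         tto_model = NULL,
                         role_probs = c(suspected = 0.90, interacting = 0.05,
                                        concomitant = 0.05),
                         reporter_mix = c(health_professional = 0.85,
                                          non_health_professional = 0.10,
                                          unknown = 0.05),
                         sex_probs = c(female = 0.406, male = 0.594),
                         seriousness_probs = c(serious = 0.961, not_serious = 0.031,
                                               unknown = 0.008),
                         outcome_probs = c(death = 0.083, not_recovered = 0.117,
                                           recovered_with_sequelae = 0.015,
                                           recovered = 0.424, unknown = 0.361),
                         age_mean = 66, age_sd = 12,
                         countries = c(US = 0.22, JP = 0.14, DE = 0.10, FR = 0.09,
                                       GB = 0.08, IT = 0.07, ES = 0.06, KR = 0.06,
                                       CA = 0.05, AU = 0.05, NL = 0.04, BE = 0.04),
                         p_missing_age = 0.08, p_missing_sex = 0.05,
                         p_partial_date = 0.15,
                         duplicate_rate = 0.02,
                         date_range = c("2005-01-01", "2020-12-01"),
                         filler_pt = NULL,
                         seed = 1) {
  planted_or <- if (is.null(planted_or)) {
    tibble::tibble(drug = character(), pt = character(), theta = numeric())
  } else tibble::as_tibble(planted_or)
  tto_model <- if (is.null(tto_model)) {
    tibble::tibble(drug = character(), pt = character(),
                   median_days = numeric(), sigma = numeric())
  } else tibble::as_tibble(tto_model)
  cfg <- structure(list(
    n_reports = as.integer(n_reports), drugs = tibble::as_tibble(drugs),
    comparator_drugs = normalise_drug_name(comparator_drugs),
    event_pts = tibble::as_tibble(event_pts),
    background_pts = tibble::as_tibble(background_pts),
    planted_or = planted_or, tto_model = tto_model,
    role_probs = role_probs, reporter_mix = reporter_mix,
    sex_probs = sex_probs, seriousness_probs = seriousness_probs,
    outcome_probs = outcome_probs, age_mean = age_mean, age_sd = age_sd,
    countries = countries, p_missing_age = p_missing_age,
    p_missing_sex = p_missing_sex, p_partial_date = p_partial_date,
    duplicate_rate = duplicate_rate, date_range = date_range,
    filler_pt = filler_pt, seed = as.integer(seed)
  ), class = "synth_config")
  cfg$drugs$name <- normalise_drug_name(cfg$drugs$name)
  cfg$planted_or$drug <- normalise_drug_name(cfg$planted_or$drug)
  cfg$tto_model$drug <- normalise_drug_name(cfg$tto_model$drug)
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$drugs$exposure_prob, cfg$event_pts$baseline_prob,
             cfg$background_pts$baseline_prob, cfg$role_probs, cfg$reporter_mix,
             cfg$sex_probs, cfg$seriousness_probs, cfg$outcome_probs,
             cfg$countries, cfg$p_missing_age, cfg$p_missing_sex,
             cfg$p_partial_date, cfg$duplicate_rate)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    vs_abort("all probabilities must lie in [0, 1]", class = "vigisignal_config_error")
  }
  if (cfg$n_reports < 1) {
    vs_abort("n_reports must be >= 1", class = "vigisignal_config_error")
  }
  if (nrow(cfg$planted_or) && any(cfg$planted_or$theta <= 0)) {
    vs_abort("planted odds-ratio multipliers theta must be > 0",
             class = "vigisignal_config_error")
  }
  all_pts <- c(cfg$event_pts$pt_name, cfg$background_pts$pt_name)
  stray <- setdiff(cfg$planted_or$pt, all_pts)
  if (length(stray)) {
    vs_abort(paste0("planted_or references unknown PT(s): ", oxford(stray)),
             class = "vigisignal_config_error")
  }
  stray <- setdiff(cfg$planted_or$drug, cfg$drugs$name)
  if (length(stray)) {
    vs_abort(paste0("planted_or references unknown drug(s): ", oxford(stray)),
             class = "vigisignal_config_error")
  }
  if (!all(is_complete_date(cfg$date_range)) ||
      earliest_date(cfg$date_range[1]) > earliest_date(cfg$date_range[2])) {
    vs_abort("date_range must be two complete dates, start <= end",
             class = "vigisignal_config_error")
  }
  invisible(cfg)
}

#' Planted true odds ratio for a drug-event pair
#'
#' @param config a `synth_config`.
#' @param drug,pt the pair.
#' @return the configured theta, or 1 for unconfigured pairs (the null).
#' @export
planted_truth <- function(config, drug, pt) {
  drug <- normalise_drug_name(drug)
  hit <- config$planted_or$drug == drug & config$planted_or$pt == pt
  if (any(hit)) config$planted_or$theta[which(hit)[1]] else 1
}

# numeric Date vector -> partial-date character, degrading a fraction of
# entries to month / year precision (60/40 split of the degraded share)
.degrade_dates <- function(days, p) {
  out <- .fmt_days(days)
  if (p > 0) {
    u <- runif(length(out))
    m <- u < 0.6 * p
    y <- !m & u < p
    out[m] <- substr(out[m], 1, 7)
    out[y] <- substr(out[y], 1, 4)
  }
  out
}

# fast Date-number -> character via the unique-day table
.fmt_days <- function(days) {
  ud <- unique(days)
  f <- format(.Date(ud), "%Y-%m-%d")
  f[match(days, ud)]
}

#' Generate a synthetic ICSR database
#'
#' Draws the database described by a [synth_config()]: fully reproducible
#' from the config seed. Generator bookkeeping needed by validation tests
#' is attached as the `"synth_truth"` attribute: a list with `duplicates`
#' (tibble `original`, `duplicate` of planted clone pairs) and `exposed`
#' (named list of primary-report ids exposed, per study drug, with a
#' suspected/interacting role).
#'
#' @param config a `synth_config`.
#' @return an `icsr_set`.
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  # run on a private RNG stream so callers' RNG state is untouched
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_reports
  ids <- sprintf("R%08d", seq_len(n))
  d0 <- as.integer(earliest_date(config$date_range[1]))
  d1 <- as.integer(earliest_date(config$date_range[2]))
  report_day <- d0 + sample.int(d1 - d0 + 1L, n, replace = TRUE) - 1L

  reporter <- sample(names(config$reporter_mix), n, TRUE, prob = config$reporter_mix)
  sex <- sample(names(config$sex_probs), n, TRUE, prob = config$sex_probs)
  sex[runif(n) < config$p_missing_sex] <- NA_character_
  age <- round(pmin(100, pmax(18, rnorm(n, config$age_mean, config$age_sd))))
  age[runif(n) < config$p_missing_age] <- NA_real_
  seriousness <- sample(names(config$seriousness_probs), n, TRUE,
                        prob = config$seriousness_probs)
  outcome <- sample(names(config$outcome_probs), n, TRUE, prob = config$outcome_probs)
  country <- sample(names(config$countries), n, TRUE, prob = config$countries)

  # --- drug exposures -------------------------------------------------------
  roles <- names(config$role_probs)
  nd <- nrow(config$drugs)
  drug_rows <- vector("list", nd + 1L)
  roi_flag <- vector("list", nd)     # suspected/interacting exposure per drug
  start_day_by_drug <- vector("list", nd)
  any_drug <- rep(FALSE, n)
  for (i in seq_len(nd)) {
    dg <- config$drugs$name[i]
    auth <- as.integer(earliest_date(config$drugs$authorisation_date[i]))
    exp_i <- runif(n) < config$drugs$exposure_prob[i]
    idx <- which(exp_i)
    role_i <- sample(roles, length(idx), TRUE, prob = config$role_probs)
    # treatment starts some time before the report, never before the later
    # of authorisation and the database window start
    start <- pmax(report_day[idx] - round(stats::rexp(length(idx), 1 / 90)),
                  pmax(d0, auth))
    start <- pmin(start, report_day[idx])
    roi <- rep(FALSE, n)
    roi[idx[role_i %in% c("suspected", "interacting")]] <- TRUE
    roi_flag[[i]] <- roi
    sd_full <- rep(NA_integer_, n)
    sd_full[idx] <- as.integer(start)
    start_day_by_drug[[i]] <- sd_full
    any_drug[idx] <- TRUE
    drug_rows[[i]] <- tibble::tibble(row = idx, drug_name = dg, role = role_i,
                                     start_day = as.integer(start))
  }
  # comparator drug for reports with no study-drug mention
  bare <- which(!any_drug)
  comp <- sample(config$comparator_drugs, length(bare), TRUE)
  comp_start <- pmax(report_day[bare] - round(stats::rexp(length(bare), 1 / 90)), d0)
  drug_rows[[nd + 1L]] <- tibble::tibble(row = bare, drug_name = comp,
                                         role = "suspected",
                                         start_day = as.integer(comp_start))
  drug_tbl <- dplyr::bind_rows(drug_rows)

  # --- reactions ------------------------------------------------------------
  pts <- rbind(config$event_pts, config$background_pts)
  rxn_rows <- vector("list", nrow(pts) + 1L)
  any_rxn <- rep(FALSE, n)
  for (j in seq_len(nrow(pts))) {
    pt <- pts$pt_name[j]
    logit_p <- rep(qlogis(pts$baseline_prob[j]), n)
    po <- config$planted_or[config$planted_or$pt == pt, ]
    for (k in seq_len(nrow(po))) {
      di <- match(po$drug[k], config$drugs$name)
      logit_p <- logit_p + log(po$theta[k]) * roi_flag[[di]]
    }
    y <- runif(n) < plogis(logit_p)
    idx <- which(y)
    # onset: log-normal TTO after drug start for modelled exposed pairs,
    # otherwise shortly before the report date
    onset <- report_day[idx] - round(stats::rexp(length(idx), 1 / 14))
    tm <- config$tto_model[config$tto_model$pt == pt, ]
    for (k in seq_len(nrow(tm))) {
      di <- match(tm$drug[k], config$drugs$name)
      if (is.na(di)) next
      hit <- which(roi_flag[[di]][idx])
      if (!length(hit)) next
      tto <- round(rlnorm(length(hit), meanlog = log(tm$median_days[k]),
                          sdlog = tm$sigma[k]))
      onset[hit] <- start_day_by_drug[[di]][idx[hit]] + as.integer(tto)
    }
    any_rxn[idx] <- TRUE
    rxn_rows[[j]] <- tibble::tibble(row = idx, pt_name = pt,
                                    onset_day = as.integer(onset))
  }
  bare_rxn <- which(!any_rxn)
  filler <- if (is.null(config$filler_pt)) {
    sample(config$background_pts$pt_name, length(bare_rxn), replace = TRUE)
  } else rep(config$filler_pt, length(bare_rxn))
  rxn_rows[[nrow(pts) + 1L]] <- tibble::tibble(
    row = bare_rxn, pt_name = filler,
    onset_day = as.integer(report_day[bare_rxn] -
                             round(stats::rexp(length(bare_rxn), 1 / 14))))
  rxn_tbl <- dplyr::bind_rows(rxn_rows)

  # --- assemble primary reports --------------------------------------------
  reports <- tibble::tibble(
    report_id = ids,
    report_date = .degrade_dates(report_day, config$p_partial_date / 3),
    country = country, reporter_qualification = reporter,
    seriousness = seriousness, outcome = outcome,
    age_years = age, sex = sex
  )
  drug_tbl <- drug_tbl[order(drug_tbl$row), ]
  drugs <- tibble::tibble(
    report_id = ids[drug_tbl$row],
    drug_seq = sequence(rle(drug_tbl$row)$lengths),
    drug_name = drug_tbl$drug_name, role = drug_tbl$role,
    start_date = .degrade_dates(drug_tbl$start_day, config$p_partial_date),
    indication_pt = NA_character_
  )
  rxn_tbl <- rxn_tbl[order(rxn_tbl$row), ]
  reactions <- tibble::tibble(
    report_id = ids[rxn_tbl$row],
    reaction_seq = sequence(rle(rxn_tbl$row)$lengths),
    pt_name = rxn_tbl$pt_name,
    onset_date = .degrade_dates(rxn_tbl$onset_day, config$p_partial_date)
  )

  # --- duplicates -----------------------------------------------------------
  dup_truth <- tibble::tibble(original = character(), duplicate = character())
  if (config$duplicate_rate > 0) {
    cloned <- which(runif(n) < config$duplicate_rate)
    if (length(cloned)) {
      orig_ids <- ids[cloned]
      dup_ids <- paste0(orig_ids, "D")
      shift <- sample(0:14, length(cloned), TRUE)
      dup_reports <- reports[cloned, ]
      dup_reports$report_id <- dup_ids
      complete <- is_complete_date(dup_reports$report_date)
      dup_reports$report_date[complete] <- .fmt_days(
        as.integer(earliest_date(dup_reports$report_date[complete])) +
          shift[complete])
      dup_drugs <- drugs[drugs$report_id %in% orig_ids, ]
      dup_drugs$report_id <- dup_ids[match(dup_drugs$report_id, orig_ids)]
      dup_rxn <- reactions[reactions$report_id %in% orig_ids, ]
      dup_rxn$report_id <- dup_ids[match(dup_rxn$report_id, orig_ids)]
      reports <- dplyr::bind_rows(reports, dup_reports)
      drugs <- dplyr::bind_rows(drugs, dup_drugs)
      reactions <- dplyr::bind_rows(reactions, dup_rxn)
      dup_truth <- tibble::tibble(original = orig_ids, duplicate = dup_ids)
    }
  }

  out <- icsr_set(reports, drugs, reactions, validate = FALSE, normalise = FALSE)
  exposed <- lapply(seq_len(nd), function(i) ids[roi_flag[[i]]])
  names(exposed) <- config$drugs$name
  attr(out, "synth_truth") <- list(duplicates = dup_truth, exposed = exposed)
  out
}
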