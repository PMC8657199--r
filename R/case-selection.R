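# Eligibility criteria, duplicate removal, analysis windows, case selection.
#
# The study design: exclude reports from non-health-professionals,
# duplicates, and reports with unknown age or sex; analyse each drug of
# interest from its marketing-authorisation date to a common window end;
# a case is an eligible in-window report mentioning the drug as suspected
# or interacting together with at least one event PT.

#' Eligibility criteria and per-drug analysis windows
#'
#' @param require_health_professional exclude reports not notified by a
#'   health professional (default `TRUE`).
#' @param require_known_age exclude reports with missing age (default `TRUE`).
#' @param require_known_sex exclude reports with missing sex (default `TRUE`).
#' @param dedup remove rule-based duplicates (default `TRUE`); see
#'   [deduplicate()].
#' @param drug_roles_of_interest drug roles defining exposure; default
#'   `c("suspected", "interacting")` (concomitant mentions never count).
#' @param window_start_by_drug named character vector mapping each drug of
#'   interest to its window start (marketing-authorisation date,
#'   `"YYYY-MM-DD"`), or `NULL` for no windows.
#' @param window_end window end date shared by all drugs (`"YYYY-MM-DD"`),
#'   or `NULL`.
#' @param dedup_window_days report dates within this many days count as the
#'   same event for duplicate detection (default 30).
#' @return an object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(require_health_professional = TRUE,
                                 require_known_age = TRUE,
                                 require_known_sex = TRUE,
                                 dedup = TRUE,
                                 drug_roles_of_interest = c("suspected", "interacting"),
                                 window_start_by_drug = NULL,
                                 window_end = NULL,
                                 dedup_window_days = 30) {
  if (!all(drug_roles_of_interest %in% .role_levels)) {
    vs_abort("drug_roles_of_interest must be drawn from suspected/interacting/concomitant",
             class = "vigisignal_config_error")
  }
  if (!is.null(window_start_by_drug)) {
    if (is.null(names(window_start_by_drug)) || any(!nzchar(names(window_start_by_drug)))) {
      vs_abort("window_start_by_drug must be a named vector (names are drug names)",
               class = "vigisignal_config_error")
    }
    names(window_start_by_drug) <- normalise_drug_name(names(window_start_by_drug))
    if (any(!is_complete_date(window_start_by_drug))) {
      vs_abort("window start dates must be complete YYYY-MM-DD dates",
               class = "vigisignal_config_error")
    }
    if (!is.null(window_end)) {
      if (!is_complete_date(window_end)) {
        vs_abort("window_end must be a complete YYYY-MM-DD date",
                 class = "vigisignal_config_error")
      }
      late <- earliest_date(window_start_by_drug) > earliest_date(window_end)
      if (any(late)) {
        vs_abort(paste0("window start after window end for: ",
                        oxford(names(window_start_by_drug)[late])),
                 class = "vigisignal_config_error")
      }
    }
  }
  structure(list(require_health_professional = isTRUE(require_health_professional),
                 require_known_age = isTRUE(require_known_age),
                 require_known_sex = isTRUE(require_known_sex),
                 dedup = isTRUE(dedup),
                 drug_roles_of_interest = drug_roles_of_interest,
                 window_start_by_drug = window_start_by_drug,
                 window_end = window_end,
                 dedup_window_days = dedup_window_days),
            class = "eligibility_criteria")
}

#' Apply eligibility filters to a report collection
#'
#' Filters are applied in a fixed order — reporter qualification, then
#' unknown age, then unknown sex, then duplicates — and each excluded
#' report is attributed the first reason that caught it. The final
#' eligible set does not depend on the order; only reason attribution
#' does. Per-drug analysis windows are *not* applied here: they are
#' drug-specific and enforced at screening time (see [in_window()]).
#'
#' @param x an `icsr_set`.
#' @param criteria an [eligibility_criteria()] object.
#' @return list with `eligible` (an `icsr_set`), `exclusions` (tibble
#'   `report_id`, `reason`) and `counts` (tibble `reason`, `n`). Always
#'   `n_reports(eligible) + nrow(exclusions) == n_reports(x)`.
#' @export
apply_eligibility <- function(x, criteria) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  r <- x$reports
  reason <- rep(NA_character_, nrow(r))
  if (criteria$require_health_professional) {
    hit <- is.na(reason) & r$reporter_qualification != "health_professional"
    reason[hit] <- "non_health_professional"
  }
  if (criteria$require_known_age) {
    hit <- is.na(reason) & is.na(r$age_years)
    reason[hit] <- "unknown_age"
  }
  if (criteria$require_known_sex) {
    hit <- is.na(reason) & is.na(r$sex)
    reason[hit] <- "unknown_sex"
  }
  if (criteria$dedup && any(is.na(reason))) {
    surv <- filter_reports(x, r$report_id[is.na(reason)])
    dd <- deduplicate(surv, roles = criteria$drug_roles_of_interest,
                      window_days = criteria$dedup_window_days)
    reason[r$report_id %in% dd$removed_ids] <- "duplicate"
    eligible <- dd$kept
  } else {
    eligible <- filter_reports(x, r$report_id[is.na(reason)])
  }
  excl <- tibble::tibble(report_id = r$report_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  counts <- dplyr::count(excl, .data$reason, name = "n")
  list(eligible = eligible, exclusions = excl, counts = counts)
}

#' Rule-based duplicate removal
#'
#' A documented stand-in for proprietary probabilistic duplicate detection
#' used by large pharmacovigilance databases. Two reports are duplicates
#' when they agree exactly on sex, age, country, the sorted set of
#' suspected/interacting drug names and the sorted set of reaction PT
#' names, and their report dates (coerced to earliest consistent day) are
#' within `window_days`. Within a duplicate group the report with the
#' earliest report date is kept, ties broken by lexicographically smallest
#' report id. The operation is idempotent.
#'
#' @param x an `icsr_set`.
#' @param roles drug roles entering the match key (default
#'   suspected/interacting).
#' @param window_days date tolerance in days (default 30).
#' @return list with `kept` (an `icsr_set`) and `removed_ids` (character).
#' @export
deduplicate <- function(x, roles = c("suspected", "interacting"), window_days = 30) {
  r <- x$reports
  if (!nrow(r)) return(list(kept = x, removed_ids = character()))
  d <- x$drugs[x$drugs$role %in% roles, c("report_id", "drug_name")]
  dkey <- vapply(split(d$drug_name, d$report_id),
                 function(v) paste(sort(unique(v)), collapse = ";"), character(1))
  rkey <- vapply(split(x$reactions$pt_name, x$reactions$report_id),
                 function(v) paste(sort(unique(v)), collapse = ";"), character(1))
  dn <- unname(dkey[r$report_id])
  dn[is.na(dn)] <- "" # report with no suspected/interacting drug
  rn <- unname(rkey[r$report_id])
  key <- paste(ifelse(is.na(r$sex), "<NA>", r$sex),
               ifelse(is.na(r$age_years), "<NA>", as.character(r$age_years)),
               ifelse(is.na(r$country), "<NA>", r$country),
               dn, rn, sep = "\x1f")
  removed <- character()
  dup_key <- key %in% key[duplicated(key)]
  if (any(dup_key)) {
    dates <- as.numeric(earliest_date(r$report_date))
    for (grp in split(which(dup_key), key[dup_key])) {
      if (length(grp) < 2L) next
      ord <- grp[order(dates[grp], r$report_id[grp])]
      # greedy clustering anchored on each cluster's earliest report
      anchor <- ord[1]
      for (i in ord[-1]) {
        gap <- dates[i] - dates[anchor]
        if (is.na(gap) || gap <= window_days) {
          removed <- c(removed, r$report_id[i])
        } else {
          anchor <- i
        }
      }
    }
  }
  kept <- if (length(removed)) filter_reports(x, setdiff(r$report_id, removed)) else x
  list(kept = kept, removed_ids = removed)
}

#' Is each report inside a drug's analysis window?
#'
#' A report is in window when its report date, coerced to the earliest
#' complete date consistent with its precision, lies in the closed
#' interval from the drug's window start (marketing authorisation) to the
#' common window end.
#'
#' @param x an `icsr_set`.
#' @param drug_name drug whose window applies; must be present in
#'   `criteria$window_start_by_drug`.
#' @param criteria an [eligibility_criteria()] with windows configured.
#' @return logical vector along the reports of `x`.
#' @export
in_window <- function(x, drug_name, criteria) {
  drug_name <- normalise_drug_name(drug_name)
  if (is.null(criteria$window_start_by_drug) ||
      !drug_name %in% names(criteria$window_start_by_drug)) {
    vs_abort(paste0("no analysis window configured for drug: ", drug_name),
             class = "vigisignal_config_error")
  }
  lo <- earliest_date(criteria$window_start_by_drug[[drug_name]])
  hi <- earliest_date(criteria$window_end %||% "9999-12-31")
  dt <- earliest_date(x$reports$report_date)
  !is.na(dt) & dt >= lo & dt <= hi
}

# report ids mentioning a drug with one of the given roles
exposed_ids <- function(x, drug_name, roles) {
  drug_name <- normalise_drug_name(drug_name)
  unique(x$drugs$report_id[x$drugs$drug_name == drug_name & x$drugs$role %in% roles])
}

# report ids mentioning any of the given reaction PTs
event_ids <- function(x, pts) {
  unique(x$reactions$report_id[x$reactions$pt_name %in% pts])
}

#' Select the cases for one drug
#'
#' Cases are the eligible reports that (i) mention `drug_name` with a role
#' of interest, (ii) report at least one event PT, and (iii) fall inside
#' the drug's analysis window.
#'
#' @param eligible an `icsr_set` that already passed [apply_eligibility()].
#' @param drug_name drug of interest.
#' @param event_pts non-empty character vector of event PT names.
#' @param criteria an [eligibility_criteria()] object (roles and windows).
#' @return an `icsr_set` of cases (subset of `eligible`).
#' @export
select_cases <- function(eligible, drug_name, event_pts, criteria) {
  if (!length(event_pts)) {
    vs_abort("event_pts must be non-empty", class = "vigisignal_usage_error")
  }
  ids <- intersect(exposed_ids(eligible, drug_name, criteria$drug_roles_of_interest),
                   event_ids(eligible, event_pts))
  if (!is.null(criteria$window_start_by_drug)) {
    win_ids <- eligible$reports$report_id[in_window(eligible, drug_name, criteria)]
    ids <- intersect(ids, win_ids)
  }
  filter_reports(eligible, ids)
}
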