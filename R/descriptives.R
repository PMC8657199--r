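# Descriptive cohort tables.
#
# Three denominators coexist in a case/non-case cohort description and are
# kept explicit throughout: the number of cases (reports), the number of
# study-drug mentions across cases (one case can mention two study drugs),
# and the number of qualifying event-PT mentions across cases (one case
# can report several renal PTs). Percentages are rounded half-up to one
# decimal, the convention of published pharmacovigilance tables.

#' Cohort characteristics summary
#'
#' Describes a case set: age distribution, sex, seriousness, outcome, top
#' reporting countries, per-drug case counts (denominator: drug mentions)
#' and top event PTs (denominator: event mentions). Ties in top-k blocks
#' break alphabetically.
#'
#' @param cases an `icsr_set` of selected cases (non-empty).
#' @param drugs character vector of study drug names.
#' @param event_pts character vector of event PT names.
#' @param k how many rows in the top-events block (default 10); the
#'   country block shows `min(k, 5)` rows.
#' @param roles drug roles that count as a study-drug mention.
#' @return an object of class `cohort_summary`: list with `n_cases`,
#'   `n_drug_mentions`, `n_event_mentions`, `age` (median/q1/q3),
#'   and tibbles `sex`, `seriousness`, `outcome`, `countries`,
#'   `drug_mentions`, `top_events`, each with `n` and `pct` columns and an
#'   explicit `denominator` attribute-style column where relevant.
#' @export
cohort_summary <- function(cases, drugs, event_pts, k = 10,
                           roles = c("suspected", "interacting")) {
  if (!n_reports(cases)) {
    vs_abort("cohort_summary needs a non-empty case set", class = "vigisignal_usage_error")
  }
  drugs <- normalise_drug_name(drugs)
  r <- cases$reports
  n_cases <- nrow(r)

  count_block <- function(values, levels = NULL, denom = n_cases, top = NULL) {
    tb <- table(values, useNA = "no")
    out <- tibble::tibble(value = names(tb), n = as.numeric(tb))
    if (!is.null(levels)) {
      out <- tibble::tibble(value = levels,
                            n = as.numeric(tb[match(levels, names(tb))]))
      out$n[is.na(out$n)] <- 0
    }
    out <- out[order(-out$n, out$value), ]
    if (!is.null(top)) out <- head(out, top)
    out$pct <- pct_half_up(out$n, denom)
    out$denominator <- denom
    out
  }

  agev <- r$age_years[!is.na(r$age_years)]
  age <- if (length(agev)) {
    q <- unname(quantile(agev, c(0.25, 0.5, 0.75), type = 7))
    list(median = q[2], q1 = q[1], q3 = q[3])
  } else list(median = NA_real_, q1 = NA_real_, q3 = NA_real_)

  # study-drug mentions: a case counts once per distinct study drug it
  # carries with a qualifying role
  dm <- dplyr::distinct(cases$drugs[cases$drugs$drug_name %in% drugs &
                                      cases$drugs$role %in% roles,
                                    c("report_id", "drug_name")])
  n_drug_mentions <- nrow(dm)
  drug_tbl <- tibble::tibble(value = drugs,
                             n = as.numeric(table(factor(dm$drug_name, levels = drugs))))
  drug_tbl$pct <- pct_half_up(drug_tbl$n, n_drug_mentions)
  drug_tbl$denominator <- n_drug_mentions

  # qualifying event mentions: a case counts once per distinct event PT
  em <- dplyr::distinct(cases$reactions[cases$reactions$pt_name %in% event_pts,
                                        c("report_id", "pt_name")])
  n_event_mentions <- nrow(em)
  ev <- count_block(em$pt_name, denom = n_event_mentions, top = k)

  structure(list(
    n_cases = n_cases,
    n_drug_mentions = n_drug_mentions,
    n_event_mentions = n_event_mentions,
    age = age,
    sex = count_block(factor(r$sex, levels = .sex_levels), levels = .sex_levels),
    seriousness = count_block(r$seriousness, levels = .seriousness_levels),
    outcome = count_block(r$outcome, levels = .outcome_levels),
    countries = count_block(r$country, top = min(k, 5)),
    drug_mentions = drug_tbl,
    top_events = ev
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases | %d study-drug mentions | %d event mentions\n",
              x$n_cases, x$n_drug_mentions, x$n_event_mentions))
  cat(sprintf("  age median %s (Q1 %s - Q3 %s)\n", format(x$age$median),
              format(x$age$q1), format(x$age$q3)))
  invisible(x)
}

#' Reporting years for one drug's cases
#'
#' Counts cases by the year of the report date; years strictly before
#' `era_cut` are pooled into one `"before <era_cut>"` row. Percentages
#' use the drug's case count as denominator.
#'
#' @param cases an `icsr_set` of cases (a drug's case set, or a larger
#'   case set — only reports mentioning `drug_name` with a role in
#'   `roles` are tabulated).
#' @param drug_name the drug.
#' @param era_cut pooling cut-point year (default 2010).
#' @param roles qualifying roles.
#' @return tibble with columns `year` (character; `"before <cut>"` first,
#'   then ascending years), `n`, `pct`.
#' @export
reporting_years <- function(cases, drug_name, era_cut = 2010,
                            roles = c("suspected", "interacting")) {
  ids <- exposed_ids(cases, drug_name, roles)
  r <- cases$reports[cases$reports$report_id %in% ids, ]
  if (!nrow(r)) {
    return(tibble::tibble(year = character(), n = numeric(), pct = numeric()))
  }
  yr <- date_year(r$report_date)
  lab <- ifelse(!is.na(yr) & yr < era_cut, paste("before", era_cut), as.character(yr))
  tb <- table(lab, useNA = "no")
  out <- tibble::tibble(year = names(tb), n = as.numeric(tb))
  before <- out$year == paste("before", era_cut)
  out <- rbind(out[before, ], out[!before, ][order(out$year[!before]), ])
  out$pct <- pct_half_up(out$n, nrow(r))
  tibble::as_tibble(out)
}

#' Co-reported adverse reactions among index-event cases
#'
#' Among the cases for `drug_name` that report `index_pt`, counts every
#' other reaction PT (the index PT itself excluded; a PT counts once per
#' case). Top-k by count, ties alphabetical; percentages are of the
#' number of index cases.
#'
#' @param cases an `icsr_set` of cases.
#' @param drug_name the drug.
#' @param index_pt the index event PT.
#' @param k number of co-reported PTs to return (>= 1).
#' @param event_pts optional event-PT universe; when supplied, `index_pt`
#'   must belong to it (usage error otherwise).
#' @param roles qualifying roles.
#' @return tibble with columns `pt`, `n`, `pct` plus the attribute
#'   `n_index_cases`.
#' @export
co_reported <- function(cases, drug_name, index_pt, k = 5, event_pts = NULL,
                        roles = c("suspected", "interacting")) {
  if (k < 1) vs_abort("k must be >= 1", class = "vigisignal_usage_error")
  if (!is.null(event_pts) && !index_pt %in% event_pts) {
    vs_abort(paste0("index_pt is not an event PT: ", index_pt),
             class = "vigisignal_usage_error")
  }
  idx_ids <- intersect(exposed_ids(cases, drug_name, roles),
                       event_ids(cases, index_pt))
  n_index <- length(idx_ids)
  rx <- dplyr::distinct(cases$reactions[cases$reactions$report_id %in% idx_ids &
                                          cases$reactions$pt_name != index_pt,
                                        c("report_id", "pt_name")])
  if (!nrow(rx)) {
    out <- tibble::tibble(pt = character(), n = numeric(), pct = numeric())
  } else {
    tb <- table(rx$pt_name)
    out <- tibble::tibble(pt = names(tb), n = as.numeric(tb))
    out <- head(out[order(-out$n, out$pt), ], k)
    out$pct <- pct_half_up(out$n, n_index)
  }
  attr(out, "n_index_cases") <- n_index
  out
}
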