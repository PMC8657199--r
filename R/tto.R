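# Time to onset (TTO): days from drug start date to event onset date.
#
# TTO is computable only when both dates are day-complete; partial dates
# are never imputed, so denominators ("available data for n cases") shrink
# honestly, mirroring how spontaneous-report data behave. Negative
# differences are implausible (onset before treatment start) and are
# logged and returned missing.

#' Compute time to onset for each case
#'
#' For each report the drug start date is the earliest day-complete start
#' among entries of `drug_name` with a role in `roles` (re-challenge
#' entries therefore anchor on the first course), and the onset date is
#' the earliest day-complete onset among entries of `pt_name`. The TTO is
#' their difference in whole days, or `NA` when either date is not
#' day-complete or the difference is negative (a warning reports how many
#' negative values were discarded).
#'
#' @param x an `icsr_set` in which every report mentions both `drug_name`
#'   (with a role in `roles`) and `pt_name`; anything else is a usage
#'   error naming the offending reports.
#' @param drug_name drug of interest.
#' @param pt_name event preferred term.
#' @param roles qualifying drug roles (default suspected/interacting).
#' @return tibble with columns `report_id` and `tto_days` (integer or
#'   `NA`), one row per report of `x` in order.
#' @export
compute_tto <- function(x, drug_name, pt_name,
                        roles = c("suspected", "interacting")) {
  drug_name <- normalise_drug_name(drug_name)
  ids <- x$reports$report_id
  dd <- x$drugs[x$drugs$drug_name == drug_name & x$drugs$role %in% roles, ]
  rr <- x$reactions[x$reactions$pt_name == pt_name, ]
  missing_drug <- setdiff(ids, dd$report_id)
  missing_pt <- setdiff(ids, rr$report_id)
  if (length(missing_drug) || length(missing_pt)) {
    vs_abort(c("compute_tto expects every report to contain the drug and the PT:",
               if (length(missing_drug))
                 stats::setNames(paste0("no '", drug_name, "' entry in: ",
                                        oxford(missing_drug)), "x"),
               if (length(missing_pt))
                 stats::setNames(paste0("no '", pt_name, "' reaction in: ",
                                        oxford(missing_pt)), "x")),
             class = "vigisignal_usage_error")
  }
  dd <- dd[is_complete_date(dd$start_date), ]
  rr <- rr[is_complete_date(rr$onset_date), ]
  min_by <- function(ids_all, grp, dates) {
    num <- as.numeric(earliest_date(dates))
    agg <- vapply(split(num, grp), min, numeric(1))
    unname(agg[match(ids_all, names(agg))])
  }
  start <- min_by(ids, dd$report_id, dd$start_date)
  onset <- min_by(ids, rr$report_id, rr$onset_date)
  tto <- as.integer(onset - start)
  neg <- !is.na(tto) & tto < 0
  if (any(neg)) {
    vs_warn(sprintf("%d negative time(s) to onset discarded as implausible (%s)",
                    sum(neg), oxford(ids[neg])),
            class = "vigisignal_negative_tto")
    tto[neg] <- NA_integer_
  }
  tibble::tibble(report_id = ids, tto_days = tto)
}

#' Summarise a set of times to onset
#'
#' Median and quartiles of the available (non-missing) TTOs plus the
#' empirical cumulative distribution. The median for even n is the mean
#' of the two central order statistics, and Q1/Q3 use linear interpolation
#' of order statistics ([stats::quantile()] type 7); the quartile
#' convention is configurable because published tables rarely state one.
#'
#' @param ttos numeric vector of TTO days; `NA`s count as missing.
#' @param quantile_type order-statistic interpolation rule passed to
#'   [stats::quantile()] (default 7).
#' @return an object of class `tto_summary`: list with `n_available`,
#'   `n_missing`, `median_days`, `q1_days`, `q3_days`, and `ecdf` (tibble
#'   `days`, `cum_fraction`; zero rows when nothing is available).
#' @export
tto_summary <- function(ttos, quantile_type = 7) {
  if (!is.numeric(ttos)) {
    vs_abort("ttos must be a numeric vector of days", class = "vigisignal_validation_error")
  }
  if (any(!is.na(ttos) & ttos < 0)) {
    vs_abort("negative times to onset are invalid here; compute_tto discards them",
             class = "vigisignal_validation_error")
  }
  avail <- ttos[!is.na(ttos)]
  if (length(avail)) {
    q <- unname(quantile(avail, probs = c(0.25, 0.5, 0.75), type = quantile_type))
    ecdf_tbl <- tto_ecdf(avail)
  } else {
    q <- rep(NA_real_, 3)
    ecdf_tbl <- tibble::tibble(days = numeric(), cum_fraction = numeric())
  }
  structure(list(n_available = length(avail), n_missing = sum(is.na(ttos)),
                 median_days = q[2], q1_days = q[1], q3_days = q[3],
                 ecdf = ecdf_tbl),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("<tto_summary> n=%d available (%d missing) | median %s days (Q1 %s; Q3 %s)\n",
              x$n_available, x$n_missing, format(x$median_days),
              format(x$q1_days), format(x$q3_days)))
  invisible(x)
}

#' Empirical cumulative distribution of times to onset
#'
#' Step function evaluated at each distinct value: the fraction at value
#' v is `count(ttos <= v) / n`. Permutation-invariant; the final fraction
#' is always 1.
#'
#' @param ttos numeric vector with at least one non-missing value
#'   (missing entries are dropped).
#' @return tibble with columns `days` (ascending distinct values) and
#'   `cum_fraction`.
#' @export
tto_ecdf <- function(ttos) {
  ttos <- ttos[!is.na(ttos)]
  if (!length(ttos)) {
    vs_abort("tto_ecdf needs at least one available time to onset",
             class = "vigisignal_usage_error")
  }
  days <- sort(unique(ttos))
  counts <- cumsum(tabulate(match(sort(ttos), days)))
  tibble::tibble(days = days, cum_fraction = counts / length(ttos))
}
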