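# 2x2 disproportionality screening with the reporting odds ratio.
#
# Case/non-case design: for a (drug, event-PT) pair over a set of eligible
# in-window reports,
#   a = reports with the drug (suspected/interacting) and the event PT
#   b = reports with the drug and only other PTs
#   c = reports without the drug but with the event PT
#   d = reports with neither
# ROR = (a/b)/(c/d) = ad/bc, with Woolf 95% CI
#   exp( ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d) ),  z = 1.96.
# A pair is screened only when a reaches the minimum case threshold
# (5, per EMA signal-detection guidance); a signal of disproportionate
# reporting (SDR) is a screened pair whose CI lower bound exceeds 1.

#' Construct a 2x2 contingency table for one drug-event pair
#'
#' @param a,b,c,d non-negative integer counts (see the classification
#'   above).
#' @param drug_name,pt_name labels carried along with the table.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug_name = NA_character_,
                              pt_name = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts))) {
    vs_abort("contingency counts must be non-negative integers",
             class = "vigisignal_validation_error")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), drug_name = drug_name, pt_name = pt_name),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s | a=%g b=%g c=%g d=%g (N=%g)\n",
              x$drug_name, x$pt_name, x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the 2x2 table for a drug-event pair over eligible reports
#'
#' Each report is counted exactly once, classified by exposure (mentions
#' the drug with a role in `roles`) crossed with event (mentions the PT,
#' counted once even if listed twice). The input is expected to be the
#' drug's eligible in-window universe.
#'
#' @param eligible an `icsr_set`, already filtered and windowed for
#'   `drug_name`.
#' @param drug_name drug of interest.
#' @param pt_name event preferred term.
#' @param roles exposure roles (default suspected/interacting).
#' @return a `contingency_table`.
#' @export
build_contingency <- function(eligible, drug_name, pt_name,
                              roles = c("suspected", "interacting")) {
  ids <- eligible$reports$report_id
  exposed <- ids %in% exposed_ids(eligible, drug_name, roles)
  event <- ids %in% event_ids(eligible, pt_name)
  contingency_table(a = sum(exposed & event), b = sum(exposed & !event),
                    c = sum(!exposed & event), d = sum(!exposed & !event),
                    drug_name = normalise_drug_name(drug_name), pt_name = pt_name)
}

#' Reporting odds ratio with its confidence interval
#'
#' Point estimate `ad/bc` and Woolf interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the estimate is undefined (`NA`): no continuity correction is
#' applied, so a reported value is always the plain cross-product ratio.
#'
#' @param table a `contingency_table`.
#' @param z normal quantile for the interval (default 1.96, a 95% CI).
#' @param min_cases minimum case count for the pair to be screenable
#'   (default 5); drives the `meets_threshold` flag.
#' @return one-row tibble with columns `drug`, `pt`, `a`, `b`, `c`, `d`,
#'   `ror`, `ci_low`, `ci_high`, `n_cases`, `meets_threshold`, `is_sdr`.
#'   `is_sdr` is `TRUE` only when the threshold is met, the estimate is
#'   defined, and `ci_low > 1`.
#' @export
ror_with_ci <- function(table, z = 1.96, min_cases = 5) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  defined <- a > 0 && b > 0 && c > 0 && d > 0
  if (defined) {
    ror <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci_low <- exp(log(ror) - z * se)
    ci_high <- exp(log(ror) + z * se)
  } else {
    ror <- ci_low <- ci_high <- NA_real_
  }
  meets <- a >= min_cases
  tibble::tibble(drug = table$drug_name, pt = table$pt_name,
                 a = a, b = b, c = c, d = d,
                 ror = ror, ci_low = ci_low, ci_high = ci_high,
                 n_cases = a, meets_threshold = meets,
                 is_sdr = meets && defined && ci_low > 1)
}

#' Screen drug-event pairs for signals of disproportionate reporting
#'
#' For each drug, the eligible universe is restricted to the drug's
#' analysis window (when criteria carry windows), every event PT is
#' cross-classified against exposure, and pairs with at least `min_cases`
#' cases are estimated. Pairs below the threshold are returned separately
#' with their case counts rather than silently dropped.
#'
#' @param eligible an `icsr_set` that passed [apply_eligibility()].
#' @param drugs character vector of drug names to screen.
#' @param event_pts character vector of event PT names.
#' @param criteria an [eligibility_criteria()] (roles; windows optional).
#' @param min_cases minimum case count `a` for estimation (default 5).
#' @param z normal quantile for the CI (default 1.96).
#' @return an object of class `screen_result`: list with `signals` (tibble
#'   of [ror_with_ci()] rows, ordered by drug then descending `a`) and
#'   `suppressed` (tibble `drug`, `pt`, `a` for below-threshold pairs).
#' @export
screen <- function(eligible, drugs, event_pts, criteria = eligibility_criteria(),
                   min_cases = 5, z = 1.96) {
  if (!length(drugs) || !length(event_pts)) {
    return(structure(list(signals = ror_with_ci(contingency_table(1, 1, 1, 1))[0, ],
                          suppressed = tibble::tibble(drug = character(),
                                                      pt = character(), a = numeric())),
                     class = "screen_result"))
  }
  drugs <- normalise_drug_name(drugs)
  signal_rows <- list()
  suppressed <- list()
  for (dg in drugs) {
    universe <- if (!is.null(criteria$window_start_by_drug)) {
      filter_reports(eligible, in_window(eligible, dg, criteria))
    } else eligible
    ids <- universe$reports$report_id
    exposed <- ids %in% exposed_ids(universe, dg, criteria$drug_roles_of_interest)
    rows <- lapply(event_pts, function(pt) {
      event <- ids %in% event_ids(universe, pt)
      tab <- contingency_table(sum(exposed & event), sum(exposed & !event),
                               sum(!exposed & event), sum(!exposed & !event),
                               drug_name = dg, pt_name = pt)
      ror_with_ci(tab, z = z, min_cases = min_cases)
    })
    rows <- dplyr::bind_rows(rows)
    rows <- rows[order(-rows$a, rows$pt), ]
    signal_rows[[dg]] <- rows[rows$meets_threshold, ]
    suppressed[[dg]] <- tibble::tibble(drug = dg,
                                       pt = rows$pt[!rows$meets_threshold],
                                       a = rows$a[!rows$meets_threshold])
  }
  structure(list(signals = dplyr::bind_rows(signal_rows),
                 suppressed = dplyr::bind_rows(suppressed)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d screened pair(s), %d suppressed below threshold\n",
              nrow(x$signals), nrow(x$suppressed)))
  if (nrow(x$signals)) {
    shown <- x$signals
    shown$ror <- round_half_up(shown$ror, 2)
    shown$ci_low <- round_half_up(shown$ci_low, 2)
    shown$ci_high <- round_half_up(shown$ci_high, 2)
    print(shown[, c("drug", "pt", "a", "ror", "ci_low", "ci_high", "is_sdr")], n = 20)
  }
  invisible(x)
}
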