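# ICSR data model and lossless IO.
#
# An `icsr_set` is a relational container for a collection of individual
# case safety reports: one tibble of report-level fields plus child tibbles
# of drug and reaction entries keyed by report_id, with sequence columns
# preserving entry order. The layout keeps whole-database operations
# (eligibility filters, 2x2 classification) vectorised even at hundreds of
# thousands of reports.
#
# The schema mirrors E2B ICSR field semantics (report, drug and reaction
# blocks) without claiming E2B compliance; see the package README for the
# documented JSON-lines and delimited dialects.

.reporter_levels    <- c("health_professional", "non_health_professional", "unknown")
.seriousness_levels <- c("serious", "not_serious", "unknown")
.outcome_levels     <- c("death", "not_recovered", "recovered_with_sequelae",
                         "recovered", "unknown")
.sex_levels         <- c("female", "male")
.role_levels        <- c("suspected", "interacting", "concomitant")

.report_cols <- c("report_id", "report_date", "country", "reporter_qualification",
                  "seriousness", "outcome", "age_years", "sex")
.drug_cols     <- c("report_id", "drug_seq", "drug_name", "role", "start_date",
                    "indication_pt")
.reaction_cols <- c("report_id", "reaction_seq", "pt_name", "onset_date")

#' Normalise a drug name
#'
#' Lower-cases, trims, and collapses internal whitespace. No thesaurus or
#' ATC mapping is applied: matching is by active-substance name only.
#'
#' @param x character vector of drug names.
#' @return normalised character vector.
#' @export
normalise_drug_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a collection of individual case safety reports
#'
#' Builds the package's central container from three tibbles: report-level
#' fields, drug entries and reaction entries, linked by `report_id`.
#' Drug names are normalised on construction (see [normalise_drug_name()]).
#'
#' @param reports tibble with columns `report_id`, `report_date`,
#'   `country`, `reporter_qualification`, `seriousness`, `outcome`,
#'   `age_years`, `sex`. Dates are partial-date strings
#'   (`"YYYY[-MM[-DD]]"`); `country` is ISO-3166 alpha-2 or `NA`.
#' @param drugs tibble with columns `report_id`, `drug_seq`, `drug_name`,
#'   `role` (`suspected`/`interacting`/`concomitant`), `start_date`,
#'   `indication_pt`.
#' @param reactions tibble with columns `report_id`, `reaction_seq`,
#'   `pt_name`, `onset_date`.
#' @param validate run full invariant checks (default `TRUE`). Skipping is
#'   an internal optimisation for data the package itself generated.
#' @param normalise normalise drug names (default `TRUE`); skipped
#'   internally when the input is a subset of an existing `icsr_set`.
#' @return an object of class `icsr_set`.
#' @export
icsr_set <- function(reports, drugs, reactions, validate = TRUE, normalise = TRUE) {
  reports   <- tibble::as_tibble(reports)[, .report_cols]
  drugs     <- tibble::as_tibble(drugs)[, .drug_cols]
  reactions <- tibble::as_tibble(reactions)[, .reaction_cols]
  if (normalise) drugs$drug_name <- normalise_drug_name(drugs$drug_name)
  x <- structure(list(reports = reports, drugs = drugs, reactions = reactions),
                 class = "icsr_set")
  if (validate) validate_icsr_set(x)
  x
}

#' An empty ICSR collection
#' @return an `icsr_set` with zero reports.
#' @export
empty_icsr_set <- function() {
  icsr_set(
    tibble::tibble(report_id = character(), report_date = character(),
                   country = character(), reporter_qualification = character(),
                   seriousness = character(), outcome = character(),
                   age_years = numeric(), sex = character()),
    tibble::tibble(report_id = character(), drug_seq = integer(),
                   drug_name = character(), role = character(),
                   start_date = character(), indication_pt = character()),
    tibble::tibble(report_id = character(), reaction_seq = integer(),
                   pt_name = character(), onset_date = character()),
    validate = FALSE
  )
}

#' Validate an ICSR collection against its invariants
#'
#' Checks: unique non-empty report ids; every report has at least one drug
#' and one reaction entry; no orphan child rows; enum fields within their
#' domains; ages within \[0, 130\]; all dates valid partial dates.
#'
#' @param x an `icsr_set`.
#' @return `x`, invisibly; errors on the first violated invariant.
#' @export
validate_icsr_set <- function(x) {
  r <- x$reports
  problems <- character()
  if (anyNA(r$report_id) || any(!nzchar(r$report_id))) {
    problems <- c(problems, "report_id must be non-empty")
  }
  if (anyDuplicated(r$report_id)) {
    dup <- unique(r$report_id[duplicated(r$report_id)])
    problems <- c(problems, paste0("duplicate report_id: ", oxford(dup)))
  }
  no_drug <- setdiff(r$report_id, x$drugs$report_id)
  if (length(no_drug)) {
    problems <- c(problems, paste0("reports without any drug entry: ", oxford(no_drug)))
  }
  no_rxn <- setdiff(r$report_id, x$reactions$report_id)
  if (length(no_rxn)) {
    problems <- c(problems, paste0("reports without any reaction entry: ", oxford(no_rxn)))
  }
  orphans <- setdiff(c(x$drugs$report_id, x$reactions$report_id), r$report_id)
  if (length(orphans)) {
    problems <- c(problems, paste0("drug/reaction rows with unknown report_id: ",
                                   oxford(unique(orphans))))
  }
  bad_age <- !is.na(r$age_years) & (r$age_years < 0 | r$age_years > 130)
  if (any(bad_age)) {
    problems <- c(problems, paste0("age_years outside [0, 130] for: ",
                                   oxford(r$report_id[bad_age])))
  }
  check_enum <- function(vals, levels, field, allow_na = FALSE) {
    bad <- !vals %in% levels & !(allow_na & is.na(vals))
    if (any(bad)) {
      problems <<- c(problems, sprintf("invalid %s value(s): %s", field,
                                       oxford(unique(vals[bad]))))
    }
  }
  check_enum(r$reporter_qualification, .reporter_levels, "reporter_qualification")
  check_enum(r$seriousness, .seriousness_levels, "seriousness")
  check_enum(r$outcome, .outcome_levels, "outcome")
  check_enum(r$sex, .sex_levels, "sex", allow_na = TRUE)
  check_enum(x$drugs$role, .role_levels, "drug role")
  if (any(is.na(x$drugs$drug_name) | !nzchar(x$drugs$drug_name))) {
    problems <- c(problems, "drug_name must be non-empty")
  }
  if (any(is.na(x$reactions$pt_name) | !nzchar(x$reactions$pt_name))) {
    problems <- c(problems, "pt_name must be non-empty")
  }
  for (col in list(c("reports", "report_date"), c("drugs", "start_date"),
                   c("reactions", "onset_date"))) {
    v <- x[[col[1]]][[col[2]]]
    bad <- !is_partial_date(v)
    if (any(bad)) {
      problems <- c(problems, sprintf("invalid %s value(s): %s", col[2],
                                      oxford(unique(v[bad]))))
    }
  }
  if (length(problems)) {
    vs_abort(c("invalid ICSR collection:", stats::setNames(problems, rep("x", length(problems)))),
             class = "vigisignal_invalid_icsr")
  }
  invisible(x)
}

#' Number of reports in a collection
#' @param x an `icsr_set`.
#' @return integer count.
#' @export
n_reports <- function(x) nrow(x$reports)

#' Subset an ICSR collection by report id
#'
#' @param x an `icsr_set`.
#' @param ids character vector of report ids to keep (order of `x` is
#'   preserved), or a logical vector along the reports table.
#' @return an `icsr_set` containing only the selected reports.
#' @export
filter_reports <- function(x, ids) {
  if (is.logical(ids)) {
    stopifnot(length(ids) == n_reports(x))
    ids <- x$reports$report_id[ids]
  }
  keep <- x$reports$report_id %in% ids
  icsr_set(x$reports[keep, ],
           x$drugs[x$drugs$report_id %in% ids, ],
           x$reactions[x$reactions$report_id %in% ids, ],
           validate = FALSE, normalise = FALSE)
}

#' @export
print.icsr_set <- function(x, ...) {
  cat(sprintf("<icsr_set> %d reports, %d drug entries, %d reaction entries\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

# ---- JSON-lines IO ---------------------------------------------------------

# map free-text enum codes to their domain, sending unknown codes to the
# "unknown" member (or NA for sex) with a logged warning
map_enum <- function(vals, levels, field, unknown = "unknown") {
  bad <- !is.na(vals) & !vals %in% levels
  if (any(bad)) {
    vs_warn(sprintf("%d unrecognised %s code(s) (%s) mapped to '%s'",
                    sum(bad), field, oxford(unique(vals[bad])), unknown %||% "NA"),
            class = "vigisignal_unknown_code")
    vals[bad] <- unknown %||% NA_character_
  }
  vals[is.na(vals)] <- if (is.null(unknown)) NA_character_ else unknown
  if (is.null(unknown)) vals[vals %in% ""] <- NA_character_
  vals
}

chr1 <- function(rec, field) {
  v <- rec[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v) || identical(v, "")) NA_character_
  else as.character(v)
}

num1 <- function(rec, field) {
  v <- rec[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
}

# parse one JSON-lines record into row fragments; stops with a record-level
# error naming the line and field when a required field is absent
parse_jsonl_record <- function(rec, line_no) {
  req_err <- function(field) {
    vs_abort(sprintf("line %d: missing required field '%s'", line_no, field),
             class = "vigisignal_record_error")
  }
  id <- chr1(rec, "report_id")
  if (is.na(id)) req_err("report_id")
  if (is.null(rec$drugs) || !length(rec$drugs)) req_err("drugs")
  if (is.null(rec$reactions) || !length(rec$reactions)) req_err("reactions")

  report <- tibble::tibble(
    report_id = id,
    report_date = chr1(rec, "report_date"),
    country = chr1(rec, "country"),
    reporter_qualification = chr1(rec, "reporter_qualification"),
    seriousness = chr1(rec, "seriousness"),
    outcome = chr1(rec, "outcome"),
    age_years = num1(rec, "age_years"),
    sex = chr1(rec, "sex")
  )
  drugs <- tibble::tibble(
    report_id = id,
    drug_seq = seq_along(rec$drugs),
    drug_name = vapply(rec$drugs, chr1, character(1), "drug_name"),
    role = vapply(rec$drugs, chr1, character(1), "role"),
    start_date = vapply(rec$drugs, chr1, character(1), "start_date"),
    indication_pt = vapply(rec$drugs, chr1, character(1), "indication_pt")
  )
  if (anyNA(drugs$drug_name)) req_err("drugs[].drug_name")
  reactions <- tibble::tibble(
    report_id = id,
    reaction_seq = seq_along(rec$reactions),
    pt_name = vapply(rec$reactions, chr1, character(1), "pt_name"),
    onset_date = vapply(rec$reactions, chr1, character(1), "onset_date")
  )
  if (anyNA(reactions$pt_name)) req_err("reactions[].pt_name")
  list(report = report, drugs = drugs, reactions = reactions)
}

#' Read a collection of ICSRs from disk
#'
#' Supports the canonical JSON-lines schema (one report object per line)
#' and the delimited dialect (comma-separated, one row per
#' report-drug-reaction triple with report fields repeated, reassembled by
#' `report_id`). Partial dates are preserved at their stated precision;
#' unrecognised reporter/seriousness/outcome codes map to `"unknown"` and
#' unrecognised sex codes to missing, each with a warning.
#'
#' @param path file to read.
#' @param format `"jsonl"` or `"delimited"`.
#' @param on_error `"abort"` (default) stops at the first invalid record
#'   naming the line and field; `"skip"` drops invalid records with a
#'   warning and records the rejected line numbers in the
#'   `"rejected_lines"` attribute, so that records read plus records
#'   rejected always account for every line presented.
#' @return an `icsr_set`.
#' @export
read_reports <- function(path, format = c("jsonl", "delimited"),
                         on_error = c("abort", "skip")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) {
    vs_abort(paste0("cannot read reports: no such file: ", path),
             class = "vigisignal_io_error")
  }
  x <- if (format == "jsonl") read_reports_jsonl(path, on_error)
       else read_reports_delimited(path, on_error)
  # harmonise enum codes
  r <- x$reports
  r$reporter_qualification <- map_enum(r$reporter_qualification, .reporter_levels,
                                       "reporter_qualification")
  r$seriousness <- map_enum(r$seriousness, .seriousness_levels, "seriousness")
  r$outcome <- map_enum(r$outcome, .outcome_levels, "outcome")
  r$sex <- map_enum(r$sex, .sex_levels, "sex", unknown = NULL)
  x$reports <- r
  validate_icsr_set(x)
  x
}

read_reports_jsonl <- function(path, on_error) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines_present <- which(nzchar(trimws(lines)))
  parts <- vector("list", length(lines_present))
  rejected <- integer()
  for (i in seq_along(lines_present)) {
    ln <- lines_present[i]
    res <- tryCatch({
      rec <- jsonlite::fromJSON(lines[ln], simplifyVector = FALSE)
      parse_jsonl_record(rec, ln)
    }, vigisignal_record_error = function(e) e,
       error = function(e) {
      vs_abort(sprintf("line %d: not valid JSON: %s", ln, conditionMessage(e)),
               class = "vigisignal_io_error")
    })
    if (inherits(res, "condition")) {
      if (on_error == "abort") rlang::cnd_signal(res)
      rejected <- c(rejected, ln)
      next
    }
    parts[[i]] <- res
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(rejected)) {
    vs_warn(sprintf("skipped %d invalid record(s) at line(s) %s",
                    length(rejected), oxford(as.character(rejected))),
            class = "vigisignal_records_skipped")
  }
  out <- if (!length(parts)) empty_icsr_set() else icsr_set(
    dplyr::bind_rows(lapply(parts, `[[`, "report")),
    dplyr::bind_rows(lapply(parts, `[[`, "drugs")),
    dplyr::bind_rows(lapply(parts, `[[`, "reactions")),
    validate = FALSE
  )
  attr(out, "rejected_lines") <- rejected
  out
}

.delim_cols <- readr::cols(
  report_id = readr::col_character(), report_date = readr::col_character(),
  country = readr::col_character(), reporter_qualification = readr::col_character(),
  seriousness = readr::col_character(), outcome = readr::col_character(),
  age_years = readr::col_double(), sex = readr::col_character(),
  drug_seq = readr::col_integer(), drug_name = readr::col_character(),
  role = readr::col_character(), start_date = readr::col_character(),
  indication_pt = readr::col_character(),
  reaction_seq = readr::col_integer(), pt_name = readr::col_character(),
  onset_date = readr::col_character()
)

read_reports_delimited <- function(path, on_error) {
  df <- readr::read_csv(path, col_types = .delim_cols, na = "",
                        progress = FALSE)
  missing_cols <- setdiff(names(.delim_cols$cols), names(df))
  if (length(missing_cols)) {
    vs_abort(paste0("delimited file lacks required column(s): ", oxford(missing_cols)),
             class = "vigisignal_io_error")
  }
  if (!nrow(df)) return(empty_icsr_set())
  bad <- is.na(df$report_id) | is.na(df$drug_name) | is.na(df$pt_name)
  if (any(bad)) {
    rows <- which(bad) + 1L # +1 for the header line
    if (on_error == "abort") {
      vs_abort(sprintf("line %d: missing required field (report_id, drug_name or pt_name)",
                       rows[1]), class = "vigisignal_record_error")
    }
    bad_ids <- unique(df$report_id[bad])
    df <- df[!bad & !(df$report_id %in% bad_ids), ]
    vs_warn(sprintf("skipped invalid row(s) at line(s) %s", oxford(as.character(rows))),
            class = "vigisignal_records_skipped")
  }
  reports <- dplyr::distinct(df[, .report_cols], .data$report_id, .keep_all = TRUE)
  drugs <- dplyr::arrange(
    dplyr::distinct(df[, .drug_cols]),
    match(.data$report_id, reports$report_id), .data$drug_seq)
  reactions <- dplyr::arrange(
    dplyr::distinct(df[, .reaction_cols]),
    match(.data$report_id, reports$report_id), .data$reaction_seq)
  icsr_set(reports, drugs, reactions, validate = FALSE)
}

# ---- writing ---------------------------------------------------------------

#' Write a collection of ICSRs to disk
#'
#' The collection is validated before anything is written, so a failed
#' invariant never leaves a partial file behind. Writing then reading back
#' (same format) reproduces every field including missingness and date
#' precision.
#'
#' @param x an `icsr_set`.
#' @param path output file.
#' @param format `"jsonl"` (canonical) or `"delimited"`.
#' @return the number of reports written, invisibly.
#' @export
write_reports <- function(x, path, format = c("jsonl", "delimited")) {
  format <- match.arg(format)
  validate_icsr_set(x)
  if (format == "jsonl") {
    write_reports_jsonl(x, path)
  } else {
    write_reports_delimited(x, path)
  }
  invisible(n_reports(x))
}

write_reports_jsonl <- function(x, path) {
  if (!n_reports(x)) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(0L))
  }
  drugs_by <- split(x$drugs[, setdiff(.drug_cols, c("report_id", "drug_seq"))],
                    factor(x$drugs$report_id, levels = x$reports$report_id))
  rxn_by <- split(x$reactions[, setdiff(.reaction_cols, c("report_id", "reaction_seq"))],
                  factor(x$reactions$report_id, levels = x$reports$report_id))
  lines <- vapply(seq_len(n_reports(x)), function(i) {
    rec <- as.list(x$reports[i, ])
    rec$drugs <- lapply(seq_len(nrow(drugs_by[[i]])), function(j) as.list(drugs_by[[i]][j, ]))
    rec$reactions <- lapply(seq_len(nrow(rxn_by[[i]])), function(j) as.list(rxn_by[[i]][j, ]))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", null = "null",
                                  digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

write_reports_delimited <- function(x, path) {
  df <- dplyr::inner_join(x$drugs, x$reactions, by = "report_id",
                          relationship = "many-to-many")
  df <- dplyr::inner_join(x$reports, df, by = "report_id")
  df <- df[order(match(df$report_id, x$reports$report_id), df$drug_seq, df$reaction_seq), ]
  readr::write_csv(df[, names(.delim_cols$cols)], path, na = "", progress = FALSE)
}
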