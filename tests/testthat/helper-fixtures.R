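# Builders for small hand-made report collections used across tests.

drug_entry <- function(drug_name = "erlotinib", role = "suspected",
                       start_date = "2015-05-01", indication_pt = NA_character_) {
  tibble::tibble(drug_name = drug_name, role = role,
                 start_date = start_date, indication_pt = indication_pt)
}

reaction_entry <- function(pt_name = "Acute kidney injury",
                           onset_date = "2015-05-20") {
  tibble::tibble(pt_name = pt_name, onset_date = onset_date)
}

mk_report <- function(id, report_date = "2015-06-01", country = "FR",
                      reporter = "health_professional", seriousness = "serious",
                      outcome = "recovered", age = 65, sex = "male",
                      drugs = drug_entry(), reactions = reaction_entry()) {
  list(report = tibble::tibble(report_id = id,
                               report_date = as.character(report_date),
                               country = as.character(country),
                               reporter_qualification = reporter,
                               seriousness = seriousness, outcome = outcome,
                               age_years = as.numeric(age),
                               sex = as.character(sex)),
       drugs = tibble::tibble(report_id = id, drug_seq = seq_len(nrow(drugs)), drugs),
       reactions = tibble::tibble(report_id = id,
                                  reaction_seq = seq_len(nrow(reactions)), reactions))
}

mk_set <- function(...) {
  parts <- list(...)
  icsr_set(dplyr::bind_rows(lapply(parts, `[[`, "report")),
           dplyr::bind_rows(lapply(parts, `[[`, "drugs")),
           dplyr::bind_rows(lapply(parts, `[[`, "reactions")))
}

# small no-frills generator config for fast synthetic databases
quick_config <- function(n = 2000, seed = 1, ...) {
  synth_config(n_reports = n, seed = seed, ...)
}

renal_dict_path <- function() {
  system.file("extdata", "renal_hierarchy_synthetic.csv", package = "vigisignal")
}

study_hlts <- c("glomerulonephritis and nephrotic syndrome", "nephritis NEC",
                "nephropathies and tubular disorders NEC", "renal disorders NEC",
                "renal failure and impairment",
                "renal hypertension and related conditions",
                "renal vascular and ischaemic conditions")
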