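# Five-level term hierarchy (SOC > HLGT > HLT > PT > LLT).
#
# Adverse events in spontaneous reports are coded as preferred terms (PTs);
# a study defines its event set by naming high-level terms (HLTs) and
# taking every PT they contain. Licensed terminology cannot be
# redistributed, so the loader reads a user-supplied simplified extract
# (CSV with columns soc,hlgt,hlt,pt,llt); the package bundles a small
# hand-written synthetic renal hierarchy for tests and examples (see
# `system.file("extdata", "renal_hierarchy_synthetic.csv", package = "vigisignal")`).

#' Load a term dictionary from a delimited extract
#'
#' The extract has one row per hierarchy path with columns
#' `soc,hlgt,hlt,pt,llt`; `llt` may be blank. A PT may appear under
#' several HLTs (multi-axiality): every ancestry is retained. Duplicate
#' `(hlt, pt)` rows are merged, pooling their LLTs.
#'
#' @param path CSV file with header `soc,hlgt,hlt,pt,llt`.
#' @return a `term_dictionary`: list with `paths` (tibble of distinct
#'   soc/hlgt/hlt/pt rows) and `llts` (tibble pt/llt).
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) {
    vs_abort(paste0("cannot read dictionary: no such file: ", path),
             class = "vigisignal_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = "", progress = FALSE)
  need <- c("soc", "hlgt", "hlt", "pt", "llt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    vs_abort(paste0("dictionary lacks required column(s): ", oxford(missing_cols)),
             class = "vigisignal_io_error")
  }
  if (!nrow(df)) {
    vs_abort("dictionary file is empty: a term dictionary needs at least one path",
             class = "vigisignal_dict_error")
  }
  for (col in c("soc", "hlgt", "hlt", "pt")) {
    df[[col]] <- trimws(df[[col]])
    bad <- is.na(df[[col]]) | !nzchar(df[[col]])
    if (any(bad)) {
      vs_abort(sprintf("dictionary row(s) %s have a blank '%s' level",
                       oxford(as.character(which(bad) + 1L)), col),
               class = "vigisignal_dict_error")
    }
  }
  paths <- dplyr::distinct(df[, c("soc", "hlgt", "hlt", "pt")])
  llts <- dplyr::distinct(df[!is.na(df$llt) & nzchar(trimws(df$llt)),
                             c("pt", "llt")])
  structure(list(paths = paths, llts = llts), class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary> %d paths | %d SOC, %d HLGT, %d HLT, %d PT, %d LLT\n",
              nrow(x$paths), length(unique(x$paths$soc)), length(unique(x$paths$hlgt)),
              length(unique(x$paths$hlt)), length(unique(x$paths$pt)), nrow(x$llts)))
  invisible(x)
}

#' Expand high-level terms to their preferred-term event set
#'
#' Returns the union of PTs whose ancestry contains any of the requested
#' HLTs. Matching is case-insensitive on the full HLT string. An HLT name
#' absent from the dictionary is an error — a silent no-match would
#' corrupt the event set.
#'
#' @param dict a `term_dictionary` from [load_dictionary()].
#' @param hlt_names character vector of HLT names (non-empty).
#' @return sorted character vector of unique PT names.
#' @export
pts_for_hlts <- function(dict, hlt_names) {
  stopifnot(inherits(dict, "term_dictionary"))
  if (!length(hlt_names)) {
    vs_abort("hlt_names must contain at least one HLT", class = "vigisignal_usage_error")
  }
  want <- tolower(trimws(hlt_names))
  have <- tolower(dict$paths$hlt)
  unmatched <- hlt_names[!want %in% have]
  if (length(unmatched)) {
    vs_abort(paste0("HLT name(s) not found in dictionary: ", oxford(unmatched)),
             class = "vigisignal_dict_error")
  }
  sort(unique(dict$paths$pt[have %in% want]))
}
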