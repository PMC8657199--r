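# Parameter-recovery simulation for the screening pipeline.
#
# The exact 2x2 counts behind published RORs from access-restricted
# databases are generally unpublished, so the package validates its
# estimator by parameter recovery: plant a known drug-event odds ratio in
# synthetic databases, run the *entire* pipeline (generate, eligibility,
# window, screen) and check that the replicate-averaged ROR recovers the
# planted truth.

#' Planted odds-ratio recovery simulation
#'
#' Generates `n_replicates` synthetic databases in which reports exposed
#' to a single drug of interest carry the event PT with probability
#' `p_event_exposed` and unexposed reports with `p_event_unexposed`
#' (planted odds ratio
#' `odds(p_event_exposed) / odds(p_event_unexposed)`), runs the full
#' screening pipeline on each, and returns the per-replicate ROR point
#' estimates. Exposure is drawn per report, so the realised exposed count
#' is binomial with mean `n_exposed`.
#'
#' The simulated reports are fully observed (health-professional
#' reporters, complete demographics and dates, no duplicates planted),
#' so the eligibility stage runs but removes nothing; duplicate removal
#' is disabled since the generator plants none here.
#'
#' @param p_event_exposed event probability among exposed reports.
#' @param n_exposed,n_unexposed expected numbers of exposed and unexposed
#'   reports per replicate.
#' @param p_event_unexposed event probability among unexposed reports
#'   (default 0.02).
#' @param n_replicates number of replicates (default 25).
#' @param base_seed seed of the first replicate; replicate r uses
#'   `base_seed + r - 1`.
#' @param min_cases screening threshold passed to [screen()] (default 5);
#'   replicates whose case count falls below it carry a missing `ror` and
#'   `is_sdr = FALSE`, exactly as the screen reports them.
#' @return tibble with one row per replicate: `replicate`, `seed`, `a`
#'   (case count), `ror`, `ci_low` and `is_sdr`.
#' @examples
#' \donttest{
#' sim <- simulate_ror_recovery(0.05222, n_exposed = 5000, n_unexposed = 50000,
#'                              n_replicates = 5)
#' mean(sim$ror) # close to the planted odds ratio 2.70
#' }
#' @export
simulate_ror_recovery <- function(p_event_exposed, n_exposed, n_unexposed,
                                  p_event_unexposed = 0.02, n_replicates = 25,
                                  base_seed = 1, min_cases = 5) {
  stopifnot(p_event_exposed > 0, p_event_exposed < 1,
            p_event_unexposed > 0, p_event_unexposed < 1)
  theta <- (p_event_exposed / (1 - p_event_exposed)) /
    (p_event_unexposed / (1 - p_event_unexposed))
  n <- n_exposed + n_unexposed
  drug <- "drug of interest"
  pt <- "Event of interest"
  criteria <- eligibility_criteria(
    dedup = FALSE,
    window_start_by_drug = stats::setNames("2005-01-01", drug),
    window_end = "2020-12-01")
  rows <- lapply(seq_len(n_replicates), function(r) {
    seed <- base_seed + r - 1
    cfg <- synth_config(
      n_reports = n, seed = seed,
      drugs = tibble::tibble(name = drug, exposure_prob = n_exposed / n,
                             authorisation_date = "2005-01-01"),
      event_pts = tibble::tibble(pt_name = pt, baseline_prob = p_event_unexposed),
      background_pts = tibble::tibble(pt_name = "Diarrhoea", baseline_prob = 0.5),
      planted_or = tibble::tibble(drug = drug, pt = pt, theta = theta),
      role_probs = c(suspected = 1, interacting = 0, concomitant = 0),
      reporter_mix = c(health_professional = 1, non_health_professional = 0,
                       unknown = 0),
      p_missing_age = 0, p_missing_sex = 0, p_partial_date = 0,
      duplicate_rate = 0, date_range = c("2005-01-01", "2020-12-01"))
    db <- generate_database(cfg)
    eligible <- apply_eligibility(db, criteria)$eligible
    res <- screen(eligible, drug, pt, criteria, min_cases = min_cases)
    if (nrow(res$signals)) {
      tibble::tibble(replicate = r, seed = seed, a = res$signals$a[1],
                     ror = res$signals$ror[1], ci_low = res$signals$ci_low[1],
                     is_sdr = res$signals$is_sdr[1])
    } else {
      tibble::tibble(replicate = r, seed = seed, a = res$suppressed$a[1],
                     ror = NA_real_, ci_low = NA_real_, is_sdr = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}
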