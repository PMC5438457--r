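# Scenario runner: AASM versus unrestricted RDD, head to head.

#' Selection-probability table for multi-phone ownership
#'
#' Builds the closed-form illustration of how minute individual inclusion
#' probabilities are under national-scale RDD, across a grid of one-phone /
#' three-phone ownership mixes: per row, the number of phones held by each
#' group, the individual inclusion probability of a one-phone and a
#' three-phone owner (for a targeted sample of `n`), and their ratio, which
#' is always the phone-count ratio (3). Probabilities are reported to 3
#' significant figures.
#'
#' @param pct_one Proportions of the population owning exactly one phone
#'   (the rest own `multi_phones`).
#' @param population Population size (default 100 million phone owners).
#' @param multi_phones Phone count of the multi-phone group.
#' @param n Targeted sample size for the probability (default 1:
#'   an individual's chance per selected number).
#' @return A `data.frame` with columns `pct_one`, `phones_one`,
#'   `p_incl_one`, `pct_multi`, `phones_multi`, `p_incl_multi`,
#'   `relative_probability`.
#' @examples
#' selection_probability_table()
#' @export
selection_probability_table <- function(pct_one = seq(1, 0.5, by = -0.1),
                                        population = 1e8,
                                        multi_phones = 3, n = 1) {
  pct_multi <- 1 - pct_one
  if (any(pct_one < 0) || any(pct_one > 1))
    stop("ownership shares must lie in [0, 1] and sum to 1 per row")
  phones_one <- population * pct_one
  phones_multi <- population * pct_multi * multi_phones
  total <- phones_one + phones_multi
  data.frame(
    pct_one = pct_one,
    phones_one = phones_one,
    p_incl_one = signif(selection_probability(n, 1, total), 3),
    pct_multi = pct_multi,
    phones_multi = phones_multi,
    p_incl_multi = signif(selection_probability(n, multi_phones, total), 3),
    relative_probability = relative_probability(multi_phones, 1))
}

# Check up front that every positive quota is reachable at all.
check_fillable <- function(config, population, quota) {
  if (is.finite(config$call_ceiling)) return(invisible(TRUE))
  p <- population$persons
  owners <- tapply(p$n_phones >= 1, factor(p$stratum, levels = quota$stratum),
                   sum, default = 0L)
  bad <- quota$stratum[quota$target > 0 & owners == 0]
  if (length(bad))
    stop("unfillable quota without a stopping rule (call_ceiling is ",
         "infinite) in strata with no phone owners: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

arm_stats <- function(run, reference, truth_owner, truth_full) {
  ws <- run_weights(run, reference)
  s <- summary(ws)
  y <- run$respondents$outcome
  est_unw <- mean(y)
  est_ps <- weighted_estimate(y, ws$poststrat)
  est_final <- weighted_estimate(y, ws)
  strata <- run$strata
  list(
    completions = run$counters$completions,
    calls = run$counters$calls,
    stages = run$counters$stages,
    numbers_generated = run$counters$numbers_generated,
    replacements = run$counters$replacements,
    strata_closed = sum(strata$status == "closed"),
    strata_abandoned = sum(strata$status == "abandoned"),
    cv_wt = s$cv_poststrat, deff_wt = s$deff_poststrat,
    cv_final = s$cv, deff_final = s$deff,
    effective_n = s$n / s$deff_poststrat,
    estimate_unweighted = est_unw,
    estimate_poststrat = est_ps$estimate,
    estimate_final = est_final$estimate,
    se_poststrat = est_ps$se,
    bias_unweighted_vs_owner = est_unw - truth_owner,
    bias_poststrat_vs_owner = est_ps$estimate - truth_owner,
    bias_poststrat_vs_full = est_ps$estimate - truth_full)
}

#' Run the AASM-versus-unrestricted-RDD comparison
#'
#' Executes the full pipeline twice on one shared synthetic population and
#' identically seeded number frame — once with the AASM quota engine
#' (strata close at target) and once as unrestricted RDD (first `total_n`
#' completions, no strata closure) — then weights both samples against the
#' population's census reference and compares achieved strata counts, the
#' CV and Kish design effect of the poststratification weights, effective
#' sample sizes, and prevalence estimates against the phone-owner and
#' full-population truths. AASM samples match the reference by
#' construction, so their weights sit near 1; the gap in CV/deff is the
#' design's whole payoff.
#'
#' @param config An [mps_scenario()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return An object of class `mps_comparison`: per-arm statistics, the
#'   per-arm stratum ledgers, the truths, and the runs themselves.
#' @examples
#' \donttest{
#' rep <- run_scenario(scenario_preset("heterogeneous", total_n = 200L))
#' rep$arms$aasm$cv_wt < rep$arms$rdd$cv_wt
#' }
#' @export
run_scenario <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "mps_scenario"))
  population <- generate_population(config, seed = seed)
  reference <- reference_distribution(population)
  quota <- make_quota_plan(reference, config$total_n)
  check_fillable(config, population, quota)

  p <- population$persons
  truth_full <- mean(p$outcome)
  truth_owner <- mean(p$outcome[p$n_phones >= 1])

  run_aasm <- run_survey(config, population, mode = "aasm", quota = quota,
                         seed = seed)
  run_rdd <- run_survey(config, population, mode = "rdd", quota = quota,
                        seed = seed)

  structure(list(
    arms = list(aasm = arm_stats(run_aasm, reference, truth_owner, truth_full),
                rdd = arm_stats(run_rdd, reference, truth_owner, truth_full)),
    strata = list(aasm = run_aasm$strata, rdd = run_rdd$strata),
    truth = list(owner_population = truth_owner,
                 full_population = truth_full),
    seed = seed,
    runs = list(aasm = run_aasm, rdd = run_rdd)
  ), class = "mps_comparison")
}

#' @export
print.mps_comparison <- function(x, ...) {
  cat("<mps_comparison> AASM vs unrestricted RDD\n")
  cat(sprintf("  truth: owner population %.4f | full population %.4f\n",
              x$truth$owner_population, x$truth$full_population))
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf(
      "  %-4s: n=%d calls=%d CV_wt=%.4f deff_wt=%.4f eff_n=%.0f est=%.4f (unw %.4f)\n",
      arm, a$completions, a$calls, a$cv_wt, a$deff_wt, a$effective_n,
      a$estimate_poststrat, a$estimate_unweighted))
  }
  invisible(x)
}

#' Serialize a comparison report to a run directory
#'
#' Writes `report.json` (per-arm statistics and truths), per-arm stratum
#' ledgers, call logs and weight tables as CSV.
#'
#' @param report An `mps_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mps_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(arms = report$arms, truth = report$truth, seed = report$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (arm in names(report$strata)) {
    utils::write.csv(report$strata[[arm]],
                     file.path(dir, paste0("strata_", arm, ".csv")),
                     row.names = FALSE)
    write_call_log(report$runs[[arm]],
                   file.path(dir, paste0("call_log_", arm, ".csv")))
    write_weights(run_weights(report$runs[[arm]]),
                  file.path(dir, paste0("weights_", arm, ".csv")))
  }
  invisible(dir)
}
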