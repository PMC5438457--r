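#' Synthesize a stratified population with unequal phone ownership
#'
#' Realises the scenario's population model: per-stratum sizes are exact
#' (deterministic allocation, so the census reference distribution is exact),
#' while phone ownership, the number of phones per owner `T_i`, and the
#' binary health outcome are drawn stochastically from the configured
#' per-stratum probabilities. People with `T_i = 0` are unreachable by a
#' mobile phone survey — the presampling coverage gap.
#'
#' @param config An [mps_scenario()].
#' @param seed Integer seed; the population stream is derived from it, so
#'   the same `(config, seed)` always yields the identical population.
#' @return An object of class `mps_population`: a list with `persons` (one
#'   row per person: dimension levels, `stratum` key, `n_phones`,
#'   propensities, `outcome`, `household_id`, `non_primary`), the stratum
#'   table and the dimension declaration.
#' @examples
#' pop <- generate_population(scenario_preset("saturation"), seed = 1)
#' nrow(pop$persons)
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "mps_scenario"))
  validate_scenario(config)
  set.seed(derive_seed(seed, "population"))
  st <- config$strata
  dimn <- names(config$dims)
  n <- sum(st$size)
  idx <- rep(seq_len(nrow(st)), st$size)

  persons <- st[idx, dimn, drop = FALSE]
  rownames(persons) <- NULL
  persons$id <- seq_len(n)
  persons$stratum <- stratum_key(persons, dimn)

  owns <- stats::rbinom(n, 1L, st$ownership[idx]) == 1L
  counts <- as.integer(names(config$phone_counts))
  n_phones <- integer(n)
  n_phones[owns] <- counts[sample.int(length(counts), sum(owns),
                                      replace = TRUE,
                                      prob = config$phone_counts)]
  persons$n_phones <- n_phones

  persons$answer_propensity <-
    (st$answer_propensity %||% rep(config$answer_propensity, nrow(st)))[idx]
  persons$response_propensity <-
    (st$response_propensity %||% rep(config$response_propensity, nrow(st)))[idx]
  persons$outcome <- stats::rbinom(n, 1L, st$prevalence[idx])

  hh_sizes <- as.integer(names(config$household_sizes))
  if (length(hh_sizes) == 1L && hh_sizes == 1L) {
    persons$household_id <- persons$id
  } else {
    # households cut across strata: shuffle people, then chop into runs
    # whose lengths are drawn from the configured size distribution
    ord <- sample.int(n)
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, hh_sizes[sample.int(length(hh_sizes),
                                            ceiling(n / min(hh_sizes)),
                                            replace = TRUE,
                                            prob = config$household_sizes)])
    sizes <- sizes[cumsum(sizes) - sizes < n]
    hid <- rep(seq_along(sizes), sizes)[seq_len(n)]
    persons$household_id <- integer(n)
    persons$household_id[ord] <- hid
  }

  persons$non_primary <- if (config$shared_phone_rate > 0)
    stats::rbinom(n, 1L, config$shared_phone_rate) == 1L else rep(FALSE, n)

  persons <- persons[, c("id", dimn, "stratum", "n_phones",
                         "answer_propensity", "response_propensity",
                         "outcome", "household_id", "non_primary")]
  structure(list(persons = persons, strata = st, dims = config$dims),
            class = "mps_population")
}

#' @export
print.mps_population <- function(x, ...) {
  p <- x$persons
  cat("<mps_population>", nrow(p), "persons,",
      length(unique(p$stratum)), "strata\n")
  cat("  phone owners:", sum(p$n_phones >= 1),
      sprintf("(%.1f%%)", 100 * mean(p$n_phones >= 1)),
      "| total phones:", sum(p$n_phones), "\n")
  invisible(x)
}

#' Census-style reference distribution of strata proportions
#'
#' The strata-proportion benchmark that quota targets and poststratification
#' weights calibrate to — in practice supplied by a recent census or DHS
#' round; here read off the synthetic population. With
#' `owners_only = TRUE` the distribution is computed over phone owners
#' (`T_i >= 1`), i.e. the population actually reachable by the survey.
#'
#' @param population An `mps_population`.
#' @param owners_only Restrict to phone owners?
#' @return An object of class `mps_reference`: a `data.frame` with the
#'   dimension levels, `stratum`, `count` and `proportion` (summing to 1).
#' @export
reference_distribution <- function(population, owners_only = FALSE) {
  stopifnot(inherits(population, "mps_population"))
  p <- population$persons
  if (owners_only) p <- p[p$n_phones >= 1, , drop = FALSE]
  if (nrow(p) == 0) stop("empty population")
  dimn <- names(population$dims)
  keys <- stratum_key(population$strata, dimn)
  cnt <- as.integer(table(factor(p$stratum, levels = keys)))
  out <- cbind(population$strata[, dimn, drop = FALSE],
               stratum = keys, count = cnt,
               proportion = cnt / sum(cnt))
  rownames(out) <- NULL
  class(out) <- c("mps_reference", "data.frame")
  out
}

#' @rdname reference_distribution
#' @param reference An `mps_reference` (or compatible data.frame with
#'   `stratum` and `proportion` columns).
#' @param path CSV file path: one row per stratum, dimension-level columns
#'   plus `count` and `proportion`.
#' @export
write_reference <- function(reference, path) {
  utils::write.csv(as.data.frame(reference), path, row.names = FALSE)
  invisible(path)
}

#' @rdname reference_distribution
#' @export
read_reference <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = NA)
  if (!all(c("stratum", "proportion") %in% names(out)))
    stop("reference CSV must have `stratum` and `proportion` columns")
  out$stratum <- as.character(out$stratum)
  if (any(out$proportion < 0) || abs(sum(out$proportion) - 1) > 1e-9)
    stop("reference proportions must be non-negative and sum to 1")
  class(out) <- c("mps_reference", "data.frame")
  out
}

#' Quantify the phone-ownership coverage gap per stratum
#'
#' Reports, for each stratum, the fraction of people owning at least one
#' phone and the outcome prevalence among owners versus non-owners. The
#' owner/non-owner outcome gap is the component of survey bias that no
#' sampling design or weighting can remove — only direct study of
#' non-owners can. Strata with no owners are flagged `unreachable`; strata
#' with no non-owners have an undefined gap and are flagged
#' `no non-owners`.
#'
#' @param population An `mps_population`.
#' @return A `data.frame` with one row per stratum: `n`, `owners`,
#'   `ownership_rate`, `outcome_owners`, `outcome_nonowners`, `gap`, `flag`.
#' @export
ownership_gap_report <- function(population) {
  stopifnot(inherits(population, "mps_population"))
  p <- population$persons
  dimn <- names(population$dims)
  keys <- stratum_key(population$strata, dimn)
  f <- factor(p$stratum, levels = keys)
  own <- p$n_phones >= 1
  n <- as.integer(table(f))
  owners <- as.integer(tapply(own, f, sum, default = 0L))
  mean_if <- function(sel) {
    vapply(keys, function(k) {
      y <- p$outcome[p$stratum == k & sel]
      if (length(y)) mean(y) else NA_real_
    }, numeric(1), USE.NAMES = FALSE)
  }
  o_own <- mean_if(own)
  o_non <- mean_if(!own)
  flag <- rep("ok", length(keys))
  flag[owners == 0] <- "unreachable"
  flag[owners == n & n > 0] <- "no non-owners"
  out <- cbind(population$strata[, dimn, drop = FALSE],
               stratum = keys, n = n, owners = owners,
               ownership_rate = ifelse(n > 0, owners / n, NA_real_),
               outcome_owners = o_own, outcome_nonowners = o_non,
               gap = o_own - o_non, flag = flag)
  rownames(out) <- NULL
  out
}
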