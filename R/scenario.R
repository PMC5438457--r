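#' Declare a mobile-network-operator numbering plan
#'
#' Governments assign each mobile network operator (MNO) one or more
#' dialling prefixes (e.g. "017", "019"); random digit dialling generates
#' suffixes under these prefixes. Allocating generated numbers
#' proportionally to operator market share keeps the frame representative
#' of the subscriber base.
#'
#' @param prefix Character vector of digit-string prefixes.
#' @param share Numeric vector of market shares; must sum to 1.
#' @param suffix_length Integer number of random digits after the prefix.
#' @return A `data.frame` with columns `prefix`, `suffix_length`, `share`.
#' @examples
#' mno_plan(c("017", "019"), c(0.6, 0.4))
#' @export
mno_plan <- function(prefix, share, suffix_length = 7L) {
  stopifnot(is.character(prefix), length(prefix) >= 1)
  if (anyDuplicated(prefix)) stop("duplicate MNO prefixes: ",
                                  paste(prefix[duplicated(prefix)], collapse = ", "))
  if (length(share) != length(prefix)) stop("`share` must match `prefix` in length")
  if (any(share < 0) || abs(sum(share) - 1) > 1e-9)
    stop("MNO market shares must be non-negative and sum to 1")
  suffix_length <- as.integer(rep(suffix_length, length.out = length(prefix)))
  if (any(suffix_length < 1) || any(suffix_length > 9))
    stop("suffix_length must be between 1 and 9 digits")
  data.frame(prefix = prefix, suffix_length = suffix_length, share = share,
             stringsAsFactors = FALSE)
}

default_mno <- function() mno_plan(c("017", "019"), c(0.6, 0.4))

#' Build a stratum table from crossed demographic dimensions
#'
#' Expands the declared dimensions (e.g. sex x age band x residence) into
#' the full Cartesian grid of strata and attaches per-stratum population
#' sizes, phone-ownership probabilities and outcome prevalences. Vectors are
#' recycled across the grid, so single numbers give uniform strata.
#'
#' @param dims Named list of character level vectors, e.g.
#'   `list(sex = c("F", "M"), residence = c("urban", "rural"))`.
#' @param size Integer per-stratum population sizes (recycled).
#' @param ownership Probability that a stratum member owns at least one
#'   phone (recycled).
#' @param prevalence Prevalence of the binary health outcome (recycled).
#' @param ... Further per-stratum columns (e.g. `answer_propensity`),
#'   recycled likewise.
#' @return A `data.frame` with one row per stratum.
#' @export
make_strata <- function(dims, size, ownership = 1, prevalence = 0.3, ...) {
  stopifnot(is.list(dims), length(dims) >= 1, !is.null(names(dims)))
  if (any(!nzchar(names(dims)))) stop("all strata dimensions must be named")
  if (any(vapply(dims, length, 1L) == 0)) stop("empty strata dimension")
  grid <- expand.grid(dims, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  grid$size <- as.integer(rep_len(size, n))
  grid$ownership <- rep_len(ownership, n)
  grid$prevalence <- rep_len(prevalence, n)
  extra <- list(...)
  for (nm in names(extra)) grid[[nm]] <- rep_len(extra[[nm]], n)
  grid
}

#' Scenario configuration for a mobile phone survey simulation
#'
#' Bundles every knob of an end-to-end simulated survey: the synthetic
#' population (strata, phone ownership, outcome prevalence), the RDD frame
#' (MNO plans, nonworking fraction Y), the dialer (redial limit, replacement
#' mode, time-of-day weights), the AASM quota engine (total sample size,
#' stopping rules, snowball referral) and the master seed. Two runs from the
#' same configuration are identical.
#'
#' @param strata Stratum table as produced by [make_strata()]: the crossed
#'   demographic dimensions plus `size`, `ownership`, `prevalence` and
#'   optionally per-stratum `answer_propensity` / `response_propensity`.
#' @param dims Optional named list of dimension levels; inferred from the
#'   non-numeric columns of `strata` when `NULL`.
#' @param phone_counts Named probability vector over phone counts among
#'   owners, e.g. `c("1" = 0.85, "2" = 0.10, "3" = 0.05)`.
#' @param answer_propensity,response_propensity Global defaults for the
#'   probability of picking up a call and of agreeing to (and starting) the
#'   interview given pickup; per-stratum columns in `strata` override them.
#' @param dropout_rate Probability an admitted respondent drops out
#'   mid-interview (battery, network); dropouts do not fill quota.
#' @param shared_phone_rate Fraction of people flagged as non-primary users
#'   of a shared handset; they can only pick up during `shared_slot`.
#' @param shared_slot Time slot in which non-primary users are reachable.
#' @param household_sizes Named probability vector over household sizes;
#'   households only matter for snowball referral.
#' @param mno MNO numbering plans, see [mno_plan()].
#' @param nonworking_fraction True fraction Y of generated numbers that are
#'   nonworking (not attached to any handset).
#' @param operator_feedback If `TRUE`, dialling a nonworking number returns
#'   a digital invalid-number signal on the first call; if `FALSE`,
#'   nonworking numbers just never answer and must exhaust redials.
#' @param total_n Target number of completed interviews.
#' @param max_redials Number of redials after the first unanswered call
#'   before a number is reclassified as nonworking.
#' @param replacement `"staged"` replaces verified-nonworking numbers at the
#'   end of each operational stage (day/shift); `"automated"` replaces each
#'   one the moment it resolves.
#' @param slot_weights Named sampling weights over calling time slots
#'   (`morning`, `afternoon`, `evening`); must sum to 1.
#' @param call_ceiling Global stopping rule: abandon all open strata once
#'   this many calls have been placed.
#' @param effort_ceiling_factor Abandon a stratum once the number of
#'   respondents screened into it reaches `effort_ceiling_factor * target`
#'   while it remains open.
#' @param snowball Enable snowball referral: an excused respondent may hand
#'   the phone to a household member from a still-open stratum.
#' @param snowball_success Probability a referral attempt succeeds.
#' @param pool_multiplier Generated number pool size as a multiple of the
#'   inflated sample size ("an order of magnitude larger" = 10).
#' @param working_assignment `"exact"` places exactly `round(P * (1 - Y))`
#'   working numbers in a pool of size P; `"bernoulli"` draws each number's
#'   status independently.
#' @param seed Master seed; module streams are derived from it with
#'   [derive_seed()].
#' @return An object of class `mps_scenario`.
#' @seealso [scenario_preset()] for ready-made scenarios,
#'   [generate_population()], [run_scenario()].
#' @export
mps_scenario <- function(strata,
                         dims = NULL,
                         phone_counts = c(`1` = 0.85, `2` = 0.10, `3` = 0.05),
                         answer_propensity = 0.7,
                         response_propensity = 0.85,
                         dropout_rate = 0.05,
                         shared_phone_rate = 0,
                         shared_slot = "evening",
                         household_sizes = c(`1` = 1),
                         mno = default_mno(),
                         nonworking_fraction = 0.3,
                         operator_feedback = TRUE,
                         total_n = 1000L,
                         max_redials = 3L,
                         replacement = c("staged", "automated"),
                         slot_weights = c(morning = 1 / 3, afternoon = 1 / 3,
                                          evening = 1 / 3),
                         call_ceiling = 2e5,
                         effort_ceiling_factor = 50,
                         snowball = FALSE,
                         snowball_success = 0.5,
                         pool_multiplier = 10,
                         working_assignment = c("exact", "bernoulli"),
                         seed = 1L) {
  replacement <- match.arg(replacement)
  working_assignment <- match.arg(working_assignment)
  if (is.null(dims)) {
    reserved <- c("size", "ownership", "prevalence",
                  "answer_propensity", "response_propensity")
    dim_cols <- setdiff(names(strata), reserved)
    dims <- lapply(strata[dim_cols], function(x) unique(as.character(x)))
    names(dims) <- dim_cols
  }
  cfg <- structure(list(
    dims = dims, strata = strata, phone_counts = phone_counts,
    answer_propensity = answer_propensity,
    response_propensity = response_propensity,
    dropout_rate = dropout_rate,
    shared_phone_rate = shared_phone_rate, shared_slot = shared_slot,
    household_sizes = household_sizes,
    mno = mno, nonworking_fraction = nonworking_fraction,
    operator_feedback = operator_feedback,
    total_n = as.integer(total_n), max_redials = as.integer(max_redials),
    replacement = replacement, slot_weights = slot_weights,
    call_ceiling = call_ceiling,
    effort_ceiling_factor = effort_ceiling_factor,
    snowball = snowball, snowball_success = snowball_success,
    pool_multiplier = pool_multiplier,
    working_assignment = working_assignment,
    seed = as.integer(seed)
  ), class = "mps_scenario")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks every field of an [mps_scenario()] (probabilities in range,
#' distributions summing to 1, strata forming the full Cartesian grid of the
#' declared dimensions, ...) and stops with a message naming the offending
#' field on the first violation.
#'
#' @param cfg An `mps_scenario` (or a bare list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_scenario <- function(cfg) {
  fail <- function(field, msg) stop("config field `", field, "`: ", msg,
                                    call. = FALSE)
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      fail(field, "must be a probability in [0, 1]")
  }
  chk_dist <- function(x, field) {
    if (!is.numeric(x) || is.null(names(x)) || any(x < 0) ||
        abs(sum(x) - 1) > 1e-9)
      fail(field, "must be a named non-negative vector summing to 1")
  }
  if (!is.list(cfg$dims) || length(cfg$dims) == 0 || is.null(names(cfg$dims)))
    fail("dims", "must be a non-empty named list of level vectors")
  if (any(vapply(cfg$dims, length, 1L) == 0))
    fail("dims", "contains an empty strata dimension")
  st <- cfg$strata
  if (!is.data.frame(st) || nrow(st) == 0) fail("strata", "must be a non-empty data.frame")
  need <- c(names(cfg$dims), "size", "ownership", "prevalence")
  miss <- setdiff(need, names(st))
  if (length(miss)) fail("strata", paste("missing column(s):", paste(miss, collapse = ", ")))
  keys <- stratum_key(st, names(cfg$dims))
  if (anyDuplicated(keys)) fail("strata", "duplicate stratum rows")
  want <- stratum_key(expand.grid(cfg$dims, KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE), names(cfg$dims))
  if (!setequal(keys, want))
    fail("strata", "rows must form the full Cartesian product of `dims`")
  if (any(st$size < 0) || any(st$size != round(st$size)))
    fail("strata$size", "must be non-negative integers")
  if (sum(st$size) == 0) fail("strata$size", "population is empty")
  chk_prob(st$ownership, "strata$ownership")
  chk_prob(st$prevalence, "strata$prevalence")
  chk_dist(cfg$phone_counts, "phone_counts")
  cnt <- suppressWarnings(as.integer(names(cfg$phone_counts)))
  if (any(is.na(cnt)) || any(cnt < 1))
    fail("phone_counts", "names must be positive integer phone counts")
  chk_prob(cfg$answer_propensity, "answer_propensity")
  chk_prob(cfg$response_propensity, "response_propensity")
  chk_prob(cfg$dropout_rate, "dropout_rate")
  chk_prob(cfg$shared_phone_rate, "shared_phone_rate")
  chk_dist(cfg$household_sizes, "household_sizes")
  if (!is.data.frame(cfg$mno)) fail("mno", "must be an mno_plan() data.frame")
  mno_plan(cfg$mno$prefix, cfg$mno$share, cfg$mno$suffix_length) # revalidate
  y <- cfg$nonworking_fraction
  if (!is.numeric(y) || y < 0 || y >= 1)
    fail("nonworking_fraction", "must be in [0, 1)")
  if (cfg$total_n < 1) fail("total_n", "must be >= 1")
  if (cfg$max_redials < 0) fail("max_redials", "must be >= 0")
  if (!cfg$replacement %in% c("staged", "automated"))
    fail("replacement", "must be \"staged\" or \"automated\"")
  sw <- cfg$slot_weights
  if (is.null(names(sw)) || any(sw < 0) || abs(sum(sw) - 1) > 1e-9)
    fail("slot_weights", "must be named, non-negative and sum to 1")
  if (!cfg$shared_slot %in% names(sw))
    fail("shared_slot", "must be one of the configured slots")
  if (cfg$call_ceiling < 1) fail("call_ceiling", "must be >= 1")
  if (cfg$effort_ceiling_factor <= 0) fail("effort_ceiling_factor", "must be > 0")
  chk_prob(cfg$snowball_success, "snowball_success")
  if (cfg$pool_multiplier < 1) fail("pool_multiplier", "must be >= 1")
  invisible(cfg)
}

#' @export
print.mps_scenario <- function(x, ...) {
  cat("<mps_scenario>\n")
  cat("  dims:", paste(sprintf("%s(%d)", names(x$dims),
                               vapply(x$dims, length, 1L)), collapse = " x "),
      "=", nrow(x$strata), "strata\n")
  cat("  population:", sum(x$strata$size),
      "| ownership range:", paste(round(range(x$strata$ownership), 3), collapse = "-"), "\n")
  cat("  total_n:", x$total_n, "| Y:", x$nonworking_fraction,
      "| replacement:", x$replacement, "| seed:", x$seed, "\n")
  invisible(x)
}

age_bands <- c("18-29", "30-44", "45-59", "60-69", "70+")

#' Ready-made simulation scenarios
#'
#' @description
#' Named presets covering the situations the simulator is built to study:
#'
#' * `"saturation"`: universal single-phone ownership, uniform propensities
#'   — the degenerate benchmark in which weighting has nothing to correct.
#' * `"scenario_a"`: low, strongly age- and residence-graded mobile
#'   penetration (a market where phones have recently arrived); elderly and
#'   rural strata are nearly unreachable, so stopping rules matter.
#' * `"scenario_b"`: high penetration with a residual gradient (a mature
#'   market); quotas are fillable but unrestricted RDD still over-represents
#'   young urban owners.
#' * `"heterogeneous"`: the head-to-head AASM-vs-RDD scenario — 20 strata
#'   (sex x 5 age bands x urban/rural), ownership falling with age,
#'   rurality and female sex, outcome prevalence rising with age.
#' * `"table2_10pct"`: single stratum in which 90% of owners hold one phone
#'   and 10% hold three, the multi-phone illustration grid's 90/10 row.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [mps_scenario()] (e.g. `seed`,
#'   `total_n`).
#' @return An `mps_scenario`.
#' @export
scenario_preset <- function(name = c("saturation", "scenario_a", "scenario_b",
                                     "heterogeneous", "table2_10pct"), ...) {
  name <- match.arg(name)
  dims <- list(sex = c("F", "M"), age = age_bands,
               residence = c("urban", "rural"))
  grid <- expand.grid(dims, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  age_i <- match(grid$age, age_bands)
  prev_by_age <- c(0.10, 0.15, 0.25, 0.35, 0.45)
  own <- function(age_mult) {
    pmin(1, age_mult[age_i] *
           ifelse(grid$residence == "urban", 1, 0.75) *
           ifelse(grid$sex == "M", 1, 0.9))
  }
  args <- switch(name,
    saturation = list(
      strata = make_strata(dims, size = 500, ownership = 1,
                           prevalence = 0.3),
      phone_counts = c(`1` = 1), nonworking_fraction = 0.3, total_n = 500L),
    scenario_a = list(
      strata = cbind(grid, size = 2000L,
                     ownership = own(c(0.50, 0.35, 0.15, 0.05, 0.02)),
                     prevalence = prev_by_age[age_i]),
      nonworking_fraction = 0.5, total_n = 500L, call_ceiling = 5e4,
      effort_ceiling_factor = 25),
    scenario_b = list(
      strata = cbind(grid, size = 2000L,
                     ownership = own(c(0.99, 0.97, 0.92, 0.85, 0.70)),
                     prevalence = prev_by_age[age_i]),
      nonworking_fraction = 0.3, total_n = 1000L),
    heterogeneous = list(
      strata = cbind(grid, size = 2000L,
                     ownership = own(c(0.95, 0.90, 0.75, 0.55, 0.35)),
                     prevalence = prev_by_age[age_i]),
      nonworking_fraction = 0.3, total_n = 1000L),
    table2_10pct = list(
      strata = make_strata(list(group = "all"), size = 10000L,
                           ownership = 1, prevalence = 0.3),
      phone_counts = c(`1` = 0.9, `3` = 0.1),
      nonworking_fraction = 0, total_n = 500L)
  )
  do.call(mps_scenario, utils::modifyList(args, list(...)))
}

#' Read / write scenario configurations as YAML
#'
#' Scenario files carry the full experiment specification (strata table,
#' ownership model, MNO plans, dialer and quota settings, seed) so that a
#' run is reproducible from the file alone. The bundled presets are shipped
#' under `system.file("extdata/scenarios", package = "mpssim")`.
#'
#' @param path File path.
#' @param cfg An `mps_scenario`.
#' @return `read_scenario()` returns an `mps_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  scenario_from_list(raw)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "mps_scenario"))
  lst <- unclass(cfg)
  lst$strata <- lapply(seq_len(nrow(cfg$strata)), function(i)
    as.list(cfg$strata[i, , drop = FALSE]))
  lst$mno <- lapply(seq_len(nrow(cfg$mno)), function(i)
    as.list(cfg$mno[i, , drop = FALSE]))
  for (f in c("phone_counts", "household_sizes", "slot_weights"))
    lst[[f]] <- as.list(lst[[f]])
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

# Rebuild an mps_scenario from a parsed YAML/JSON list, with field-level
# error reporting for malformed files.
scenario_from_list <- function(raw) {
  need <- function(f) {
    if (is.null(raw[[f]])) stop("config field `", f, "`: missing", call. = FALSE)
    raw[[f]]
  }
  strata <- do.call(rbind, lapply(need("strata"), as.data.frame,
                                  stringsAsFactors = FALSE))
  mno_raw <- do.call(rbind, lapply(need("mno"), as.data.frame,
                                   stringsAsFactors = FALSE))
  as_dist <- function(f) {
    x <- need(f)
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  dims <- lapply(need("dims"), as.character)
  mps_scenario(
    strata = strata, dims = dims,
    phone_counts = as_dist("phone_counts"),
    answer_propensity = need("answer_propensity"),
    response_propensity = need("response_propensity"),
    dropout_rate = need("dropout_rate"),
    shared_phone_rate = raw$shared_phone_rate %||% 0,
    shared_slot = raw$shared_slot %||% "evening",
    household_sizes = as_dist("household_sizes"),
    mno = mno_plan(as.character(mno_raw$prefix), mno_raw$share,
                   mno_raw$suffix_length),
    nonworking_fraction = need("nonworking_fraction"),
    operator_feedback = need("operator_feedback"),
    total_n = need("total_n"),
    max_redials = need("max_redials"),
    replacement = need("replacement"),
    slot_weights = as_dist("slot_weights"),
    call_ceiling = need("call_ceiling"),
    effort_ceiling_factor = need("effort_ceiling_factor"),
    snowball = raw$snowball %||% FALSE,
    snowball_success = raw$snowball_success %||% 0.5,
    pool_multiplier = need("pool_multiplier"),
    working_assignment = raw$working_assignment %||% "exact",
    seed = need("seed")
  )
}
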