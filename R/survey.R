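# Survey engine: simulated dialling with accelerated sequential replacement
# and automated active strata monitoring (AASM).
#
# The engine state is an environment so the per-call bookkeeping (statuses,
# attempts, quota fill counts, effort counters, the call log) mutates in
# place; the public surface builds a state, advances it stage by stage and
# freezes it into a plain `mps_run` list at the end.

ST_UNRESOLVED <- 0L
ST_HOUSEHOLD <- 1L
ST_NONWORKING <- 2L
status_labels <- c("unresolved", "verified_household", "verified_nonworking")

SS_OPEN <- 1L
SS_CLOSED <- 2L
SS_ABANDONED <- 3L
strata_labels <- c("open", "closed", "abandoned")

# questionnaire modules whose order is randomized per completed interview,
# so every module gets a turn at the dropout-protected front position
survey_modules <- c("demographics", "ncd_risk_factors", "healthcare_access")

#' Build a quota plan from a reference distribution
#'
#' Converts census/DHS strata proportions into integer per-stratum targets
#' summing exactly to `total_n` (largest-remainder rounding). These targets
#' are the quotas AASM fills and closes.
#'
#' @param reference An [reference_distribution()] (or data.frame with
#'   `stratum` and `proportion` columns).
#' @param total_n Total number of completed interviews.
#' @return A `data.frame` of class `mps_quota` with `stratum`, `proportion`,
#'   `target`.
#' @examples
#' ref <- data.frame(stratum = c("A", "B", "C"), proportion = rep(1, 3) / 3)
#' make_quota_plan(ref, 100)$target # 34 33 33
#' @export
make_quota_plan <- function(reference, total_n) {
  stopifnot(is.data.frame(reference),
            all(c("stratum", "proportion") %in% names(reference)))
  if (nrow(reference) == 0) stop("empty reference distribution")
  if (total_n < 1) stop("total_n must be >= 1")
  if (any(reference$proportion < 0) ||
      abs(sum(reference$proportion) - 1) > 1e-9)
    stop("reference proportions must be non-negative and sum to 1")
  out <- data.frame(stratum = as.character(reference$stratum),
                    proportion = reference$proportion,
                    target = largest_remainder(reference$proportion, total_n),
                    stringsAsFactors = FALSE)
  class(out) <- c("mps_quota", "data.frame")
  out
}

#' Draw randomized time-of-day slots for calls
#'
#' Call times are randomized across configured slots so that people who use
#' a (possibly shared) phone at different times of day all have a chance of
#' being reached; evening targeting is expressed by skewing the weights.
#'
#' @param n Number of calls.
#' @param weights Named non-negative weights summing to 1.
#' @param seed Optional seed (`NULL` = current stream).
#' @return Character vector of slot names, length `n`.
#' @export
randomize_time_slots <- function(n, weights, seed = NULL) {
  if (is.null(names(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("slot weights must be named, non-negative and sum to 1")
  if (!is.null(seed)) set.seed(derive_seed(seed, "slots"))
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Create a dialer/AASM engine state
#'
#' Seeds the frame stream, generates the initial number pool
#' (`pool_multiplier` times the inflated sample size, with the first
#' `ceiling(total_n / (1 - Y))` numbers activated for dialling), assigns
#' working statuses and owners, initialises the quota ledger, then seeds the
#' dialer stream. The state is advanced with [run_stage()].
#'
#' @param config An [mps_scenario()].
#' @param population An `mps_population`.
#' @param mode `"aasm"` (quota engine active: strata close at target) or
#'   `"rdd"` (unrestricted: every screened respondent is admitted until
#'   `total_n` completions).
#' @param quota Optional [make_quota_plan()]; computed from the population's
#'   own reference distribution when `NULL`.
#' @param seed Master seed (defaults to `config$seed`).
#' @return An environment of class `mps_dialer_state`.
#' @export
new_dialer_state <- function(config, population, mode = c("aasm", "rdd"),
                             quota = NULL, seed = config$seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "mps_scenario"),
            inherits(population, "mps_population"))
  e <- new.env(parent = emptyenv())
  e$cfg <- config
  e$mode <- mode

  ref <- reference_distribution(population)
  if (is.null(quota)) quota <- make_quota_plan(ref, config$total_n)
  e$reference <- ref
  e$s_key <- quota$stratum
  e$s_target <- quota$target
  k <- length(e$s_key)
  e$s_filled <- integer(k)
  e$s_status <- ifelse(e$s_target == 0L, SS_CLOSED, SS_OPEN)
  e$s_effort <- integer(k)

  p <- population$persons
  e$p_answer <- p$answer_propensity
  e$p_resp <- p$response_propensity
  e$p_phones <- p$n_phones
  e$p_str <- match(p$stratum, e$s_key)
  e$p_house <- p$household_id
  e$p_nonprim <- p$non_primary
  e$p_outcome <- p$outcome
  e$p_done <- logical(nrow(p))

  # frame stream: initial pool + working/owner assignment
  set.seed(derive_seed(seed, "frame"))
  e$registry <- new_registry()
  e$inflated <- inflate_sample_size(config$total_n, config$nonworking_fraction)
  gen <- as.integer(ceiling(config$pool_multiplier * e$inflated))
  pool <- build_number_pool(config$mno, gen, registry = e$registry)
  pool <- assign_numbers(pool, population, config$nonworking_fraction,
                         method = config$working_assignment)
  e$population <- population
  e$n_number <- pool$number
  e$n_prefix <- pool$prefix
  e$n_batch <- pool$batch
  e$n_working <- pool$working
  e$n_owner <- pool$owner_id
  e$n_status <- rep(ST_UNRESOLVED, gen)
  e$n_attempts <- integer(gen)
  e$n_active <- c(rep(TRUE, min(e$inflated, gen)),
                  rep(FALSE, max(gen - e$inflated, 0L)))
  e$n_reclassified <- logical(gen)

  e$calls <- 0L
  e$stage <- 0L
  e$completions <- 0L
  e$replacements <- 0L
  e$nw_replaced <- 0L
  e$top_ups <- 0L
  e$hit_ceiling <- FALSE

  # call log (grown by doubling)
  e$log_cap <- 4096L
  e$l_n <- 0L
  for (col in c("l_stage", "l_number", "l_slot", "l_outcome",
                "l_respondent", "l_stratum", "l_referral", "l_modules"))
    assign(col, vector(if (col %in% c("l_stage", "l_respondent")) "integer"
                       else if (col == "l_referral") "logical"
                       else "character", e$log_cap), envir = e)

  set.seed(derive_seed(seed, paste0("dialer-", mode)))
  class(e) <- "mps_dialer_state"
  e
}

log_row <- function(e, number, slot, outcome, respondent = NA_integer_,
                    stratum = NA_character_, referral = FALSE,
                    modules = NA_character_) {
  i <- e$l_n + 1L
  if (i > e$log_cap) {
    e$log_cap <- e$log_cap * 2L
    for (col in c("l_stage", "l_number", "l_slot", "l_outcome",
                  "l_respondent", "l_stratum", "l_referral", "l_modules")) {
      v <- get(col, envir = e)
      length(v) <- e$log_cap
      assign(col, v, envir = e)
    }
  }
  e$l_stage[i] <- e$stage
  e$l_number[i] <- number
  e$l_slot[i] <- slot
  e$l_outcome[i] <- outcome
  e$l_respondent[i] <- respondent
  e$l_stratum[i] <- stratum
  e$l_referral[i] <- referral
  e$l_modules[i] <- modules
  e$l_n <- i
}

#' Screen an answering respondent into their stratum
#'
#' The opening questions of the interview establish the respondent's
#' demographic profile; screening maps them to a stratum and increments that
#' stratum's effort counter. Screening never touches fill counts.
#'
#' @param state An engine state.
#' @param person_id Integer person id.
#' @return The respondent's stratum key (character).
#' @export
screen_respondent <- function(state, person_id) {
  s <- state$p_str[person_id]
  if (is.na(s)) stop("respondent's attributes fall outside the declared strata")
  state$s_effort[s] <- state$s_effort[s] + 1L
  state$s_key[s]
}

#' Admit or excuse a screened respondent
#'
#' The AASM decision: a respondent is admitted if and only if their stratum
#' is still open; once a stratum's quota of completed interviews is met it
#' closes and later members are excused without further questions. In
#' unrestricted-RDD mode every respondent is admitted until the overall
#' completion target is reached.
#'
#' @param state An engine state.
#' @param stratum Stratum key.
#' @return `"admit"` or `"excuse"`.
#' @export
admit_or_excuse <- function(state, stratum) {
  if (state$mode == "rdd")
    return(if (state$completions < state$cfg$total_n) "admit" else "excuse")
  s <- match(stratum, state$s_key)
  if (is.na(s)) stop("unknown stratum: ", stratum)
  if (state$s_status[s] == SS_OPEN) "admit" else "excuse"
}

# Record a completed interview: only completions fill quota.
complete_interview <- function(e, s) {
  if (e$mode == "aasm" && e$s_status[s] != SS_OPEN)
    stop("invariant violation: admitting into a closed stratum")
  e$s_filled[s] <- e$s_filled[s] + 1L
  e$completions <- e$completions + 1L
  if (e$mode == "aasm" && e$s_filled[s] == e$s_target[s])
    e$s_status[s] <- SS_CLOSED
  paste(sample(survey_modules), collapse = ";")
}

snowball_attempt <- function(e, person, number, slot) {
  if (!e$cfg$snowball || e$mode != "aasm") return(invisible(NULL))
  hh <- which(e$p_house == e$p_house[person] & !e$p_done &
                e$s_status[e$p_str] == SS_OPEN)
  hh <- setdiff(hh, person)
  if (!length(hh)) return(invisible(NULL))
  if (stats::runif(1) >= e$cfg$snowball_success) return(invisible(NULL))
  m <- hh[sample.int(length(hh), 1L)]
  key <- screen_respondent(e, m)
  e$p_done[m] <- TRUE
  s <- e$p_str[m]
  if (stats::runif(1) < e$cfg$dropout_rate) {
    log_row(e, number, slot, "answered_dropout", m, key, referral = TRUE)
  } else {
    mods <- complete_interview(e, s)
    log_row(e, number, slot, "answered_complete", m, key, referral = TRUE,
            modules = mods)
  }
  invisible(m)
}

#' Place one call
#'
#' Simulates a single dial of an active pool number: nonworking numbers
#' yield an invalid-number signal (with operator feedback) or silence;
#' working numbers are answered with the owner's answer propensity
#' (modulated by time slot for non-primary users of shared phones), and
#' answered calls proceed through refusal, screening, quota admission,
#' possible mid-interview dropout, and possible snowball referral. Statuses,
#' attempt counts, quota ledger and call log are updated in place.
#'
#' @param state An engine state.
#' @param i Pool index of the number to dial.
#' @param slot Time slot of the call.
#' @return The call outcome (character), invisibly.
#' @export
dial <- function(state, i, slot) {
  e <- state
  if (e$n_status[i] == ST_NONWORKING)
    stop("program logic error: dialling a number already verified nonworking")
  e$calls <- e$calls + 1L
  e$n_attempts[i] <- e$n_attempts[i] + 1L
  num <- e$n_number[i]

  if (!e$n_working[i]) {
    if (e$cfg$operator_feedback) {
      e$n_status[i] <- ST_NONWORKING
      log_row(e, num, slot, "nonworking_signal")
      return(invisible("nonworking_signal"))
    }
    log_row(e, num, slot, "no_answer")
    return(invisible("no_answer"))
  }

  o <- e$n_owner[i]
  mod <- if (e$p_nonprim[o] && slot != e$cfg$shared_slot) 0 else 1
  if (stats::runif(1) >= e$p_answer[o] * mod) {
    log_row(e, num, slot, "no_answer")
    return(invisible("no_answer"))
  }

  # answered: the number is a verified household either way
  e$n_status[i] <- ST_HOUSEHOLD
  key <- e$s_key[e$p_str[o]]
  if (e$p_done[o]) {
    log_row(e, num, slot, "answered_excused", o, key)
    return(invisible("answered_excused"))
  }
  if (stats::runif(1) >= e$p_resp[o]) {
    e$p_done[o] <- TRUE
    log_row(e, num, slot, "answered_refused", o, key)
    return(invisible("answered_refused"))
  }
  key <- screen_respondent(e, o)
  s <- e$p_str[o]
  if (admit_or_excuse(e, key) == "excuse") {
    e$p_done[o] <- TRUE
    log_row(e, num, slot, "answered_excused", o, key)
    snowball_attempt(e, o, num, slot)
    return(invisible("answered_excused"))
  }
  e$p_done[o] <- TRUE
  if (stats::runif(1) < e$cfg$dropout_rate) {
    log_row(e, num, slot, "answered_dropout", o, key)
    return(invisible("answered_dropout"))
  }
  mods <- complete_interview(e, s)
  log_row(e, num, slot, "answered_complete", o, key, modules = mods)
  invisible("answered_complete")
}

survey_stopped <- function(e) {
  if (e$hit_ceiling) return(TRUE)
  if (e$mode == "rdd") e$completions >= e$cfg$total_n
  else all(e$s_status != SS_OPEN)
}

# Activate k numbers: surplus first, then freshly generated batches.
activate_numbers <- function(e, k) {
  idx <- which(!e$n_active)[seq_len(min(k, sum(!e$n_active)))]
  short <- k - length(idx)
  if (short > 0) {
    pool <- build_number_pool(e$cfg$mno, short, registry = e$registry)
    pool <- assign_numbers(pool, e$population, e$cfg$nonworking_fraction,
                           method = e$cfg$working_assignment)
    new_idx <- length(e$n_number) + seq_len(short)
    e$n_number <- c(e$n_number, pool$number)
    e$n_prefix <- c(e$n_prefix, pool$prefix)
    e$n_batch <- c(e$n_batch, pool$batch)
    e$n_working <- c(e$n_working, pool$working)
    e$n_owner <- c(e$n_owner, pool$owner_id)
    e$n_status <- c(e$n_status, rep(ST_UNRESOLVED, short))
    e$n_attempts <- c(e$n_attempts, integer(short))
    e$n_active <- c(e$n_active, logical(short))
    e$n_reclassified <- c(e$n_reclassified, logical(short))
    idx <- c(idx, new_idx)
  }
  e$n_active[idx] <- TRUE
  idx
}

# Reclassify unresolved numbers that have exhausted their redials.
reclassify_exhausted <- function(e, idx = seq_along(e$n_status)) {
  sel <- idx[e$n_status[idx] == ST_UNRESOLVED &
               e$n_attempts[idx] > e$cfg$max_redials]
  e$n_status[sel] <- ST_NONWORKING
  e$n_reclassified[sel] <- TRUE
  sel
}

#' Replace verified-nonworking numbers with fresh random numbers
#'
#' The accelerated-sequential-replacement bookkeeping step: unresolved
#' numbers past the redial budget are reclassified as nonworking, and every
#' number verified nonworking since the last replacement is replaced by one
#' fresh unique number (surplus pool first, new batches when the pool is
#' depleted), restoring the active pool size. In staged mode [run_stage()]
#' calls this at the end of each stage; in automated mode replacement
#' happens per resolution and this is a no-op for already-replaced numbers.
#'
#' @param state An engine state.
#' @return Integer number of replacements made, invisibly.
#' @export
sequential_replacement <- function(state) {
  e <- state
  reclassify_exhausted(e)
  k <- sum(e$n_status == ST_NONWORKING) - e$nw_replaced
  if (k > 0) {
    activate_numbers(e, k)
    e$nw_replaced <- e$nw_replaced + k
    e$replacements <- e$replacements + k
  }
  invisible(as.integer(max(k, 0L)))
}

#' Apply the stopping rules
#'
#' Abandons a still-open stratum once the screening effort mapped to it
#' reaches `effort_ceiling_factor * target`, and abandons all open strata
#' once the global call ceiling is hit — the escape hatch for quotas that
#' cannot be met because a population group is not reachable by phone.
#' Abandoned strata excuse all later members and never reopen.
#'
#' @param state An engine state.
#' @return Character vector of stratum keys abandoned by this check.
#' @export
apply_stopping_rule <- function(state) {
  e <- state
  open <- e$s_status == SS_OPEN
  hit <- open & e$s_effort >= e$cfg$effort_ceiling_factor * pmax(e$s_target, 1L)
  if (e$calls >= e$cfg$call_ceiling) {
    hit <- hit | open
    e$hit_ceiling <- TRUE
  }
  e$s_status[hit] <- SS_ABANDONED
  e$s_key[hit]
}

#' Run one operational stage of dialling
#'
#' Dials every active unresolved number at most once, in random order, with
#' randomized time slots. In staged replacement mode, numbers verified
#' nonworking during the stage are replaced in one batch at the end of the
#' stage (the end-of-day/shift bookkeeping); in automated mode each number
#' is replaced the moment it resolves and its replacement joins the same
#' stage's queue. Stops mid-stage as soon as the survey's stopping
#' condition is met.
#'
#' @param state An engine state.
#' @return Number of calls placed this stage, invisibly.
#' @export
run_stage <- function(state) {
  e <- state
  queue <- which(e$n_active & e$n_status == ST_UNRESOLVED)
  if (length(queue) == 0) return(invisible(0L))
  e$stage <- e$stage + 1L
  queue <- queue[sample.int(length(queue))]
  calls0 <- e$calls
  automated <- e$cfg$replacement == "automated"
  sw <- e$cfg$slot_weights
  pos <- 1L
  while (pos <= length(queue)) {
    if (survey_stopped(e)) break
    if (e$calls >= e$cfg$call_ceiling) {
      apply_stopping_rule(e)
      break
    }
    i <- queue[pos]
    slot <- sample(names(sw), 1L, prob = sw)
    dial(e, i, slot)
    if (automated) {
      reclassify_exhausted(e, i)
      if (e$n_status[i] == ST_NONWORKING) {
        new_idx <- activate_numbers(e, 1L)
        e$nw_replaced <- e$nw_replaced + 1L
        e$replacements <- e$replacements + 1L
        queue <- c(queue, new_idx)
      }
    }
    pos <- pos + 1L
  }
  sequential_replacement(e)
  apply_stopping_rule(e)
  invisible(e$calls - calls0)
}

#' Run a complete simulated survey
#'
#' Advances the engine stage by stage until the stopping condition holds:
#' in AASM mode, every stratum closed (quota met) or abandoned; in
#' unrestricted-RDD mode, the overall completion target reached. If the
#' active pool is exhausted before the survey completes, a fresh pool of
#' inflated-sample size is activated ("new pools can be generated").
#'
#' @inheritParams new_dialer_state
#' @return An object of class `mps_run`: the call log, final number pool,
#'   final stratum ledger, respondent table and run counters.
#' @examples
#' cfg <- scenario_preset("saturation", total_n = 50L)
#' pop <- generate_population(cfg, seed = 1)
#' run <- run_survey(cfg, pop, mode = "aasm", seed = 1)
#' run$counters$completions
#' @export
run_survey <- function(config, population, mode = c("aasm", "rdd"),
                       quota = NULL, seed = config$seed) {
  state <- new_dialer_state(config, population, mode = mode, quota = quota,
                            seed = seed)
  guard <- 0L
  while (!survey_stopped(state)) {
    if (!any(state$n_active & state$n_status == ST_UNRESOLVED)) {
      activate_numbers(state, state$inflated)
      state$top_ups <- state$top_ups + 1L
    }
    run_stage(state)
    guard <- guard + 1L
    if (guard > 10000L) stop("survey did not terminate within 10000 stages")
  }
  finalize_run(state)
}

finalize_run <- function(e) {
  n <- e$l_n
  log <- data.frame(
    stage = e$l_stage[seq_len(n)], number = e$l_number[seq_len(n)],
    time_slot = e$l_slot[seq_len(n)], outcome = e$l_outcome[seq_len(n)],
    respondent_id = e$l_respondent[seq_len(n)],
    stratum = e$l_stratum[seq_len(n)], referral = e$l_referral[seq_len(n)],
    modules = e$l_modules[seq_len(n)], stringsAsFactors = FALSE)
  pool <- data.frame(
    number = e$n_number, prefix = e$n_prefix, batch = e$n_batch,
    working = e$n_working, owner_id = e$n_owner,
    status = status_labels[e$n_status + 1L], attempts = e$n_attempts,
    active = e$n_active, reclassified = e$n_reclassified,
    stringsAsFactors = FALSE)
  strata <- data.frame(
    stratum = e$s_key, target = e$s_target, filled = e$s_filled,
    status = strata_labels[e$s_status], effort = e$s_effort,
    stringsAsFactors = FALSE)
  compl <- log[log$outcome == "answered_complete", , drop = FALSE]
  respondents <- data.frame(
    respondent_id = compl$respondent_id, stratum = compl$stratum,
    n_phones = e$p_phones[compl$respondent_id],
    outcome = e$p_outcome[compl$respondent_id],
    referral = compl$referral, stringsAsFactors = FALSE)
  structure(list(
    mode = e$mode, log = log, pool = pool, strata = strata,
    respondents = respondents, reference = e$reference,
    counters = list(calls = e$calls, stages = e$stage,
                    completions = e$completions,
                    replacements = e$replacements, top_ups = e$top_ups,
                    numbers_generated = nrow(pool),
                    hit_call_ceiling = e$hit_ceiling),
    config = e$cfg
  ), class = "mps_run")
}

#' @export
print.mps_run <- function(x, ...) {
  ct <- x$counters
  cat("<mps_run>", x$mode, "arm:", ct$completions, "completions in",
      ct$calls, "calls over", ct$stages, "stages\n")
  cat("  numbers generated:", ct$numbers_generated,
      "| replacements:", ct$replacements, "\n")
  st <- table(x$strata$status)
  cat("  strata:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Audit the replacement bookkeeping of a finished run
#'
#' Checks the conservation invariants of accelerated sequential
#' replacement: every generated number is in exactly one terminal state
#' (verified household, verified nonworking, or unresolved/never-dialled
#' surplus); no number exceeded its redial budget; nonworking numbers have
#' no owner; and the number of replacements equals the number of verified
#' nonworking numbers (reclassified unresolved included).
#'
#' @param run An `mps_run`.
#' @return A list with `ok` (logical) and the per-state `counts`,
#'   `replacements` and any `problems` found.
#' @export
audit_conservation <- function(run) {
  pool <- run$pool
  problems <- character(0)
  if (!all(pool$status %in% status_labels))
    problems <- c(problems, "unknown pool status")
  counts <- table(factor(pool$status, levels = status_labels))
  if (sum(counts) != nrow(pool))
    problems <- c(problems, "statuses do not partition the pool")
  if (any(pool$attempts > run$config$max_redials + 1L))
    problems <- c(problems, "a number exceeded max_redials + 1 attempts")
  if (any(!pool$working & !is.na(pool$owner_id)))
    problems <- c(problems, "nonworking number with an owner")
  if (any(pool$status == "verified_household" & !pool$working))
    problems <- c(problems, "nonworking number verified as household")
  if (any(pool$attempts > 0 & !pool$active))
    problems <- c(problems, "inactive number was dialled")
  nw <- sum(pool$status == "verified_nonworking")
  if (run$counters$replacements != nw)
    problems <- c(problems,
                  sprintf("replacements (%d) != verified nonworking (%d)",
                          run$counters$replacements, nw))
  list(ok = length(problems) == 0, counts = counts,
       replacements = run$counters$replacements, problems = problems)
}

#' Per-stratum nonresponse table of a run
#'
#' Computes the nonresponse rate f per stratum from the call log:
#' refusals and mid-interview dropouts over all eligible contacts
#' (refused + dropout + completed). Excused respondents are survey-design
#' exclusions, not nonresponse, and do not enter f.
#'
#' @param run An `mps_run`.
#' @return A `data.frame` with `group` (stratum key), `f`, `n_contacts`.
#' @export
nonresponse_table <- function(run) {
  lg <- run$log
  el <- lg[lg$outcome %in% c("answered_refused", "answered_dropout",
                             "answered_complete"), , drop = FALSE]
  if (nrow(el) == 0)
    return(data.frame(group = character(0), f = numeric(0),
                      n_contacts = integer(0)))
  grp <- factor(el$stratum)
  nonresp <- el$outcome != "answered_complete"
  f <- as.numeric(tapply(nonresp, grp, mean))
  data.frame(group = levels(grp), f = f,
             n_contacts = as.integer(table(grp)),
             stringsAsFactors = FALSE)
}

#' Export a run's call log or stratum ledger as CSV
#'
#' @param run An `mps_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_call_log <- function(run, path) {
  utils::write.csv(run$log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_log
#' @export
write_strata_table <- function(run, path) {
  utils::write.csv(run$strata, path, row.names = FALSE)
  invisible(path)
}
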