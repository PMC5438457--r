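# Engine states for op-level tests are built from small scenarios and then
# nudged directly (e.g. forcing a number nonworking) to pin down single-call
# behaviour.

make_state <- function(cfg, seed = 1, mode = "aasm") {
  pop <- generate_population(cfg, seed = seed)
  new_dialer_state(cfg, pop, mode = mode, seed = seed)
}

test_that("a nonworking number with operator feedback resolves on first dial", {
  cfg <- degenerate_scenario(nonworking_fraction = 0.5,
                             operator_feedback = TRUE)
  st <- make_state(cfg)
  i <- which(!st$n_working)[1]
  out <- dial(st, i, "morning")
  expect_equal(out, "nonworking_signal")
  expect_equal(st$n_status[i], 2L) # verified_nonworking
  expect_error(dial(st, i, "morning"), "verified nonworking")
})

test_that("without feedback a nonworking number must exhaust its redials", {
  cfg <- degenerate_scenario(nonworking_fraction = 0.5,
                             operator_feedback = FALSE, max_redials = 2L)
  st <- make_state(cfg)
  i <- which(!st$n_working)[1]
  for (k in 1:3) expect_equal(dial(st, i, "morning"), "no_answer")
  expect_equal(st$n_status[i], 0L)     # still unresolved
  sequential_replacement(st)
  expect_equal(st$n_status[i], 2L)     # reclassified nonworking
  expect_true(st$n_reclassified[i])
})

test_that("a sure-answering owner in an open stratum completes the survey", {
  cfg <- degenerate_scenario()
  st <- make_state(cfg)
  i <- which(st$n_working & st$n_active)[1]
  o <- st$n_owner[i]
  expect_equal(dial(st, i, "evening"), "answered_complete")
  expect_equal(st$n_status[i], 1L) # verified_household
  expect_equal(st$completions, 1L)
  expect_equal(st$s_filled[st$p_str[o]], 1L)
  # the completed interview records a randomized module order
  mods <- st$l_modules[st$l_n]
  expect_setequal(strsplit(mods, ";")[[1]],
                  c("demographics", "ncd_risk_factors", "healthcare_access"))
})

test_that("a never-answering owner is reclassified nonworking after redials", {
  cfg <- degenerate_scenario(answer_propensity = 0, max_redials = 3L)
  st <- make_state(cfg)
  i <- which(st$n_working & st$n_active)[1]
  for (k in 1:4) expect_equal(dial(st, i, "morning"), "no_answer")
  expect_equal(st$n_attempts[i], 4L)
  sequential_replacement(st)
  expect_equal(st$n_status[i], 2L)
})

test_that("a refusal is recorded distinctly and consumes the number", {
  cfg <- degenerate_scenario(response_propensity = 0)
  st <- make_state(cfg)
  i <- which(st$n_working & st$n_active)[1]
  expect_equal(dial(st, i, "morning"), "answered_refused")
  expect_equal(st$n_status[i], 1L) # verified household, but no interview
  expect_true(st$p_done[st$n_owner[i]])
  expect_equal(st$completions, 0L)
})

test_that("a stage dials every active unresolved number exactly once", {
  cfg <- degenerate_scenario(n = 100L, total_n = 90L)
  st <- make_state(cfg)
  n_active <- sum(st$n_active & st$n_status == 0L)
  run_stage(st)
  expect_equal(st$calls, n_active)
  expect_equal(st$l_n, n_active)
  expect_equal(anyDuplicated(st$l_number[seq_len(st$l_n)]), 0L)

  # all numbers resolved: a further stage places no calls
  st$n_status[st$n_status == 0L] <- 2L
  st$nw_replaced <- sum(st$n_status == 2L) # pretend already replaced
  before <- st$calls
  run_stage(st)
  expect_equal(st$calls, before)
})

test_that("a seeded stage re-run produces identical call records", {
  cfg <- scenario_preset("heterogeneous", total_n = 100L)
  logs <- lapply(1:2, function(k) {
    st <- make_state(cfg, seed = 5)
    run_stage(st)
    st$l_outcome[seq_len(st$l_n)]
  })
  expect_identical(logs[[1]], logs[[2]])
})

test_that("replacement adds exactly one fresh unique number per nonworking", {
  cfg <- degenerate_scenario(n = 200L, total_n = 150L,
                             nonworking_fraction = 0.4)
  st <- make_state(cfg)
  run_stage(st)
  nw <- sum(st$n_status == 2L)
  expect_gt(nw, 0)
  expect_equal(st$replacements, nw)
  # active pool restored: unresolved+household actives = inflated size
  expect_equal(sum(st$n_active), st$inflated + nw)
  expect_equal(anyDuplicated(st$n_number), 0L)
  # zero nonworking -> zero replacements
  cfg0 <- degenerate_scenario(total_n = 10L, nonworking_fraction = 0)
  st0 <- make_state(cfg0)
  run_stage(st0)
  expect_equal(st0$replacements, 0L)
})

test_that("time-slot randomization follows the configured weights", {
  expect_true(all(randomize_time_slots(50, c(evening = 1)) == "evening"))
  set.seed(8)
  slots <- randomize_time_slots(3000, c(morning = 1 / 3, afternoon = 1 / 3,
                                        evening = 1 / 3))
  counts <- table(slots)
  expect_true(all(abs(counts - 1000) <= 3 * sqrt(3000 * (1 / 3) * (2 / 3))))
  s1 <- randomize_time_slots(100, c(morning = 0.5, evening = 0.5), seed = 3)
  s2 <- randomize_time_slots(100, c(morning = 0.5, evening = 0.5), seed = 3)
  expect_identical(s1, s2)
  expect_error(randomize_time_slots(10, c(a = 0.5, b = 0.6)), "sum to 1")
})

test_that("contact frequency is proportional to phones owned", {
  # 10% of people own 3 phones, 90% own 1: over many dials the per-person
  # contact-rate ratio converges to 3 within Monte-Carlo error
  cfg <- scenario_preset("table2_10pct")
  pop <- generate_population(cfg, seed = 2)
  pool <- build_number_pool(cfg$mno, 20000, seed = 2)
  pool <- assign_numbers(pool, pop, Y = 0, seed = 2)
  contacts <- tabulate(pool$owner_id, nbins = nrow(pop$persons))
  g3 <- pop$persons$n_phones == 3
  m1 <- mean(contacts[!g3]); m3 <- mean(contacts[g3])
  se1 <- stats::sd(contacts[!g3]) / sqrt(sum(!g3))
  se3 <- stats::sd(contacts[g3]) / sqrt(sum(g3))
  ratio <- m3 / m1
  se_ratio <- ratio * sqrt((se1 / m1)^2 + (se3 / m3)^2)
  expect_lt(abs(ratio - 3), 3 * se_ratio)
})

test_that("every number ends in exactly one terminal state, replacements conserved", {
  for (mode in c("staged", "automated")) {
    cfg <- scenario_preset("heterogeneous", total_n = 150L, replacement = mode)
    pop <- generate_population(cfg, seed = 4)
    run <- run_survey(cfg, pop, mode = "aasm", seed = 4)
    audit <- audit_conservation(run)
    expect_true(audit$ok)
    expect_equal(sum(audit$counts), run$counters$numbers_generated)
    expect_equal(audit$replacements,
                 sum(run$pool$status == "verified_nonworking"))
  }
})

test_that("staged and automated modes complete the same respondents under degenerate propensities", {
  # all-or-nothing propensities and a quota covering the whole population:
  # both replacement modes must interview exactly the same people
  completed <- lapply(c("staged", "automated"), function(mode) {
    cfg <- degenerate_scenario(n = 40L, total_n = 40L,
                               nonworking_fraction = 0.4, replacement = mode,
                               seed = 21L)
    pop <- generate_population(cfg, seed = 21)
    run <- run_survey(cfg, pop, mode = "aasm", seed = 21)
    expect_equal(run$counters$completions, 40L)
    sort(run$respondents$respondent_id)
  })
  expect_identical(completed[[1]], completed[[2]])
})

test_that("non-primary users of shared phones only answer in the shared slot", {
  cfg <- degenerate_scenario(n = 60L, total_n = 30L, shared_phone_rate = 1,
                             slot_weights = c(morning = 1, afternoon = 0,
                                              evening = 0))
  st <- make_state(cfg)
  i <- which(st$n_working & st$n_active)[1]
  expect_equal(dial(st, i, "morning"), "no_answer")   # wrong slot
  expect_equal(dial(st, i, "evening"), "answered_complete")
})
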