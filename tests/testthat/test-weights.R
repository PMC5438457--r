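test_that("poststratification weights are reference over sample proportions", {
  ref <- data.frame(stratum = c("A", "B"), proportion = c(0.6, 0.4))
  w <- poststrat_weights(rep(c("A", "B"), each = 50), ref)
  expect_equal(unique(w[1:50]), 1.2)
  expect_equal(unique(w[51:100]), 0.8)
  # sample already at reference: all weights 1
  w1 <- poststrat_weights(rep(c("A", "B"), c(60, 40)), ref)
  expect_true(all(w1 == 1))
  expect_error(poststrat_weights(c("A", "C"), ref), "absent from reference")
  expect_error(poststrat_weights(character(0), ref), "empty sample")
  ref0 <- data.frame(stratum = c("A", "B"), proportion = c(1, 0))
  expect_error(poststrat_weights(c("A", "B"), ref0), "zero reference")
})

test_that("weighted strata shares equal the reference exactly after calibration", {
  set.seed(4)
  ref <- data.frame(stratum = letters[1:5],
                    proportion = c(0.3, 0.25, 0.2, 0.15, 0.1))
  for (i in 1:20) {
    samp <- sample(letters[1:5], 400, replace = TRUE)
    w <- poststrat_weights(samp, ref)
    shares <- tapply(w, factor(samp, levels = letters[1:5]), sum) / sum(w)
    expect_equal(as.numeric(shares), ref$proportion, tolerance = 1e-12)
  }
})

test_that("nonresponse factor is the inverse response rate", {
  expect_equal(nonresponse_factor(0), 1)
  expect_equal(nonresponse_factor(0.5), 2)
  expect_equal(nonresponse_factor(0.9), 10)
  expect_error(nonresponse_factor(1), "\\[0, 1\\)")
  # simulation oracle: a group of 200 with 50% response propensity gives an
  # inverse realized response rate near 2
  set.seed(12)
  responded <- stats::rbinom(200, 1, 0.5)
  r_hat <- 1 / mean(responded)
  expect_lt(abs(r_hat - 2), 3 * 2^2 * sqrt(0.25 / 200)) # delta-method 3 SE
  expect_equal(nonresponse_factor(1 - mean(responded)), r_hat)
})

test_that("multi-phone adjustment equalizes per-person contribution", {
  ws <- weight_set(rep("A", 4), normalize = FALSE)
  ws2 <- adjust_multiphone(ws, c(1, 2, 1, 2))
  expect_equal(ws2$A, c(1, 0.5, 1, 0.5))
  expect_error(adjust_multiphone(ws, c(1, 0, 1, 1)), ">= 1")
  # people contacted in proportion to their phone count contribute equally
  # after A = 1/T: simulated contact counts, weighted by 1/T
  set.seed(13)
  T_i <- sample(c(1L, 3L), 2000, replace = TRUE, prob = c(0.9, 0.1))
  contacts <- stats::rpois(2000, 5 * T_i) # contact rate proportional to T
  contrib <- contacts / T_i
  m1 <- mean(contrib[T_i == 1]); m3 <- mean(contrib[T_i == 3])
  se <- sqrt(stats::var(contrib[T_i == 1]) / sum(T_i == 1) +
               stats::var(contrib[T_i == 3]) / sum(T_i == 3))
  expect_lt(abs(m3 / m1 - 1), 3 * se / m1)
})

test_that("selection probabilities follow n * phones / total phones", {
  expect_equal(selection_probability(1, 1, 1e8), 1e-8)
  expect_equal(selection_probability(1, 3, 1.2e8), 2.5e-8)
  expect_equal(selection_probability(1, 1, 2e8), 5e-9)
  expect_equal(selection_probability(1000, 2, 1e8), 2e-5)
  expect_error(selection_probability(1, 1, 0), "positive")
  expect_error(selection_probability(1, 0, 10), ">= 1")
  expect_equal(relative_probability(3, 1), 3)
  expect_equal(relative_probability(1, 1), 1)
  expect_equal(relative_probability(2, 1), 2)
})

test_that("CV of weights is the population SD over the mean, scale invariant", {
  expect_equal(cv_weights(rep(2, 10)), 0)
  expect_equal(cv_weights(c(1, 3)), 0.5)
  set.seed(14)
  w <- stats::rlnorm(50)
  expect_equal(cv_weights(w), cv_weights(17.3 * w), tolerance = 1e-12)
  expect_error(cv_weights(c(1, -1)), "positive")
})

test_that("Kish design effect agrees with both closed forms", {
  expect_equal(kish_deff(rep(1, 5)), 1)
  w <- c(1, 1, 1, 3)
  expect_equal(kish_deff(w), 4 / 3)
  expect_equal(kish_deff(w), 4 * sum(w^2) / sum(w)^2)
  expect_equal(cv_weights(w)^2, 1 / 3)
  # deff >= 1 for any positive weights, and the identity
  # 1 + CV^2 = n * sum(w^2) / sum(w)^2 holds to 1e-12
  set.seed(15)
  for (i in 1:200) {
    w <- stats::rlnorm(sample(2:300, 1), sdlog = stats::runif(1, 0, 1.5))
    d <- kish_deff(w)
    expect_gte(d, 1)
    expect_equal(d, length(w) * sum(w^2) / sum(w)^2, tolerance = 1e-12)
  }
})

test_that("effective sample size is n over deff", {
  expect_equal(effective_n(rep(1, 100)), 100)
  expect_equal(effective_n(c(1, 1, 1, 3)), 3)
  set.seed(16)
  for (i in 1:20) {
    w <- stats::rlnorm(100)
    expect_lte(effective_n(w), 100)
  }
})

test_that("trimming clips, preserves the total and reduces the CV", {
  w <- c(1, 1, 10)
  tw <- trim_weights(w, upper = 2)
  expect_equal(tw, c(3, 3, 6))
  expect_equal(sum(tw), sum(w))
  expect_lt(cv_weights(tw), cv_weights(w))
  expect_equal(trim_weights(w, lower = 0.5, upper = 20), w) # containing bounds
  expect_error(trim_weights(w, lower = 3, upper = 2), "lower <= upper")
  set.seed(17)
  for (i in 1:20) {
    w <- stats::rlnorm(200, sdlog = 1)
    tw <- trim_weights(w, lower = 0.5, upper = 2)
    expect_equal(sum(tw), sum(w), tolerance = 1e-9)
    expect_lte(cv_weights(tw), cv_weights(w) + 1e-12)
  }
})

test_that("trimming heterogeneous strata weights shifts the estimate", {
  # two strata with different outcomes; trimming the large weight moves the
  # weighted mean away from the calibrated value
  y <- c(rep(1, 90), rep(0, 10))
  w <- c(rep(0.6 / 0.9, 90), rep(0.4 / 0.1, 10))
  est <- weighted_estimate(y, w)$estimate
  expect_equal(est, 0.6)
  tw <- trim_weights(w, upper = 2)
  est_t <- weighted_estimate(y, tw)$estimate
  expect_gt(abs(est_t - 0.6), 0.01)
})

test_that("weighted estimates restore the population mix", {
  # equal weights give the ordinary mean with variance sigma^2 / n
  y <- c(1, 0, 1, 1)
  est <- weighted_estimate(y, rep(1, 4))
  expect_equal(est$estimate, 0.75)
  expect_equal(est$deff, 1)
  expect_equal(est$variance, stats::var(y) / 4)
  # strata A all 1, B all 0, reference 0.6/0.4: any sample split
  # poststratifies back to 0.6
  ref <- data.frame(stratum = c("A", "B"), proportion = c(0.6, 0.4))
  for (nA in c(10, 50, 90)) {
    samp <- rep(c("A", "B"), c(nA, 100 - nA))
    w <- poststrat_weights(samp, ref)
    y <- as.numeric(samp == "A")
    expect_equal(weighted_estimate(y, w)$estimate, 0.6, tolerance = 1e-12)
  }
  expect_error(weighted_estimate(c(1, 0), c(1, 1, 1)), "differ in length")
})

test_that("weight sets compose factors multiplicatively and normalize to mean 1", {
  ws <- weight_set(c("A", "A", "B"), poststrat = c(1.2, 1.2, 0.8),
                   R = c(2, 2, 1), A = c(1, 0.5, 1))
  expect_equal(mean(ws$w), 1)
  raw <- c(1.2 * 2, 1.2 * 2 * 0.5, 0.8)
  expect_equal(ws$w, raw / mean(raw))
  s <- summary(ws)
  expect_equal(s$n, 3)
  expect_equal(s$deff, kish_deff(ws$w))
  expect_error(weight_set("A", poststrat = 0), "positive")
})

test_that("nonresponse adjustment maps group rates onto respondents", {
  ws <- weight_set(c("A", "B", "A"))
  tab <- data.frame(group = c("A", "B"), f = c(0.5, 0))
  ws2 <- adjust_nonresponse(ws, tab)
  expect_equal(ws2$R, c(2, 1, 2))
  expect_error(adjust_nonresponse(ws, data.frame(group = "A", f = 0.1)),
               "missing from nonresponse table")
})

test_that("poststratification removes differential-selection bias among owners", {
  # Stratum A: high ownership, eager answerers, prevalence 0.2;
  # stratum B: low ownership, reluctant answerers, prevalence 0.4.
  # The raw answered sample over-represents A; calibrating to the
  # owner-population strata distribution recovers the owner-population
  # prevalence, which no amount of weighting can do for non-owners.
  cfg <- two_strata_scenario(20000L, 20000L, ownership = c(0.9, 0.3),
                             prevalence = c(0.2, 0.4),
                             phone_counts = c(`1` = 1))
  cfg$strata$answer_propensity <- c(0.9, 0.3)
  pop <- generate_population(cfg, seed = 18)
  owners <- pop$persons[pop$persons$n_phones >= 1, ]
  truth_owner <- mean(owners$outcome)

  set.seed(18)
  n <- 5000L
  pool <- build_number_pool(cfg$mno, 30000)
  pool <- assign_numbers(pool, pop, Y = 0)
  answered <- stats::runif(nrow(pool)) <
    pop$persons$answer_propensity[pool$owner_id]
  resp <- pool$owner_id[answered][seq_len(n)]
  y <- pop$persons$outcome[resp]
  strat <- pop$persons$stratum[resp]

  ref_own <- reference_distribution(pop, owners_only = TRUE)
  w <- poststrat_weights(strat, ref_own)
  est <- weighted_estimate(y, w)
  se_unw <- sqrt(mean(y) * (1 - mean(y)) / n)
  expect_lt(abs(est$estimate - truth_owner), 3 * est$se)   # bias removed
  expect_gt(abs(mean(y) - truth_owner), 3 * se_unw)        # raw mean biased
  # calibration is exact
  shares <- tapply(w, factor(strat, levels = ref_own$stratum), sum) / sum(w)
  expect_equal(as.numeric(shares), ref_own$proportion, tolerance = 1e-12)
})
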