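# Shared fixture scenarios, built in code.

# Two strata A/B with configurable sizes and ownership; single dimension.
two_strata_scenario <- function(size_a = 500L, size_b = 500L,
                                ownership = c(1, 1),
                                prevalence = c(0.3, 0.3), ...) {
  strata <- make_strata(list(group = c("A", "B")),
                        size = c(size_a, size_b),
                        ownership = ownership, prevalence = prevalence)
  mps_scenario(strata = strata, ...)
}

# Degenerate saturation: everyone owns exactly one phone, always answers,
# always completes.
degenerate_scenario <- function(n = 100L, total_n = 20L, ...) {
  args <- list(
    size_a = n %/% 2L, size_b = n - n %/% 2L,
    phone_counts = c(`1` = 1),
    answer_propensity = 1, response_propensity = 1, dropout_rate = 0,
    nonworking_fraction = 0, total_n = total_n)
  do.call(two_strata_scenario, utils::modifyList(args, list(...)))
}
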