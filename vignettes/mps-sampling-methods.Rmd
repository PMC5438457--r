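---
title: "Simulating mobile phone surveys: RDD frames, active strata monitoring, and weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mobile phone surveys: RDD frames, active strata monitoring, and weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpssim)
```

## The problem

Mobile phone surveys (MPS) in low- and middle-income countries sample from
the population of mobile phone owners by random digit dialling (RDD):
candidate numbers are generated under the prefixes that governments assign
to mobile network operators, dialled, and the people who answer are
interviewed about health outcomes (here, a binary indicator such as a
noncommunicable-disease risk factor). Three things stand between that
procedure and a representative estimate:

1. **Coverage.** Phone ownership is unequal — typically lower among older,
   female and rural populations — so the frame of phone owners is a biased
   subset of the population.
2. **Selection among owners.** Nonworking numbers, differential answering
   behaviour and multiple-phone ownership distort who, among owners, ends
   up in the sample. A person with $T_i$ phones is contacted at $T_i$ times
   the rate of a single-phone owner.
3. **Weighting costs precision.** Poststratification can repair the
   realized sample composition, but variable weights inflate the variance
   of every estimate by the Kish design effect
   $\mathrm{deff}_{wt} = 1 + CV^2_{wt}$, where $CV_{wt}$ is the
   coefficient of variation of the weights.

Automated active strata monitoring (AASM) attacks the third point at the
sampling stage: because MPS calls are cheap and screened in real time, the
survey can hold a quota for every demographic stratum (from census or DHS
proportions), admit an answering respondent only while their stratum is
open, and close each stratum the moment its quota of completed interviews
is met. A sample built this way already matches the reference
distribution, so the poststratification weights all sit near 1 and the design effect stays
near its floor of 1.

`mpssim` implements this whole pipeline as a seeded simulator, so the
claims above become measurable: the same synthetic population can be
surveyed with and without AASM and the two weight distributions compared.

## The simulation model

### Population

A population is declared per stratum (by default sex x five age bands x
urban/rural). Per-stratum sizes are **exact** — deterministic allocation,
so the census-style reference distribution read off the population is
exact — while everything individual is stochastic: a person owns at least
one phone with the stratum's ownership probability; owners draw their
phone count $T_i$ from a configurable distribution (default
$\Pr(1)=0.85$, $\Pr(2)=0.10$, $\Pr(3)=0.05$; a preset with only 1 or 3
phones reproduces the closed-form illustration grid); the binary outcome
is Bernoulli with the stratum's prevalence. People with $T_i = 0$ are
unreachable, which is precisely the coverage gap: `ownership_gap_report()`
quantifies it, and nothing downstream ever repairs it. That is a modelling
statement, not an accident — weighting repairs the composition of the
*owner* sample, never the absence of non-owners.

### Frame

`build_number_pool()` allocates generated numbers across operator prefixes
exactly proportionally to market share (largest-remainder rounding, so the
shares are testable identities rather than expectations) and guarantees
uniqueness across every batch of a run through a registry. A fraction $Y$
of generated numbers is nonworking. We model the working share of a pool
as **fixed** (`working_assignment = "exact"`): the operator's subscription
census is a fixed set, so a large generated pool contains essentially a
fixed fraction $1-Y$ of working numbers, with the randomness living in
*which* numbers are working and which handset each one reaches.
Replacement batches use stochastic rounding so the expected share stays
exactly $1-Y$; a per-number Bernoulli mode is available for comparison.
Under the exact model the classical inflation rule — dial
$\lceil n/(1-Y)\rceil$ numbers to obtain $n$ working contacts — holds in
expectation with equality, which is what the calibration test asserts.

Each working number reaches a phone slot (person repeated $T_i$ times)
chosen uniformly at random, independently per number: generated numbers
are a sparse sample of a vast number space, so collisions on a single
handset are rare and harmless, and per-person contact rates are exactly
proportional to $T_i$.

### Dialler and replacement

Calls have three statuses: *verified household*, *verified nonworking*,
and *unresolved*. With operator feedback enabled a nonworking number
resolves on its first dial; otherwise it must exhaust the redial budget
(`max_redials`, default 3 — the field practice is "a predetermined number"
and we had to fix one) before being reclassified nonworking. Accelerated
sequential replacement then replaces every verified-nonworking number with
exactly one fresh unique number, either at the end of each operational
stage (`"staged"`, the traditional end-of-shift bookkeeping) or the moment
each number resolves (`"automated"`). The conservation audit
(`audit_conservation()`) checks the books: every generated number ends in
exactly one terminal state and replacements equal verified-nonworking
numbers, reclassifications included.

Answered calls proceed through refusal (recorded distinctly from
no-answer, because refusals feed the nonresponse adjustment), screening,
quota admission, and a Bernoulli mid-interview dropout (battery/network;
dropouts never fill quota). Call times are randomized over morning /
afternoon / evening slots; people flagged as non-primary users of a shared
handset answer only in the configured shared slot, a deliberately minimal
mechanism for phone sharing. Completed interviews record a random
permutation of the questionnaire modules, so no module is systematically
exposed to late-interview dropout.

### Quota engine

`make_quota_plan()` turns reference proportions into integer targets
(largest remainder, summing exactly to `total_n`). Screening maps each
answering, non-refusing respondent to a stratum and increments its effort
counter; `admit_or_excuse()` admits if and only if the stratum is open.
Only *completions* increment the fill count — admitting-then-dropping-out
does not — and a stratum closes exactly when filled reaches target.
People are never interviewed twice (sampling without replacement), and
closed strata never reopen; excused respondents are logged for the effort
accounting.

Two escape hatches handle unfillable quotas: a per-stratum effort ceiling
(abandon after `effort_ceiling_factor x target` screenings while still
open; default 50, a value we fixed since field practice names none) and a
global call ceiling that abandons all open strata. A stratum with zero
phone owners generates no screenings at all, so only the global ceiling
can retire it; `run_scenario()` refuses configurations where such a
stratum is paired with an infinite ceiling. Optional snowball referral
lets an excused respondent hand the phone to a household member from a
still-open stratum — the one mechanism that reaches phone-less people, at
the price of a nonprobabilistic step (referrals are flagged in the log).
Households default to size 1, which disables the mechanism.

### Weighting

Three factors compose multiplicatively (order is immaterial for a
product): poststratification $w_h = \pi_h / p_h$ (reference over sample
proportion), the nonresponse factor $R_i = 1/(1-f_i)$ with $f_i$ the
group's nonresponse rate (refusals plus dropouts over eligible contacts —
excused respondents are design exclusions, not nonresponse), and the
multi-phone factor $A_i = 1/T_i$. The final weights are normalised to
mean 1, which changes nothing reported. The nonresponse factor's
inverse-response-rate form is the standard one consistent with "$f$ is the
nonresponse rate"; we document it as an interpretation since only the
rate itself is pinned down externally.

Diagnostics use the divide-by-$n$ (population) variance in
$CV_{wt}$, under which the Kish identity
$1 + CV^2_{wt} \equiv n\sum w_i^2 / (\sum w_i)^2$ is exact — the test
suite property-checks it to $10^{-12}$. `weighted_estimate()` reports the
Kish approximation $\widehat{\mathrm{var}} = (s^2_y/n)\,\mathrm{deff}$,
labelled as an approximation. `trim_weights()` clips to bounds and
rescales to preserve the weight total; it provably cannot raise the CV,
and the tests demonstrate the bias it can introduce on heterogeneous
strata.

### Which truth a calibrated estimate recovers

Calibrating to the *owner-population* strata distribution makes the
weighted estimate consistent for the owner-population prevalence: within a
stratum, being contacted and answering is independent of the outcome, so
poststratification removes all selection bias *among owners* (the
differential-ownership test asserts this at $n = 5000$ within 3
Monte-Carlo SEs, while the unweighted estimate stays biased). Calibrating
to the census distribution instead targets the census mix of
owner-conditional means — equal to the full-population prevalence only if
owners and non-owners share outcome distributions within strata. The
comparison report therefore states bias against both truths and asserts
nothing about the non-owner gap.

## Head-to-head design

`run_scenario()` runs both arms — AASM and unrestricted RDD (identical
pipeline, admission unconditional until `total_n` completions; the
cleanest isolation of the quota engine) — against the *same* population
and identically seeded initial frame. The master seed spawns named
substreams (population / frame / dialler) via `derive_seed()`, so
toggling one module never perturbs another's draws and every run is
bit-reproducible. The headline comparison is on the poststratification
factor's CV and deff, since that is the component quota sampling is
designed to shrink; the fully composed weights are reported alongside.

## Default study conditions

The `heterogeneous` preset is the reference condition for the comparison:
40 000 people in 20 strata (2 000 each), ownership the product of age
(0.95 down to 0.35 across bands), residence (rural x 0.75) and sex
(female x 0.9) multipliers — a range of 0.24 to 0.95 spanning the
gradients typically reported — prevalence rising with age from 0.10 to
0.45, answer propensity 0.7, response propensity 0.85, dropout 0.05,
nonworking fraction $Y = 0.3$, and 1 000 completions per arm. Since the
schematic low/high-penetration pictures this emulates are not quantified
anywhere, these values are illustrative choices fixed once, not
calibrated estimates. The test suite runs this comparison at 1 000
completions per arm, the Monte-Carlo contact-rate check at $10^5$
generated numbers, the calibration check at 1 000 replicates of
$n = 200$, and the bias-removal check at $n = 5000$ — sizes at which the
asserted effects dwarf their Monte-Carlo errors.

## What passing tests do and do not show

The generator draws independent Bernoulli individuals inside exactly-sized
strata; real populations have household clustering of both phones and
outcomes, interviewer effects, day-of-week structure, and ownership
correlated with the outcome *within* strata. Passing tests show the
machinery is correct and that AASM's variance advantage holds under
honest, unequal-ownership conditions; they do not show that any particular
real survey's biases are captured, and nothing here measures — or could
measure — the non-owner coverage gap. Known limitations, by design: no
geographic/mobility modelling, no panel structure, no raking over multiple
margins, no replication-based variance estimation, and a refusal
terminalises its number (no callbacks), a choice we made explicit rather
than found in field practice.
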