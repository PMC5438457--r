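# mpssim

Simulation and statistics for **mobile phone surveys (MPS)** sampled by
random digit dialling (RDD), built for survey methodologists studying
health surveys in settings where phone ownership is widespread but
unequal.

Household surveys of noncommunicable-disease risk factors increasingly
move from face-to-face interviews to automated mobile phone calls. That
shift raises a chain of statistical questions this package makes
computable on synthetic populations:

- **Frame**: generate unique candidate numbers under mobile-operator
  prefixes, proportionally to market share; estimate the nonworking
  fraction *Y* from a test pool; inflate the dialling target by
  `ceiling(n / (1 - Y))`.
- **Dialling**: simulate call outcomes (invalid-number signals,
  no-answers, refusals, dropouts) with *accelerated sequential
  replacement* — every number verified nonworking, including unresolved
  numbers past the redial budget, is replaced by a fresh unique number,
  either per stage (end of shift) or automatically per resolution.
- **AASM — automated active strata monitoring**: real-time quota
  sampling. Each answering respondent is screened into a demographic
  stratum; they are interviewed only while their stratum is open, and a
  stratum closes the moment its quota (census/DHS proportion x *n*) of
  completed interviews is met. Stopping rules and snowball referral
  handle hard-to-reach strata.
- **Weighting**: poststratification `w_h = reference_h / sample_h`,
  nonresponse factor `R = 1 / (1 - f)`, multi-phone factor `A = 1 / T_i`,
  weight trimming, and the Kish diagnostics
  `deff_wt = 1 + CV²_wt = n Σw² / (Σw)²` with effective sample size
  `n / deff`. The individual selection probability is
  `n · N_p / N_T` (phones owned over total phones), so a three-phone
  owner is included at exactly three times the rate of a one-phone owner
  — while remaining, in a national number space, vanishingly unlikely to
  be called at all.

The headline experiment, `run_scenario()`, surveys one synthetic
population twice — with the AASM quota engine and as unrestricted RDD —
and shows that quota-exact sampling collapses the variability of the
poststratification weights and with it the design effect.

## Worked example

```r
library(mpssim)

cfg <- scenario_preset("heterogeneous", seed = 42L)  # 20 strata, ownership 0.24-0.95
rep <- run_scenario(cfg)
print(rep)
#> <mps_comparison> AASM vs unrestricted RDD
#>   truth: owner population 0.2216 | full population 0.2602
#>   aasm: n=1000 calls=5868 CV_wt=0.0000 deff_wt=1.0000 eff_n=1000 est=0.2700 (unw 0.2700)
#>   rdd : n=1000 calls=2454 CV_wt=0.4857 deff_wt=1.2359 eff_n=809 est=0.2958 (unw 0.2440)
```

Reading this: both arms completed 1000 interviews on the same population
and number frame. The AASM sample matches the census reference by
construction, so its poststratification weights are constant
(`CV_wt = 0`, `deff_wt = 1`) and all 1000 interviews count. The
unrestricted-RDD sample over-represents high-ownership strata; repairing
it needs weights with `CV_wt = 0.49`, inflating variance by
`deff_wt = 1.24` and shrinking the effective sample to 809. AASM costs
more calls (5868 vs 2454) — the price of filling the slow strata — and
buys precision. The unweighted RDD estimate (0.2440) differs from its
poststratified repair (0.2958); neither arm can say anything about the
0.039 gap between owner-population and full-population truth, which is a
coverage problem, not a weighting problem (`ownership_gap_report()`
quantifies it).

The closed-form selection-probability grid:

```r
selection_probability_table()[2, ]
#>   pct_one phones_one p_incl_one pct_multi phones_multi p_incl_multi relative_probability
#> 2     0.9      9e+07   8.33e-09       0.1        3e+07      2.5e-08                    3
```

With 90 million one-phone owners and 10 million three-phone owners
(120 million phones), a one-phone owner's inclusion probability per
selected number is 8.33e-09, a three-phone owner's 2.5e-08 — exactly
threefold, and still infinitesimal.

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mps-sim.R", package="mpssim"))')" \
  simulate --config inst/extdata/scenarios/heterogeneous.yaml --seed 42 --out runs/demo
```

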