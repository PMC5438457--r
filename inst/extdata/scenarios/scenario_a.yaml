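dims:
  sex:
  - F
  - M
  age:
  - 18-29
  - 30-44
  - 45-59
  - 60-69
  - 70+
  residence:
  - urban
  - rural
strata:
- sex: F
  age: 18-29
  residence: urban
  size: 2000
  ownership: 0.45
  prevalence: 0.1
- sex: M
  age: 18-29
  residence: urban
  size: 2000
  ownership: 0.5
  prevalence: 0.1
- sex: F
  age: 30-44
  residence: urban
  size: 2000
  ownership: 0.315
  prevalence: 0.15
- sex: M
  age: 30-44
  residence: urban
  size: 2000
  ownership: 0.35
  prevalence: 0.15
- sex: F
  age: 45-59
  residence: urban
  size: 2000
  ownership: 0.135
  prevalence: 0.25
- sex: M
  age: 45-59
  residence: urban
  size: 2000
  ownership: 0.15
  prevalence: 0.25
- sex: F
  age: 60-69
  residence: urban
  size: 2000
  ownership: 0.045
  prevalence: 0.35
- sex: M
  age: 60-69
  residence: urban
  size: 2000
  ownership: 0.05
  prevalence: 0.35
- sex: F
  age: 70+
  residence: urban
  size: 2000
  ownership: 0.018
  prevalence: 0.45
- sex: M
  age: 70+
  residence: urban
  size: 2000
  ownership: 0.02
  prevalence: 0.45
- sex: F
  age: 18-29
  residence: rural
  size: 2000
  ownership: 0.3375
  prevalence: 0.1
- sex: M
  age: 18-29
  residence: rural
  size: 2000
  ownership: 0.375
  prevalence: 0.1
- sex: F
  age: 30-44
  residence: rural
  size: 2000
  ownership: 0.23625
  prevalence: 0.15
- sex: M
  age: 30-44
  residence: rural
  size: 2000
  ownership: 0.2625
  prevalence: 0.15
- sex: F
  age: 45-59
  residence: rural
  size: 2000
  ownership: 0.10125
  prevalence: 0.25
- sex: M
  age: 45-59
  residence: rural
  size: 2000
  ownership: 0.1125
  prevalence: 0.25
- sex: F
  age: 60-69
  residence: rural
  size: 2000
  ownership: 0.03375
  prevalence: 0.35
- sex: M
  age: 60-69
  residence: rural
  size: 2000
  ownership: 0.0375
  prevalence: 0.35
- sex: F
  age: 70+
  residence: rural
  size: 2000
  ownership: 0.0135
  prevalence: 0.45
- sex: M
  age: 70+
  residence: rural
  size: 2000
  ownership: 0.015
  prevalence: 0.45
phone_counts:
  '1': 0.85
  '2': 0.1
  '3': 0.05
answer_propensity: 0.7
response_propensity: 0.85
dropout_rate: 0.05
shared_phone_rate: 0.0
shared_slot: evening
household_sizes:
  '1': 1.0
mno:
- prefix: '017'
  suffix_length: 7
  share: 0.6
- prefix: 019
  suffix_length: 7
  share: 0.4
nonworking_fraction: 0.5
operator_feedback: yes
total_n: 500
max_redials: 3
replacement: staged
slot_weights:
  morning: 0.333333333333333
  afternoon: 0.333333333333333
  evening: 0.333333333333333
call_ceiling: 50000.0
effort_ceiling_factor: 25.0
snowball: no
snowball_success: 0.5
pool_multiplier: 10.0
working_assignment: exact
seed: 1
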