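dims:
  group: all
strata:
- group: all
  size: 10000
  ownership: 1.0
  prevalence: 0.3
phone_counts:
  '1': 0.9
  '3': 0.1
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
nonworking_fraction: 0.0
operator_feedback: yes
total_n: 500
max_redials: 3
replacement: staged
slot_weights:
  morning: 0.333333333333333
  afternoon: 0.333333333333333
  evening: 0.333333333333333
call_ceiling: 200000.0
effort_ceiling_factor: 50.0
snowball: no
snowball_success: 0.5
pool_multiplier: 10.0
working_assignment: exact
seed: 1
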