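# Bundled hypothetical case studies for the workplace wellbeing
# cost-consequence model. All values are 2024 GBP prices.
#
# Notes:
# - base_case: the turnover unit cost is listed but no turnover effect is
#   modelled (no effectiveness evidence), so the turnover component is
#   omitted from results. The published presentation of this case prints a
#   presenteeism incremental cost of -174,575 (hence a total of -210,373
#   and -4,207 per person), which does not follow from these inputs under
#   the model's stated arithmetic (50 x 9.6 x 379.51 = 182,164.80); this
#   package reproduces the arithmetic, not those three printed cells.
# - scenario_1: the intervention is funded as a lump sum (5,000 programme
#   + 105,000 of released working time = 110,000), so it is encoded as
#   fixed_cost with cost_per_person 0.
# - scenario_2: opt-in participation; 75 of the 250-person company take
#   part, and 75 is the modelled (and per-person denominator) headcount.
# - scenario_5: absenteeism worsens by 0.3 days/year, encoded as a
#   negative days-avoided effect.
scenarios:
- name: base_case
  n_participants: 50
  cost_per_person: 100
  fixed_cost: 0
  unit_costs:
    absenteeism_per_day: 189.76
    presenteeism_per_day: 379.51
    turnover_per_case: 18488.43
  effects:
    absenteeism_days_avoided: 4.3
    presenteeism_days_avoided: 9.6
- name: scenario_1
  n_participants: 600
  cost_per_person: 0
  fixed_cost: 110000
  unit_costs:
    absenteeism_per_day: 216
    presenteeism_per_day: 216
  effects:
    absenteeism_days_avoided: 1.3
    presenteeism_days_avoided: 2.5
- name: scenario_2
  n_participants: 75
  cost_per_person: 160
  fixed_cost: 0
  unit_costs:
    absenteeism_per_day: 259
  effects:
    absenteeism_days_avoided: 0.6
- name: scenario_3
  n_participants: 100
  cost_per_person: 300
  fixed_cost: 0
  unit_costs:
    absenteeism_per_day: 370
    turnover_per_case: 22799
  effects:
    absenteeism_days_avoided: 1.1
    turnover_reduction_pp: 0.5
- name: scenario_4
  n_participants: 40
  cost_per_person: 52
  fixed_cost: 0
  unit_costs:
    turnover_per_case: 9119
  effects:
    turnover_reduction_pp: 2
- name: scenario_5
  n_participants: 5
  cost_per_person: 165
  fixed_cost: 0
  unit_costs:
    absenteeism_per_day: 148
    presenteeism_per_day: 148
  effects:
    absenteeism_days_avoided: -0.3
    presenteeism_days_avoided: 1.8
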