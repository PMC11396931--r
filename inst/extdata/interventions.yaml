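# Default intervention roster: baseline/target coverages and the
# implementation window, with programme costs for the two policy
# interventions chosen so each totals its published programme budget over
# the 20-year window. Effect sizes are model inputs (see the methods
# vignette for how the defaults were chosen and how to calibrate them
# against a reported DALY reduction).
interventions:
  - name: marketing_restrictions
    target_ages: [2, 18]
    target_group: all
    baseline_coverage: 0.00
    target_coverage: 0.80
    effect: 0.10
    unit_cost: 225000        # fixed annual programme cost, CNY
    cost_mode: program
    window: [2025, 2044]
  - name: fopl
    target_ages: [0, 19]
    target_group: all
    baseline_coverage: 0.05
    target_coverage: 1.00
    effect: 0.02
    unit_cost: 1325000       # fixed annual programme cost, CNY
    cost_mode: program
    window: [2025, 2044]
  - name: nutrition_counseling
    target_ages: [0, 19]
    target_group: affected
    baseline_coverage: 0.00
    target_coverage: 0.40
    effect: 0.15
    unit_cost: 50            # CNY per covered affected person-year
    cost_mode: per_person
    window: [2025, 2044]
  - name: family_based
    target_ages: [6, 7]
    target_group: all
    baseline_coverage: 0.00
    target_coverage: 0.80
    effect: 0.10
    unit_cost: 60            # CNY per covered person-year
    cost_mode: per_person
    window: [2025, 2044]
  - name: school_based
    target_ages: [6, 17]
    target_group: all
    baseline_coverage: 0.05
    target_coverage: 0.80
    effect: 0.08
    unit_cost: 260           # CNY per covered person-year
    cost_mode: per_person
    window: [2025, 2044]
packages:
  - name: package_1
    members: [marketing_restrictions, fopl]
    combination_rule: multiplicative_residual
  - name: package_2
    members: [marketing_restrictions, fopl, school_based, nutrition_counseling]
    combination_rule: multiplicative_residual
  - name: all_five
    members: [marketing_restrictions, fopl, nutrition_counseling,
              family_based, school_based]
    combination_rule: multiplicative_residual
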