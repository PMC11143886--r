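# Example run configuration: a reduced-population run of the targeted
# scenario with the odds-ratio bracket.
seed: 1
years: 10
scenario: targeted
population_size: 2000000
population_method: expected
odds_ratio: 1.9
or_ci: [1.8, 2.0]
output_dir: cadprs_example_run
parameters:
  costs:
    statin_cost_per_year: 203.92
    prs_unit_cost: 147.20
    wtp_per_qaly: 50000
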