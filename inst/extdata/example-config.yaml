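# Example pregsim run configuration (see inst/schema/config-schema.json).
n_women: 10000
age: {type: uniform, min: 25, max: 34}
duration_days: 365
scenario: population_mix
schedule: {type: periodic, interval_days: 91}
timing_policy: random
assay: serum_quantitative
mode: mc
n_reps: 50
seed: 1
parameter_table: bundled-default
out_dir: results
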