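calibration: calibration_synthetic.csv
recovery: recovery_synthetic.csv
decay: decay_synthetic.csv
residue: residue_synthetic.csv
residue_summary: residue_summary_reference.csv
consumption: consumption_synthetic.csv
subgroups: subgroups_reference.csv
toxicology: toxicology_reference.csv
censor_policy: half_loq
variability_factor: 3
n_iter: 1000
seed: 20240314
loq: 0.05
output_dir: resrisk_run
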