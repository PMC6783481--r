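# Example pipeline configuration: fields omitted keep package defaults.
flank_bp: 3000
min_sources: 2
rpm_detect: 1.0
rs_min: 0.3
fdr_max: 0.05
master_fraction: 0.25
max_link_distance_bp: 1000000
n_permutations: 10000
seed: 1
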