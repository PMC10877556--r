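# Example pipeline configuration: a synthetic run under the default study
# conditions.  Load with read_pipeline_config(), run with run_pipeline().
synthetic:
  grid_nx: 20
  grid_ny: 20
  n_species_per_group: 40
  spatial_range: 3
  seed: 1
seed: 1
min_species: 3
anomaly_mode: signed
alpha: 0.05
cor_threshold: 0.7
n_perm: 199
max_mems: 10
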