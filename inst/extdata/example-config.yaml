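# Desk-scale example configuration for run_pipeline() / equimeta.R.
# Field-scale analyses use the same layout with
#   profile: {n_pairs_per_subsample: 15000000, n_repeats: 100}
out_dir: equimeta_run
seed: 1
simulate:
  n_species: 6
  n_pairs: 1500
  arg_catalog_size: 6
  cazy_catalog_size: 12
  defect_rates:
    ambiguous: 0.02
    low_quality: 0.02
    adapter: 0.02
    host: 0.02
profile:
  n_pairs_per_subsample: 1000
  n_repeats: 5
  rare_sample_threshold: 2
cazy:
  min_score: 60
  max_evalue: 1.0e-5
associate:
  target: habitat
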