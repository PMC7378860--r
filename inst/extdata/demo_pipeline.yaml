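# Demo pipeline configuration: a small three-round simulated serial-transfer
# experiment with one parasite class. Run with
#   Rscript inst/scripts/coevotrace.R --config inst/extdata/demo_pipeline.yaml
output_dir: coevotrace_demo
seed: 91
dominance_threshold: 0.10
top_n: 90
simulation:
  n_rounds: 3
  host_length: 150
  deletion_windows:
    parasite-alpha: [20, 130]
  substitution_rate: 0.002
  indel_rate: 0
  deletion_event_rate: 0.02
  init_molecules: 40
  droplet_capacity: 60
  replication_factor_host: 4
  max_population: 50000
  reads_per_round: 120
  seq_error_rate: 0
  seed: 91
length_bins:
  class_label: [host, parasite-alpha]
  min_length: [130, 20]
  max_length: [170, 60]
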