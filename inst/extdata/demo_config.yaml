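# Demonstration pipeline configuration: a small simulated three-cohort study
# with two planted risk proteins. Run with
#   run_pipeline(system.file("extdata", "demo_config.yaml",
#                            package = "protomark"), out_dir)
seed: 20
simulate:
  cohorts:
    - {name: EPIC, n_sets: 100, full_library: true}
    - {name: NSHDS, n_sets: 50, full_library: true}
    - {name: HUNT, n_sets: 100, full_library: false}
  n_proteins: 40
  n_shared: 30
  n_panels: 4
  n_shared_panels: 3
  n_duplicates: 6
  lod_quantile: 0.02
  planted:
    - {protein: P0001, beta0: 0.89}    # strong risk marker, OR ~ 2.4 per SD
    - {protein: P0002, beta0: -0.30}   # weak inverse marker, OR ~ 0.74 per SD
selection:
  n_iter: 50
  min_sets_per_side: 15
network:
  n_resamples: 40
top_proteins: 6
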