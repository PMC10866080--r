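# Small end-to-end fixture: 60-genome synthetic community.
seed: 11
out_dir: nstrat_out
simulate:
  n_genomes: 60
  decoys_per_genome: 10
search:
  n_decoys_calibration: 150
prevalence:
  n_boot: 300
  scheme: plain
call:
  require_nird: true
associate:
  ordination_k: 2
  ordination_method: pca
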