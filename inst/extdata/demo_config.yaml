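# Demo run: supercoiled donor carrying the ds98-931 homology.
reference: donor_ds98-931_synthetic
homology_window: [1000, 1931]
threshold: t40w50
length_cutoff: 400
bin_size: 100
seed: 1
simulation:
  n_molecules: 400
  dloop_fraction: 0.15
  conversion_efficiency: 0.58
  breathing_rate: 0.02
  bottom_to_top_read_ratio: 2.0
  indel_rate: 0.001
  truncation_fraction: 0.01
  topology:
    sigma: -0.07
    plasmid_length: 3000
    bp_per_supercoil: 10.4
    mode: supercoiled
  length_model:
    kind: truncnorm
    mean: 210
    sd: 50
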