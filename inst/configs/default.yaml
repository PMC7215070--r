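# Default pipeline configuration: the synthetic benchmark conditions the
# package documents (about 300 proteins, 500 positive + 500 negative pairs,
# 16 first-level learners in five-fold stacking).
seed: 1
outdir: stackppi_run
variant: grid
technique: ~
simulate:
  n_proteins: 300
  length_range: [60, 400]
  n_motif_families: 8
  motif_length: 12
  motif_copies: 3
  insertion_noise: 0.05
  membership_probs: [0.55, 0.40, 0.05]
  n_positive_pairs: 500
  localization_count: 7
filters:
  min_len: 50
  max_identity: ~
  neg_ratio: 1.0
  per_protein_cap: ~
encoders:
  lag: 30
  lambda: 15
  omega: 0.05
  ld_distribution: count
  correlation: signed
  nonstandard: impute
learners:
  techniques: [ac, ct, ld, pseaac]
  epochs: 8
  batch_size: 32
  lr: 0.003
  val_fraction: 0.15
  patience: 4
stacking:
  K: 5
  meta_layers: [32, 16]
  eta: 0.1
  max_iters: 600
  epsilon: 0.000001
evaluation:
  test_fraction: 0.2
  threshold: 0.5
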