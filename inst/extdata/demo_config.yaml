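# Demo configuration: a small synthetic study exercising every stage.
seed: 7
synthdata:
  n_tumor: 40
  n_normal: 10
  n_mirna: 40
  n_lncrna: 25
  n_mrna: 80
  frac_de: 0.4
  log2fc_de: 3
  nb_dispersion: 0.1
  n_true_edges: 30
  edge_effect: 0.9
  n_triplets: 5
  n_prognostic: 3
  beta_prognostic: 0.7
  censor_rate: 0.3
  motif_width: 8
  n_tf: 2
thresholds:
  fc: 2
  p: 0.05
  pcc: 0.9
  fimo_p: 1.0e-4
  hub_fraction: 0.2
  n_null: 200
  flank: 2000
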