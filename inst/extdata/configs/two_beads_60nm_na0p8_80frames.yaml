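# In-silico replication: two beads 60 nm apart resolved from only 80
# sub-frames with a 0.8-NA detection objective.
scene:
  kind: two_beads
  separation: 60
  size: 156
  dx_f: 5
n_frames: 80
imaging:
  na_det: 0.8
  lambda_em: 520
  binning: 13
recon:
  upsample: 3
  max_iter: 12
  tol: 1.0e-9
  inner_rho: 6
  inner_illum: 6
  psf_radius: 24
master_seed: 1
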