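# In-silico replication: two beads 40 nm apart, NA 1.5, 16 nm recon pixel.
scene:
  kind: two_beads
  separation: 40
  size: 104
  dx_f: 5
n_frames: 200
imaging:
  na_det: 1.5
  lambda_em: 520
  binning: 13
recon:
  upsample: 4
  max_iter: 15
  tol: 1.0e-9
  inner_rho: 8
  inner_illum: 8
  psf_radius: 17
master_seed: 1
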