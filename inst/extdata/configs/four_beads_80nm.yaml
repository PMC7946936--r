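# In-silico replication: four beads, closest pair 80 nm, 500 speckle frames,
# NA 1.5 detection, camera pixel 65 nm, blind-SIM at 3x upsampling.
scene:
  kind: bead_cluster
  size: 208
  dx_f: 5
n_frames: 500
imaging:
  na_det: 1.5
  lambda_em: 520
  binning: 13
recon:
  upsample: 3
  max_iter: 22
  tol: 1.0e-9
  inner_rho: 8
  inner_illum: 8
  psf_radius: 17
master_seed: 1
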