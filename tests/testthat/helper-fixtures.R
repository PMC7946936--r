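# Shared fixtures, built in code at test time.

# Tiny camera-grid (u = 1) stack generated exactly by the blind-SIM forward
# operator: structured cosine patterns that sum to a uniform field, a sparse
# bead-like object, no noise. Used for exact-recovery and cost checks.
tiny_exact_stack <- function(nc = 16L, M = 6L, dx_c = 65) {
  psf <- widefield_psf(0.8, 520, dx_c, radius = 6L, model = "gaussian")
  x <- (0:(nc - 1L))
  rho <- matrix(0, nc, nc)
  rho[max(2L, nc %/% 3L), max(2L, nc %/% 2L)] <- 1
  rho[min(nc - 1L, 2L * nc %/% 3L), max(3L, nc %/% 2L + 1L)] <- 0.7
  I <- array(0, c(nc, nc, M))
  for (m in seq_len(M - 1L)) {
    ph <- 2 * pi * m / (M - 1L)
    I[, , m] <- 1 + 0.8 * cos(outer(2 * pi * x * (m %% 3 + 1) / nc,
                                    2 * pi * x * ((m + 1) %% 2) / nc, "+") +
                                ph)
  }
  I[, , M] <- M - apply(I[, , -M, drop = FALSE], c(1L, 2L), sum)
  I[I < 0] <- 0
  # re-balance so the patterns sum exactly to M (uniform level 1)
  s <- apply(I, c(1L, 2L), sum)
  I <- I * as.vector(M / s)
  conv <- specklemain:::make_stack_convolver(nc, nc, psf$kernel)
  frames <- specklemain:::bin_stack(
    conv$forward(array(as.vector(rho) * as.vector(I), dim(I))), 1L)
  stack <- structure(list(frames = frames, dx_c = dx_c, noise = list(),
                          seeds = seq_len(M), meta = list(normalized = TRUE)),
                     class = "frame_stack")
  list(stack = stack, psf = psf, rho = rho, illumination = I)
}

# Small end-to-end speckle experiment config for pipeline tests: 8x8 camera
# pixels, few frames, few iterations - minutes of physics in seconds.
tiny_experiment_config <- function(n_frames = 8L, master_seed = 1L,
                                   kind = "two_beads", separation = 120) {
  experiment_config(
    scene = list(kind = kind, size = 104L, dx_f = 5, separation = separation),
    n_frames = n_frames,
    imaging = list(na_det = 0.8, lambda_em = 520, binning = 13L,
                   photons_scale = 5000, background = 5, read_sd = 1),
    recon = list(upsample = 2L, max_iter = 6L, tol = 1e-9,
                 tikhonov = 1e-3),
    master_seed = master_seed)
}
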