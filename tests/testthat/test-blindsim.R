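# Blind-SIM cost, constraints, and reconstruction behavior.

test_that("min_frames follows the N^2 information bound", {
  for (N in 1:6) expect_identical(min_frames(N), as.integer(N^2))
  expect_identical(min_frames(1, 2.5), 3L)   # N = 1 -> ceiling(alpha)
  expect_identical(min_frames(3, 1), 9L)
  expect_identical(min_frames(4, 2), 32L)
  expect_error(min_frames(0.5), "gain")
})

test_that("cost is exact at the generating truth and correct at zero", {
  fx <- tiny_exact_stack()
  energy <- sum(fx$stack$frames^2)
  c_truth <- blindsim_cost(fx$rho, fx$illumination, fx$stack, fx$psf)
  expect_lt(c_truth, 1e-8 * energy)
  c_zero <- blindsim_cost(fx$rho * 0, fx$illumination, fx$stack, fx$psf)
  expect_equal(c_zero, energy, tolerance = 1e-12)
  # any local perturbation of the truth increases the cost
  for (k in 1:3) {
    set.seed(k)
    r2 <- fx$rho + matrix(rnorm(length(fx$rho), 0, 1e-3), nrow(fx$rho))
    expect_gt(blindsim_cost(r2, fx$illumination, fx$stack, fx$psf), c_truth)
  }
  expect_error(blindsim_cost(fx$rho[1:4, 1:4], fx$illumination, fx$stack,
                             fx$psf), "inconsistent")
})

test_that("noiseless exact recovery at u = 1", {
  fx <- tiny_exact_stack()
  # frozen true illumination: the object subproblem is linear least
  # squares and conjugate gradients drive the cost to machine zero
  rec_k <- reconstruct(fx$stack, fx$psf,
                       recon_options(upsample = 1, max_iter = 30,
                                     tol = 1e-16, tikhonov = 0,
                                     inner_rho = 30,
                                     estimate_illumination = FALSE),
                       illumination = fx$illumination)
  expect_lt(tail(rec_k$cost, 1), 1e-6 * rec_k$cost[1])
  # fully blind: alternating block descent reaches a near-zero partial
  # optimum of the bilinear objective (block-coordinate stationary points
  # of a nonconvex bilinear fit need not be the global zero; on a smooth
  # noiseless instance the plateau is ~1e-5..1e-4 of the initial cost)
  nc <- 12L; M <- 4L
  psf_b <- widefield_psf(0.8, 520, 65, radius = 5L, model = "gaussian")
  x <- 0:(nc - 1)
  gsn <- function(cx, cy, s) outer(exp(-(x - cx)^2 / (2 * s^2)),
                                   exp(-(x - cy)^2 / (2 * s^2)))
  rho_b <- gsn(4, 6, 1.2) + 0.7 * gsn(8, 7, 1.5)
  Ib <- array(0, c(nc, nc, M))
  for (m in seq_len(M - 1L)) {
    ph <- 2 * pi * m / (M - 1L)
    Ib[, , m] <- 1 + 0.8 * cos(outer(2 * pi * x * (m %% 3 + 1) / nc,
                                     2 * pi * x * ((m + 1) %% 2) / nc,
                                     "+") + ph)
  }
  Ib[, , M] <- M - apply(Ib[, , -M, drop = FALSE], c(1, 2), sum)
  Ib[Ib < 0] <- 0
  Ib <- Ib * as.vector(M / apply(Ib, c(1, 2), sum))
  cb <- specklemain:::make_stack_convolver(nc, nc, psf_b$kernel)
  fr <- cb$forward(array(as.vector(rho_b) * as.vector(Ib), dim(Ib)))
  stk <- structure(list(frames = fr, dx_c = 65, noise = list(),
                        seeds = seq_len(M),
                        meta = list(normalized = TRUE)),
                   class = "frame_stack")
  rec_b <- reconstruct(stk, psf_b,
                       recon_options(upsample = 1, max_iter = 100,
                                     tol = 1e-16, tikhonov = 0,
                                     inner_rho = 40, inner_illum = 40))
  expect_lt(tail(rec_b$cost, 1), 1e-3 * rec_b$cost[1])
})

test_that("reconstruction respects its constraints and is monotone", {
  fx <- tiny_exact_stack()
  # perturb the frames with a little noise so the fit is non-trivial
  set.seed(9)
  stack <- fx$stack
  stack$frames <- pmax(stack$frames +
                         array(rnorm(length(stack$frames), 0,
                                     0.02 * max(stack$frames)),
                               dim(stack$frames)), 0)
  rec <- reconstruct(stack, fx$psf,
                     recon_options(upsample = 2, max_iter = 8,
                                   inner_rho = 4, inner_illum = 4))
  expect_true(all(diff(rec$cost) <= 1e-9))          # non-increasing
  expect_true(all(rec$rho >= 0))
  expect_true(all(rec$illumination >= -1e-12))
  # patterns add up to the uniform field by construction
  s <- apply(rec$illumination, c(1, 2), sum)
  M <- dim(rec$illumination)[3]
  expect_lt(max(abs(s - M * 1)), 1e-6)
  # determinism
  rec2 <- reconstruct(stack, fx$psf,
                      recon_options(upsample = 2, max_iter = 8,
                                    inner_rho = 4, inner_illum = 4))
  expect_identical(rec$rho, rec2$rho)
  expect_error(reconstruct(structure(list(frames = stack$frames[, , 1,
                                                                drop = FALSE],
                                          dx_c = 65, noise = list(),
                                          seeds = 1, meta = list()),
                                     class = "frame_stack"), fx$psf),
               "insufficient")
})

test_that("known-illumination deconvolution recovers a bead position", {
  # single off-center bead, uniform known illumination, noiseless
  n <- 104L; bin <- 13L; nc <- n %/% bin
  d <- matrix(0, n, n); d <- specklemain:::add_bead(d, 5, 230, 280, 46)
  sc <- specklemain:::new_scene(d, 5)
  psf_sim <- widefield_psf(1.5, 520, 5, radius = 40)
  fr <- acquire_frame(sc, NULL, psf_sim, binning = bin, photons_scale = 1,
                      noiseless = TRUE)
  M <- 2L
  stack <- structure(list(frames = array(rep(fr, M), c(nc, nc, M)),
                          dx_c = 65, noise = list(), seeds = 1:M,
                          meta = list()), class = "frame_stack")
  u <- 3L; nf <- nc * u
  psf_rec <- widefield_psf(1.5, 520, 65 / u, radius = 16)
  rec <- reconstruct(stack, psf_rec,
                     recon_options(upsample = u, max_iter = 40, tol = 1e-10,
                                   estimate_illumination = FALSE,
                                   inner_rho = 10),
                     illumination = array(1, c(nf, nf, M)))
  # intensity centroid within one recon pixel of the true center
  w <- rec$rho / sum(rec$rho)
  xs <- (seq_len(nf) - 0.5) * rec$dx - 2.5
  est <- c(sum(rowSums(w) * xs), sum(colSums(w) * xs))
  expect_lt(max(abs(est - c(230, 280))), rec$dx)
})

test_that("more frames reduce reconstruction error on a fixed scene", {
  mse <- sapply(c(10L, 40L), function(M) {
    errs <- sapply(1:2, function(seed) {
      cfg <- tiny_experiment_config(n_frames = M, master_seed = seed)
      res <- run_experiment(cfg)
      # compare against the scene downsampled to the recon grid
      sc <- res$scene; rec <- res$recon
      nf <- nrow(rec$rho)
      gr <- ((1:nf) - 0.5) * rec$dx / sc$dx_f + 0.5
      truth <- matrix(specklemain:::bilinear_sample(
        sc$density, rep(gr, times = nf), rep(gr, each = nf)), nf, nf)
      a <- rec$rho / sum(rec$rho); b <- truth / sum(truth)
      mean((a - b)^2)
    })
    mean(errs)
  })
  expect_lt(mse[2], mse[1])
})
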