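## End-to-end in-silico experiments: scene -> roughness -> speckles ->
## frame stack -> blind-SIM -> metrics, driven by one config list / YAML
## file and one master seed.

#' Stage seeds derived from a master seed
#'
#' Deterministic counter scheme: stage k uses seed
#' `(master * 1000 + 7919 * k) mod 2^31`, so any stage can be re-run in
#' isolation. Stages are numbered: 1 roughness, 2 incident fields (one seed
#' per frame, consecutive), 3 camera noise, 4 reconstruction jitter.
#'
#' @param master integer master seed
#' @param stage stage index >= 1
#' @return integer seed
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1000 + 7919 * stage) %% 2147483647)
}

#' Default experiment configuration
#'
#' Returns the configuration list for an in-silico speckle-illumination
#' experiment; every entry can be overridden through `...` (nested lists are
#' merged). See the bundled YAML configs under
#' `system.file("extdata/configs", package = "specklemain")` for the
#' replication scenarios.
#'
#' @param ... overrides, e.g. `scene = list(kind = "two_beads",
#'   separation = 40)`, `n_frames = 200`. The scene grid size field is
#'   named `size` (not `n`: bare `n` is a YAML 1.1 boolean)
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(...) {
  base <- list(
    scene = list(kind = "bead_cluster", size = 208, dx_f = 5,
                 separation = NULL, diameter = 46),
    optics = list(lambda_exc = 488, na_inc = 0.2, n_modes = 100,
                  n_pairs = 3, d_metal = 10, d_diel = 4,
                  rms = 1.1, corr_length = 35, z = 10,
                  beta = sqrt(0.2) / 1.1),
    imaging = list(na_det = 1.5, lambda_em = 520, binning = 13,
                   photons_scale = 5000, background = 10, read_sd = 2),
    n_frames = 500,
    recon = list(upsample = 3, max_iter = 25, tol = 1e-7,
                 tikhonov = 1e-3),
    metrics = list(dip_threshold = 0.8, frc = FALSE),
    master_seed = 1
  )
  ov <- list(...)
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  structure(merge_lists(base, ov), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with any subset of the [experiment_config()] fields
#' @return `experiment_config`
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' @keywords internal
build_scene <- function(cfg) {
  sc <- cfg$scene
  switch(sc$kind,
    two_beads = two_bead_scene(sc$separation, diameter = sc$diameter,
                               dx_f = sc$dx_f, n = sc$size),
    bead_cluster = bead_cluster_scene(positions = sc$positions,
                                      diameter = sc$diameter,
                                      dx_f = sc$dx_f, n = sc$size),
    qdots = qdot_scene(density = sc$density, seed = sc$seed %||% 1,
                       dx_f = sc$dx_f, n = sc$size),
    filaments = filament_scene(seed = sc$seed %||% 1,
                               n_filaments = sc$n_filaments %||% 3,
                               dx_f = sc$dx_f, n = sc$size),
    stop("unknown scene kind: ", sc$kind))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an in-silico speckle-illumination experiment
#'
#' Executes the full pipeline deterministically from the config's master
#' seed: generates the scene and the rough HMM surface, simulates one
#' speckle pattern and one camera frame per illumination realization,
#' forms the diffraction-limited average, background-subtracts and
#' normalizes the stack, reconstructs by blind-SIM, and measures the
#' requested metrics. When `outdir` is given, writes the stack,
#' reconstruction, diffraction-limited image and a YAML manifest of every
#' parameter and seed.
#'
#' @param config an [experiment_config()]
#' @param outdir optional output directory
#' @param verbose print per-stage progress
#' @return list of class `experiment_result`: `scene`, `stack`
#'   (normalized), `diffraction_limited`, `recon` (`recon_result`),
#'   `metrics` (two-peak verdicts and optional FRC), `config`, `seeds`
#' @export
run_experiment <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  op <- config$optics
  master <- config$master_seed
  seeds <- list(roughness = stage_seed(master, 1),
                incident0 = stage_seed(master, 2),
                noise = stage_seed(master, 3),
                recon = stage_seed(master, 4))
  say <- function(...) if (verbose) message(...)

  say("scene: ", config$scene$kind)
  scene <- build_scene(config)
  n <- nrow(scene$density)

  say("roughness + transfer filter")
  rough <- generate_height_map(n, scene$dx_f, op$rms, op$corr_length,
                               seed = seeds$roughness)
  stack_hmm <- hmm_stack(n_pairs = op$n_pairs, d_metal = op$d_metal,
                         d_diel = op$d_diel)
  k0 <- 2 * pi / op$lambda_exc
  filt <- transmission_filter(stack_hmm, op$lambda_exc,
                              max(k_radius_grid(n, scene$dx_f)) + k0)

  say("speckle patterns + frames (", config$n_frames, ")")
  im <- config$imaging
  psf_sim <- widefield_psf(im$na_det, im$lambda_em, scene$dx_f)
  patterns <- lapply(seq_len(config$n_frames), function(m)
    hmm_speckle(incident_field(op$lambda_exc, op$na_inc, op$n_modes,
                               seed = seeds$incident0 + m),
                stack_hmm, rough, op$lambda_exc, z = op$z, beta = op$beta,
                filter = filt))
  stack <- acquire_stack(scene, patterns, psf_sim, binning = im$binning,
                         photons_scale = im$photons_scale,
                         background = im$background, read_sd = im$read_sd,
                         noise_seed = seeds$noise)
  dl <- diffraction_limited(stack)

  ## preprocessing: subtract the known background level, per-frame normalize
  stack$frames <- pmax(stack$frames - im$background, 0)
  stack <- normalize_stack(stack)

  say("blind-SIM reconstruction")
  rc <- config$recon
  u <- rc$upsample
  dxr <- stack$dx_c / u
  ## reconstruction PSF truncated at 1.6 Airy radii (keeps the main lobe
  ## and first ring) unless overridden - the padding this implies dominates
  ## the per-iteration FFT cost
  rad <- rc$psf_radius %||%
    ceiling(1.6 * 0.61 * im$lambda_em / im$na_det / dxr)
  psf_rec <- widefield_psf(im$na_det, im$lambda_em, dxr, radius = rad)
  opts <- recon_options(upsample = u, max_iter = rc$max_iter, tol = rc$tol,
                        tikhonov = rc$tikhonov, seed = seeds$recon,
                        inner_rho = rc$inner_rho %||% 10L,
                        inner_illum = rc$inner_illum %||% 10L)
  recon <- reconstruct(stack, psf_rec, opts)

  say("metrics")
  met <- list()
  if (config$scene$kind %in% c("two_beads", "bead_cluster")) {
    pr <- closest_pair(scene)
    ## bead centers in reconstruction pixel coordinates
    ctr <- (pr + scene$dx_f / 2) / recon$dx + 0.5
    met$two_peak <- two_peak_separation_2d(
      recon$rho, dx = recon$dx, centers = ctr,
      search_radius = 50 / recon$dx,
      dip_threshold = config$metrics$dip_threshold)
    met$two_peak_dl <- two_peak_separation(dl, dx = stack$dx_c,
                                           dip_threshold =
                                             config$metrics$dip_threshold)
  }
  if (isTRUE(config$metrics$frc)) {
    met$frc <- split_stack_frc(stack, psf_rec, opts)
  }

  result <- structure(list(scene = scene, stack = stack,
                           diffraction_limited = dl, recon = recon,
                           metrics = met, config = config, seeds = seeds),
                      class = "experiment_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_stack(stack, file.path(outdir, "stack.tif"))
    write_image(recon$rho, file.path(outdir, "recon.tif"), dx = recon$dx)
    write_image(dl, file.path(outdir, "diffraction_limited.tif"),
                dx = stack$dx_c)
    utils::write.csv(data.frame(iteration = seq_along(recon$cost) - 1L,
                                cost = recon$cost),
                     file.path(outdir, "cost_history.csv"),
                     row.names = FALSE)
    manifest <- list(config = unclass(config), seeds = seeds,
                     metrics = summarize_metrics(met))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  result
}

## Scene coordinates [nm] of the closest bead pair.
#' @keywords internal
closest_pair <- function(scene) {
  pos <- if (!is.null(scene$meta$centers)) scene$meta$centers else
    scene$meta$positions
  if (is.null(pos)) stop("scene has no recorded bead positions")
  if (nrow(pos) == 2L) return(pos)
  dmat <- as.matrix(stats::dist(pos))
  diag(dmat) <- Inf
  ij <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
  pos[c(ij[1L], ij[2L]), , drop = FALSE]
}

#' @keywords internal
summarize_metrics <- function(met) {
  out <- list()
  if (!is.null(met$two_peak))
    out$two_peak <- list(resolved = met$two_peak$resolved,
                         separation = met$two_peak$separation)
  if (!is.null(met$two_peak_dl))
    out$diffraction_limited <- list(resolved = met$two_peak_dl$resolved)
  if (!is.null(met$frc))
    out$frc_resolution <- met$frc$resolution
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$config$scene$kind, "with",
      dim(x$stack$frames)[3L], "frames\n")
  if (!is.null(x$metrics$two_peak)) {
    tp <- x$metrics$two_peak
    cat(sprintf("  closest pair: resolved = %s, separation = %.1f nm\n",
                tp$resolved, if (is.na(tp$separation)) NA else tp$separation))
    cat(sprintf("  diffraction-limited resolved = %s\n",
                x$metrics$two_peak_dl$resolved))
  }
  if (!is.null(x$metrics$frc))
    cat(sprintf("  FRC resolution = %.1f nm\n", x$metrics$frc$resolution))
  invisible(x)
}
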