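# Speckle synthesis above the rough HMM and its spectral characterization.

stack488 <- hmm_stack()

test_that("incident fields are reproducible and diffraction limited", {
  inc <- incident_field(488, 0.2, 50, seed = 3)
  inc2 <- incident_field(488, 0.2, 50, seed = 3)
  expect_identical(inc[c("kx", "ky", "amplitude")],
                   inc2[c("kx", "ky", "amplitude")])
  k0 <- 2 * pi / 488
  expect_true(all(sqrt(inc$kx^2 + inc$ky^2) <= 0.2 * k0 + 1e-12))
  # NA = 0: single normal plane wave, uniform free-space intensity
  p0 <- free_space_speckle(incident_field(488, 0, 1, seed = 1), 64, 8)
  expect_equal(max(abs(p0$intensity - 1)), 0, tolerance = 1e-9)
  # fully developed speckle: contrast ~ 1 over seeds (field wide enough to
  # average several speckle grains of size ~lambda/(2 NA) ~ 1.2 um)
  ctr <- sapply(1:10, function(s)
    stats::sd(free_space_speckle(incident_field(488, 0.2, 100, seed = s),
                                 256, 40)$intensity))
  expect_lt(abs(mean(ctr) - 1), 0.15)
})

test_that("flat surface passes only the specular beam", {
  flat <- generate_height_map(64, 8, rms = 0, corr_length = 40, seed = 1)
  sp <- hmm_transmitted_spectrum(plane_wave(488, 0), stack488, flat, 488)
  expect_equal(max(Mod(sp$a)), 0)          # no scattered halo
  expect_equal(nrow(sp$specular), 1L)
  fl <- field_above_surface(sp, 10)
  I <- Mod(fl$field)^2
  t0 <- Mod(tmm_coefficients(stack488, 488, 0, "TM")$t)^2
  expect_equal(max(abs(I - t0)), 0, tolerance = 1e-9)
})

test_that("angular spectrum support stays within the physical bound", {
  n <- 250; dx <- 4
  rough <- generate_height_map(n, dx, 1.1, 35, seed = 5)
  k0 <- 2 * pi / 488
  filt <- transmission_filter(stack488, 488, max(k_radius_grid(n, dx)) + k0)
  cell <- unit_cell(ag_material(), 10, silica_material(), 4)
  kmax <- max_k_support(cell, 488) * k0
  bound <- 0.2 * k0 + kmax + 4 / 35        # incidence + Bloch + roughness
  for (s in 1:3) {
    sp <- hmm_transmitted_spectrum(incident_field(488, 0.2, 50, seed = s),
                                   stack488, rough, 488, filter = filt)
    en <- Mod(sp$a)^2
    beyond <- sum(en[k_radius_grid(n, dx) > bound])
    expect_lt(beyond / sum(en), 0.01)
  }
})

test_that("evanescent decay follows the closed form", {
  # a single evanescent component at |k| = 10 k0
  k0 <- 2 * pi / 488
  spec <- structure(list(a = matrix(0i, 32, 32),
                         specular = data.frame(kx = 10 * k0, ky = 0,
                                               amplitude = 1 + 0i),
                         dx = 2, wavelength = 488),
                    class = "angular_spectrum")
  f0 <- field_above_surface(spec, 0)
  f10 <- field_above_surface(spec, 10)
  ratio <- max(Mod(f10$field)) / max(Mod(f0$field))
  expect_equal(ratio, exp(-sqrt(100 - 1) * k0 * 10), tolerance = 1e-9)
  # z = 0 is the identity transform
  expect_equal(max(abs(Mod(f0$field) - 1)), 0, tolerance = 1e-9)
})

test_that("speckle intensity is normalized, deterministic and tunable", {
  n <- 200; dx <- 5
  rough <- generate_height_map(n, dx, 1.1, 35, seed = 7)
  p1 <- hmm_speckle(plane_wave(488, 0), stack488, rough, 488)
  expect_equal(mean(p1$intensity), 1, tolerance = 1e-12)
  expect_true(all(p1$intensity >= 0))
  p1b <- hmm_speckle(plane_wave(488, 0), stack488, rough, 488)
  expect_identical(p1$intensity, p1b$intensity)   # bit-identical rerun
  # global phase invariance of the intensity
  fl <- field_above_surface(
    hmm_transmitted_spectrum(plane_wave(488, 0), stack488, rough, 488), 10)
  fl2 <- fl; fl2$field <- fl$field * exp(1i * 0.73)
  expect_equal(speckle_intensity(fl)$intensity,
               speckle_intensity(fl2)$intensity, tolerance = 1e-12)
  # angle and wavelength tunability
  p_th <- hmm_speckle(plane_wave(488, 20), stack488, rough, 488)
  expect_lt(cross_correlation(p1, p_th), 1 - 1e-3)
  p_wl <- hmm_speckle(plane_wave(600, 0), stack488, rough, 600)
  expect_lt(cross_correlation(p1, p_wl), 1 - 1e-3)
})

test_that("radial MTF identifies pure tones and sub-diffraction content", {
  # pure cosine intensity of period P -> single dominant ring at 1/P
  n <- 128; dx <- 4; P <- 32
  I <- 1 + 0.5 * cos(2 * pi * (0:(n - 1)) * dx / (P * dx))
  pat <- structure(list(intensity = matrix(I, n, n), dx = dx,
                        wavelength = 488, z = 0, meta = list()),
                   class = "speckle_pattern")
  mt <- radial_mtf(pat)
  expect_equal(mt$freq[which.max(mt$mtf)], 1 / (P * dx), tolerance = 1e-9)
  # HMM speckle carries more energy beyond the incident diffraction limit
  # than the free-space control
  n <- 200; dx <- 5
  rough <- generate_height_map(n, dx, 1.1, 35, seed = 11)
  inc <- incident_field(488, 0.2, 100, seed = 2)
  m_hmm <- radial_mtf(hmm_speckle(inc, stack488, rough, 488),
                      apodize = TRUE)
  m_free <- radial_mtf(free_space_speckle(inc, n, dx, z = 10),
                       apodize = TRUE)
  cutoff <- 2 * 0.2 / 488
  area <- function(m) sum(m$mtf[m$freq > 1.5 * cutoff])
  expect_gt(area(m_hmm), 2 * area(m_free))
  # free-space control has no content beyond its diffraction limit; on a
  # window wide enough to resolve the incident passband (4 um) only a
  # Hann-leakage floor remains well past the cutoff
  m_free4 <- radial_mtf(free_space_speckle(inc, 400, 10, z = 10),
                        apodize = TRUE)
  expect_lt(max(m_free4$mtf[m_free4$freq > 3 * cutoff]), 1e-3)
})

test_that("cross-correlation behaves as an inner product", {
  n <- 150; dx <- 5
  r1 <- generate_height_map(n, dx, 1.1, 35, seed = 1)
  r2 <- generate_height_map(n, dx, 1.1, 35, seed = 2)
  p1 <- hmm_speckle(plane_wave(488, 0), stack488, r1, 488)
  p2 <- hmm_speckle(plane_wave(488, 0), stack488, r2, 488)
  expect_equal(cross_correlation(p1, p1), 1, tolerance = 1e-12)
  expect_lt(abs(cross_correlation(p1, p2)), 0.1)  # independent roughness
  const <- p1; const$intensity <- matrix(1, n, n)
  expect_error(cross_correlation(p1, const), "constant")
})

test_that("decorrelation angle scan is monotone and bounded", {
  # near-unity threshold crosses at the first scanned angles
  dec <- decorrelation_angle(stack488, 488, threshold = 0.99,
                             angles_deg = 0:6, seeds = 1, n = 150, dx = 5)
  expect_lte(dec$angle, 4)
  # flat surface: pure specular, correlation 1 at every angle -> sentinel
  expect_warning(
    dec_flat <- decorrelation_angle(stack488, 488, angles_deg = 0:3,
                                    seeds = 1, n = 64, dx = 8, rms = 0),
    "never crossed")
  expect_true(is.na(dec_flat$angle))
})
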