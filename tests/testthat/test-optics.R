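# Multilayer optics: permittivities, transfer matrix, dispersion.

test_that("permittivity handles constant-index and tabulated materials", {
  expect_equal(permittivity(silica_material(), 488), 2.1316 + 0i)
  expect_equal(permittivity(silica_material(), 900), 2.1316 + 0i)
  expect_equal(permittivity(constant_material("vacuum", 1), 550), 1 + 0i)
  eps_ag <- permittivity(ag_material(), 488)
  expect_lt(Re(eps_ag), -5)
  expect_gt(Im(eps_ag), 0)
  expect_error(permittivity(ag_material(), 100), "Johnson")
  expect_error(tabulated_material("bad", c(500, 400), cbind(c(1, 1),
                                                            c(0, 0))),
               "increasing")
})

test_that("TMM reproduces the Fresnel coefficients of a single interface", {
  # analytic Fresnel oracle, both polarizations, several angles
  n1 <- 1; n2 <- 1.5
  s <- layer_stack(substrate = constant_material("glass", n2))
  for (th in c(0, 20, 45, 70) * pi / 180) {
    k0 <- 2 * pi / 500
    kp <- n1 * k0 * sin(th)
    c1 <- cos(th)
    c2 <- sqrt(1 - (n1 * sin(th) / n2)^2)
    r_te <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
    r_tm <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
    te <- tmm_coefficients(s, 500, kp, "TE")
    tm <- tmm_coefficients(s, 500, kp, "TM")
    expect_equal(te$R, r_te^2, tolerance = 1e-12)
    expect_equal(tm$R, r_tm^2, tolerance = 1e-12)
    expect_equal(te$R + te$T, 1, tolerance = 1e-12)  # lossless
    expect_equal(tm$R + tm$T, 1, tolerance = 1e-12)
  }
  # empty stack, same media on both sides
  empty <- layer_stack(substrate = air_material())
  co <- tmm_coefficients(empty, 500, 0, "TM")
  expect_equal(co$r, 0 + 0i, tolerance = 1e-14)
  expect_equal(co$t, 1 + 0i, tolerance = 1e-14)
  expect_equal(co$T, 1, tolerance = 1e-14)
})

test_that("TMM conserves energy and is reciprocal for the HMM stack", {
  st <- hmm_stack()
  for (wl in c(405, 488, 600)) {
    for (kp_rel in c(0, 0.4, 0.9)) {
      co <- tmm_coefficients(st, wl, kp_rel * 2 * pi / wl, "TM")
      expect_equal(co$R + co$T + co$A, 1, tolerance = 1e-12)
      expect_gte(co$A, 0)  # absorbing Ag
    }
  }
  # lossless multilayer: A = 0 at propagating incidence
  loss_free <- layer_stack(list(
    list(material = constant_material("hi", 2.1), thickness = 80),
    list(material = silica_material(), thickness = 120)))
  co <- tmm_coefficients(loss_free, 500, 0.5 * 2 * pi / 500, "TE")
  expect_equal(co$A, 0, tolerance = 1e-10)
  # reciprocity: reversed stack order and exchanged half-spaces, same T
  st_rev <- layer_stack(rev(st$layers), superstrate = glass_material(),
                        substrate = air_material())
  for (kp_rel in c(0, 0.5)) {
    kp <- kp_rel * 2 * pi / 488
    expect_equal(tmm_coefficients(st, 488, kp, "TM")$T,
                 tmm_coefficients(st_rev, 488, kp, "TM")$T,
                 tolerance = 1e-10)
  }
  expect_error(tmm_coefficients(st, 488, 1.5 * 2 * pi / 488),
               "evanescent")
})

test_that("HMM transmission matches the reported values at 488 and 405 nm", {
  st <- hmm_stack()
  T488 <- tmm_coefficients(st, 488, 0, "TM")$T
  T405 <- tmm_coefficients(st, 405, 0, "TM")$T
  expect_gt(T488, 0.07); expect_lt(T488, 0.23)   # ~15% +- 8 points
  expect_gt(T405, 0.22); expect_lt(T405, 0.38)   # ~30% +- 8 points
})

test_that("effective medium theory limits and hyperbolic signs", {
  eps_m <- -9 + 0.3i; eps_d <- 2.1316 + 0i
  expect_equal(emt_permittivities(0, eps_m, eps_d),
               list(eps_parallel = eps_d, eps_perp = eps_d))
  expect_equal(emt_permittivities(1, eps_m, eps_d),
               list(eps_parallel = eps_m, eps_perp = eps_m))
  # Ag/SiO2 at 488 nm, f = 10/14: hyperbolic (type II) sign pattern
  emt <- emt_permittivities(10 / 14, permittivity(ag_material(), 488),
                            2.1316)
  expect_lt(Re(emt$eps_parallel), 0)
  expect_gt(Re(emt$eps_perp), 0)
  expect_error(emt_permittivities(0.5, -1, 1), "singular")
})

test_that("Bloch dispersion: homogeneous limit and EMT convergence", {
  glass <- constant_material("n15", 1.5)
  cell <- unit_cell(glass, 7, glass, 13)
  k0 <- 2 * pi / 500
  for (kp_rel in c(0, 0.6)) {
    K <- bloch_kz(cell, 500, kp_rel * k0, "TM")
    expect_equal(K, sqrt(as.complex(1.5^2 - kp_rel^2)) * k0,
                 tolerance = 1e-9)
  }
  # Lambda -> 0 at fixed k_parallel: K -> EMT extraordinary kz monotonically
  kp <- 1.5 * 2 * pi / 488
  emt <- emt_permittivities(0.5, permittivity(ag_material(), 488), 2.1316)
  kz_emt <- sqrt(emt$eps_parallel * ((2 * pi / 488)^2 -
                                       kp^2 / emt$eps_perp))
  if (Im(kz_emt) < 0) kz_emt <- -kz_emt
  errs <- sapply(1:6, function(j) {
    d <- 10 / 2^(j - 1)
    cell_j <- unit_cell(ag_material(), d, silica_material(), d)
    Mod(bloch_kz(cell_j, 488, kp, "TM") - kz_emt)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("k-space support of the 20 nm period Ag/SiO2 cell is ~10 k0", {
  cell <- unit_cell(ag_material(), 10, silica_material(), 10)
  kmax <- max_k_support(cell, 488)
  expect_gte(kmax, 8); expect_lte(kmax, 12)
  # air-like cell: K = kz of free space exactly, so the attenuation
  # criterion Im(K)*Lambda < 1 admits k up to sqrt(k0^2 + 1/Lambda^2)
  # (closed form), reached at the scan resolution
  vac <- constant_material("air", 1)
  k0 <- 2 * pi / 488
  expect_equal(max_k_support(unit_cell(vac, 10, vac, 10), 488),
               sqrt(k0^2 + (1 / 20)^2) / k0, tolerance = 0.06)
  # support non-increasing with the period at fixed fill fraction
  kms <- sapply(c(14, 20, 28, 40), function(L)
    max_k_support(unit_cell(ag_material(), L / 2, silica_material(),
                            L / 2), 488))
  expect_true(all(diff(kms) <= 0))
})

test_that("isofrequency curves have the right limits and shapes", {
  air <- isofrequency_curve("air", c(0, 0.5, 1), 488)
  expect_equal(air$kz_re[1], 1, tolerance = 1e-12)
  expect_equal(air$kz_re[3], 0, tolerance = 1e-9)
  expect_equal(air$kz_im, c(0, 0, 0), tolerance = 1e-9)
  # symmetry under kx -> -kx
  sym <- isofrequency_curve("air", c(-0.5, 0.5), 488)
  expect_equal(sym$kz_re[1], sym$kz_re[2])
  # hyperbolic EMT: on the propagating branch (kx above sqrt(Re eps_perp))
  # Re(kz) grows with kx (open hyperbola)
  cell <- unit_cell(ag_material(), 10, silica_material(), 10)
  emt <- isofrequency_curve("emt", seq(3, 9, by = 0.5), 488, cell)
  expect_true(all(diff(emt$kz_re) > 0))
})

test_that("resolution budget is additive and reproduces the SIM factor 2", {
  wf <- resolution_budget(1.5, 520, k_illum_max = 0)
  expect_equal(wf$f, wf$f_det)
  # f_illum = f_det -> ratio exactly 2
  b2 <- resolution_budget(1.5, 520, k_illum_max = 1.5, lambda_illum = 520)
  expect_identical(b2$ratio, 2)
  # homogeneity: doubling both cutoffs doubles f
  b <- resolution_budget(1.5, 520, 10, 488)
  bb <- resolution_budget(1.5, 260, 10, 244)
  expect_equal(bb$f, 2 * b$f)
  # hand-computed example: NA 1.5 / 520 nm with 10 k0 illumination at 488
  expect_equal(b$f, 2 * 1.5 / 520 + 2 * 10 / 488, tolerance = 1e-12)
  expect_equal(b$min_period, 1 / (2 * 1.5 / 520 + 2 * 10 / 488),
               tolerance = 1e-12)
})
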