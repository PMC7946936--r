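---
title: "Metamaterial-assisted speckle illumination nanoscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metamaterial-assisted speckle illumination nanoscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(specklemain)
```

## The imaging problem

Widefield fluorescence microscopy cannot transfer object spatial
frequencies beyond the detection cutoff $f_{det} = 2\,NA_{det}/\lambda_{em}$.
Structured illumination doubles this budget at best when the illumination
itself is diffraction limited, because the detectable support is the sum

$$ f = f_{det} + f_{illum}. $$

A hyperbolic metamaterial (HMM) substrate — here a sputtered multilayer of
thin Ag and SiO$_2$ films — supports propagating Bloch modes with in-plane
wavevectors far beyond the free-space light line, so near-field illumination
structured by the substrate can carry $f_{illum}$ many times larger than any
far-field pattern. Nanoscale interface roughness scatters a diffraction-
limited incident field into these high-$k$ modes, producing sub-diffraction
speckle directly on the substrate surface. Imaging a specimen under many
such speckle realizations and jointly estimating the object and the unknown
patterns (blind-SIM) then yields resolution well below the detection limit.
This package implements that entire chain in silico: multilayer optics,
rough-surface synthesis, speckle generation, the fluorescence forward
model, blind-SIM reconstruction, and resolution metrics.

## Multilayer optics

**Materials.** Ag uses the bundled Johnson & Christy (1972) $(n,k)$ table,
interpolated linearly in $n$ and $k$ within its tabulated range (requests
outside the range are an error, not an extrapolation). SiO$_2$ is
non-dispersive with $n = 1.46$; the substrate defaults to coverslip glass,
$n = 1.52$ (a typical value; the sources only name "glass"). Time
convention $e^{-i\omega t}$ throughout: passive materials have
$\mathrm{Im}\,\epsilon \ge 0$ and all layer-normal wavevectors take the
principal square root with $\mathrm{Im}\,k_z \ge 0$.

**Transfer matrix.** `tmm_coefficients()` is the standard interface-matrix
product for stratified media. Power transmittance includes the normal
power-flux ratio between substrate and superstrate, so $R + T + A = 1$
exactly, with $A \ge 0$ the absorbed fraction for the lossy Ag stack. For
the default 3-pair {10 nm Ag / 4 nm SiO$_2$} stack this reproduces the
measured transmission scale of the physical substrate (about 15% at 488 nm
and 30% at 405 nm; the package computes 16.7% and 31.4% with the bundled
optical constants — the unit tests assert these within the tolerance that
the bulk-vs-film discrepancy of thin-Ag optical constants warrants).

**Dispersion.** `emt_permittivities()` gives the first-order effective-
medium tensor; `bloch_kz()` solves the two-layer Bloch relation

$$ \cos K\Lambda = \cos k_1 d_1 \cos k_2 d_2 -
   \tfrac12\left(\eta + \eta^{-1}\right) \sin k_1 d_1 \sin k_2 d_2, \qquad
   \eta_{TM} = \frac{\epsilon_2 k_1}{\epsilon_1 k_2}, $$

with the branch fixed by $\mathrm{Im}\,K \ge 0$ and
$\mathrm{Re}\,K\Lambda \in [0, \pi]$. `max_k_support()` scans
$k_\parallel/k_0$ in steps of 0.05 up to the zone edge and reports the
largest value with per-period attenuation $\mathrm{Im}(K)\Lambda < 1$; both
the threshold and the step are exposed. For the 20 nm period cell at 488 nm
(equal fill, 10/10 nm — the fill fraction behind the published "about
10 k0" figure is not stated, so equal fill is the documented default) the
supported band reaches 9.05 $k_0$. Note that this attenuation criterion is
deliberately loose for very thin periods: even in vacuum a 20 nm period
admits $\mathrm{Im}(K)\Lambda < 1$ out to
$\sqrt{k_0^2 + \Lambda^{-2}} \approx 4 k_0$; the criterion is meaningful as
a band-structure probe, not as a free-space sanity limit.

## Rough surfaces

`generate_height_map()` synthesizes Gaussian-correlated height maps
spectrally: white Gaussian noise is filtered by the amplitude filter
$\exp(-k^2 C_l^2/8)$, giving the target autocorrelation
$\exp(-r^2/C_l^2)$ whose $1/e$ radius is $C_l$; the map is then
mean-subtracted and rescaled so the RMS is met exactly. The synthesis is
periodic (wrap-around correlation at the edges). The defaults RMS = 1.1 nm
and $C_l$ = 35 nm are the AFM-measured statistics of the sputtered
multilayer. `surface_statistics()` measures RMS as the population standard
deviation and $C_l$ as the first $1/e$ crossing of the radially averaged
circular autocorrelation (linear interpolation between radial bins); RMS is
exact by construction, $C_l$ carries a few percent of sampling error at the
512$^2$ AFM geometry.

## Speckle synthesis: a single-scattering surrogate

Full-wave (FDTD) solution of the rough multilayer is outside this package's
scope. The speckle module replaces it with a declared first-Born,
single-scattering angular-spectrum surrogate:

1. The incident diffraction-limited field is a sum of plane waves drawn
   uniformly over the $NA_{inc} = 0.2$ disk with uniform random phases
   (`incident_field()`), or a single tilted plane wave for the
   angle-tunability analyses.
2. Interface roughness acts as one effective thin phase screen at the top
   interface, linearized: $E \mapsto E\,(1 + i\beta h(r))$. Each incident
   component $q$ thus contributes a specular delta plus a scattered halo
   $i\beta\,\tilde h(k - q)$.
3. The spectrum is filtered by the multilayer transfer amplitude $t(|k|)$
   (`transmission_filter()`), then propagated to $z$ = 10 nm above the top
   surface (the height at which the reference intensity maps are defined):
   propagating components gain phase, evanescent ones decay as
   $e^{-|k_z| z}$.

Two implementation decisions deserve emphasis.

**Off-grid wavevectors.** On a 1 µm window the DFT frequency bin is
0.49 $k_0$ — wider than the whole $NA = 0.2$ incident disk, and wider than
the in-plane wavevector change of a 14° tilt. Snapping incident wavevectors
to the grid would alias the entire incident diversity to a single bin (and
fabricate a spurious, exactly-one-bin decorrelation angle). Incident and
specular components are therefore kept at their exact wavevectors as
analytic phase ramps; only the scattered halo lives on the DFT grid.

**The transfer amplitude at evanescent $k$.** The filter is the exact TM
transfer-matrix transmission amplitude of the stack, evaluated for
evanescent in-plane wavevectors as well (only the *power* normalization is
undefined there; the amplitude is not). This contains the Bloch-band
attenuation of deep-evanescent components exactly and, just as importantly,
the stack's surface-plasmon resonances, which enhance transmission in
bands around 2 $k_0$ and again near 9 $k_0$. An earlier variant that
stitched a separate Bloch attenuation factor onto the propagating-side
amplitude created an artificial notch at the light line whose long-range
kernel ringing dominated the angle decorrelation; the exact amplitude has
no such seam.

**Coupling constant.** $\beta$ (units 1/nm) sets the scattered power of
the linearized screen; the default $\beta = \sqrt{0.2}/1.1$ puts 20% of
the specular power into the (unfiltered) halo at the reference 1.1 nm
roughness. After the stack's resonant filtering this yields essentially
fully developed speckle at the surface (single-beam intensity contrast
close to 1), consistent with the reference full-wave intensity maps.

Under this surrogate the half-correlation incidence-angle difference at
488 nm evaluates to roughly 20° (scan of 1° steps, five roughness seeds,
Pearson correlation of normalized intensities). The full-wave reference
value is about 15°; a first-order surrogate cannot be expected to match a
multiple-scattering quantity to better than tens of percent, and the
package treats the value as model-dependent. Monotone decay of the
correlation with angle — the qualitative requirement — holds.

## Fluorescence forward model

A camera frame of object $\rho$ (fluorophore density on a fine grid, unit
integrated density per bead) under illumination $I_m$ is

$$ M_m = \mathrm{Poisson}\!\left(s\, D\!\left[H \ast (\rho I_m)\right] + b\right)
   + \mathcal N(0, \sigma_r^2), $$

with $H$ the Airy detection PSF $(2J_1(v)/v)^2$ (truncated and normalized;
a Gaussian with $\sigma = 0.21\lambda/NA$ is available), $D$ the camera
binning (65 nm pixels by default, 13 fine pixels), $s$ the photon scale
(default 5000 expected photons per bead per frame — a bright but realistic
budget for 46 nm beads; not stated by the reference, exposed in config),
$b$ a uniform background (default 10 photons/pixel) and read noise
$\sigma_r = 2$ counts. Convolution uses reflective padding. Before
reconstruction, stacks are background-subtracted and each frame divided by
its mean (per-frame intensity normalization, default on).

The fine simulation grid is 5 nm; reconstruction runs on a different grid
(camera pixel / upsampling factor), so forward simulation and inversion
never share a discretization.

## Blind-SIM reconstruction

All $M$ frames are explained by one nonnegative object $\hat\rho$ (on the
upsampled grid) and $M$ nonnegative patterns $\hat I_m$ constrained to add
up to a uniform field $\sum_m \hat I_m = M I_0$; the constraint is
eliminated exactly by expressing the last pattern through the others. The
objective is

$$ C = \sum_m \big\| M_m - D[H \ast (\hat\rho \hat I_m)] \big\|^2
     + \lambda \sum_m \|\nabla \hat I_m\|^2, $$

with a mild smoothing weight $\lambda = 10^{-3}$ (an artifact choice that
stabilizes the bilinear problem; not part of the reference method).
Minimization alternates between the two blocks. Each block subproblem is
linear least squares, so each outer iteration runs a few conjugate-gradient
iterations per block (defaults: 10 and 10) restricted to the inactive set
(variables pinned at zero with outward gradients are masked, so the
nonnegativity projection cannot cancel the step), followed by projection
and a backtracking safeguard that only ever accepts a lower objective. The
objective is therefore non-increasing by construction, and the whole run is
deterministic. Initialization: $\hat\rho^0$ is the upsampled mean frame,
$\hat I_m^0 = I_0$ uniform.

Two practical notes. First, plain gradient descent (with exact line
searches) stalls badly on this problem — the PSF-plus-binning operator is
so smoothing that steepest descent fits the passband and then makes no
visible progress on the super-resolved components; the inner CG iterations
are what make the reconstruction work. Second, on noiseless synthetic
problems the alternating scheme reaches a partial optimum that is typically
$10^{-5}$–$10^{-4}$ of the initial cost rather than machine zero: block-
coordinate stationary points of a nonconvex bilinear objective need not be
global. With the true patterns supplied and frozen the problem is linear
and CG drives the cost to numerical zero.

Pattern diversity matters as much as pattern bandwidth. Because every
speckle shares the fixed roughness of one substrate, patterns from
different incident realizations are substantially correlated (pairwise
intensity correlations of 0.2–0.8 under the surrogate), which raises the
number of frames needed well beyond the information-theoretic
$N^2$ bound exposed by `min_frames()`.

## Resolution metrics

**Fourier ring correlation.** `frc_curve()` computes
$\mathrm{Re}\sum F_1 F_2^* / \sqrt{\sum|F_1|^2 \sum|F_2|^2}$ over rings one
frequency bin wide (optional Tukey apodization, default on for
reconstructions, off for raw frames); `frc_resolution()` returns the
inverse of the first crossing below $1/7$, with linear interpolation
between rings and a flagged Nyquist fallback when no crossing occurs.
`split_stack_frc()` reconstructs even- and odd-indexed frames
independently — the standard split when only one acquisition exists.

**Two-peak resolvability.** `two_peak_separation()` samples a line profile
at 10x sub-pixel density, finds local maxima, and declares the two highest
resolved when the dip between them falls below 0.8 of the lower peak — a
conservative Rayleigh-like rule (the reference reports resolvability
without printing a dip criterion). `two_peak_separation_2d()` is the
variant used for bead pairs: it first locates the actual 2-D reconstruction
peaks near the two expected positions (3x3 centroid refinement) and then
applies the dip rule along the line through them, mirroring the
cross-section-along-the-arrow practice for bead images.

## In-silico replication scenarios

Three bundled configs (`inst/extdata/configs/`) replicate the bead
experiments at desk scale. All use a region of interest of 12–16 camera
pixels (0.8–1 µm of field), which holds the full pipeline — 80 to 500
frames of speckle generation, acquisition and joint estimation — to
minutes per run on one core; the iteration budgets in the configs
(12–22 outer iterations, 6–8 CG steps per block) are set at the point
where the objective has visibly plateaued on these problems.

* `four_beads_80nm.yaml` — four beads with an 80 nm closest pair, 500
  frames, NA 1.5, 22 nm reconstruction pixel. The reconstruction resolves
  all four beads and the measured closest-pair separation lands within
  about ten nanometres of truth (the acceptance suite asserts 80 ± 22 nm).
* `two_beads_40nm.yaml` — a 40 nm pair at NA 1.5, 16 nm reconstruction
  pixel, 200 frames.
* `two_beads_60nm_na0p8_80frames.yaml` — a 60 nm pair at NA 0.8 with only
  80 frames.

The last two scenarios push the surrogate beyond what it can deliver: at
$z$ = 10 nm the evanescent decay and the Gaussian roughness spectrum
(correlation length 35 nm) leave little illumination energy at the
$\sim$7–9 $k_0$ in-plane frequencies those separations require, and the
estimator — even when handed the true patterns and four times the frames —
collapses the pair to a single source. The corresponding acceptance checks
are expected to fail under this model and are reported as such rather than
recalibrated; the physical experiments succeed because the real multilayer
converts more power into those bands (multiple scattering through six
rough interfaces) than a single linearized screen does.

## Determinism and seeds

Every random stage — roughness, incident fields, camera noise, optional
initialization jitter — consumes an explicit seed. `run_experiment()`
derives stage seeds from one master seed via
`stage_seed(master, k) = (1000 master + 7919 k) mod 2^31`, records all of
them in the output manifest, and reruns bit-identically. RNG state of the
caller is saved and restored around every seeded helper.

## Known limitations

* Scalar fields; the TM transfer function stands in for full vector
  propagation, and polarization effects on the speckle are absent.
* Single effective scattering screen; volumetric disorder of all six
  interfaces is lumped into one, which underestimates high-$k$ conversion
  and pattern diversity (see the replication notes above).
* Gaussian roughness autocorrelation, hence rapidly decaying spectral
  tails; measured surfaces often carry heavier tails.
* No fluorophore photophysics, no metal quenching, no axial structure: a
  46 nm bead samples the illumination at one height.
* The decorrelation angle is model-dependent at the tens-of-percent level;
  only its monotone decay should be read quantitatively.
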