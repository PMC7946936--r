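Package: specklemain
Title: Speckle Metamaterial-Assisted Illumination Nanoscopy: Simulation and
    Blind-SIM Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates sub-diffraction speckle illumination generated by a
    rough Ag/SiO2 hyperbolic-metamaterial (HMM) substrate and reconstructs
    super-resolved fluorescence images from multi-frame speckle-illuminated
    stacks by blind structured-illumination (blind-SIM) joint estimation.
    Includes transfer-matrix multilayer optics, Bloch and effective-medium
    dispersion of metal-dielectric multilayers, Gaussian-correlated rough
    surface synthesis, an angular-spectrum speckle model, a widefield
    fluorescence forward model with Poisson and read noise, and resolution
    metrics (Fourier ring correlation, two-peak resolvability).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
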