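Package: rwpsf
Title: Point-Spread-Function Models from the Richards-Wolf Diffraction Integral
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes scalar and vectorial microscope point-spread functions
    (PSFs) as parameterisations of the Richards-Wolf diffraction integral.
    Four propagators are provided (scalar/vectorial crossed with
    Cartesian/spherical parameterisations), together with generalised
    amplitude and phase correction factors (Gibson-Lanni index-mismatch
    aberrations, Zernike and custom pupil phases, apodisation, Gaussian
    envelope, Fresnel transmission coefficients), a sized chirp-Z Fourier
    transform for arbitrary focal-plane pixel sizes, composite Simpson
    quadrature for the Bessel-kernel integrals, and a validation suite that
    measures convergence orders against the analytic Airy disk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
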