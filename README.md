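# rwpsf

Scalar and vectorial point-spread functions (PSFs) for high-NA microscopy,
computed from the Richards–Wolf diffraction integral.

The PSF — the 3D image a microscope forms of an ideal point emitter — is the
workhorse of deconvolution, PSF engineering and single-molecule localisation
microscopy. At high numerical aperture the paraxial Airy model is no longer
adequate: the focal field must be assembled as a superposition of plane
waves over the full aperture cone,

```
E(ρ) = -(i f k / 2π) ∫∫_Ω  a(s) e^{iW(s)} e∞(s) e^{i k s·ρ} dΩ,
```

where `s = (sinθ cosϕ, sinθ sinϕ, cosθ)` runs over directions inside the
cut-off `s_max = NA/n_i`, `e∞` is the far field on the Gaussian reference
sphere, `k = 2πn/λ`, and `a(s)`, `W(s)` are amplitude and phase correction
factors. Two equivalent parameterisations of this one integral give the two
families of PSF models in use:

* **Cartesian** — integrate over `(sx, sy)` with `dΩ = dsx dsy / sz`: each
  z-plane is a sized 2D Fourier transform of `e∞ e^{i k s_z z}/s_z`,
  evaluated here by a chirp-Z transform so the focal pixel size is
  arbitrary. Works for *any* pupil.
* **Spherical** — for axisymmetric pupils the azimuthal integral closes
  into Bessel functions, leaving 1D θ-integrals
  (`J0` in the scalar case; `I0/I1/I2` integrals with `J0, J1, J2` kernels
  in the vectorial case) evaluated by composite Simpson quadrature.

Both carry one (scalar) or three (vectorial x, y, z) field channels in a
`(z, channel, x, y)` stack. Correction factors — Gibson–Lanni
stratified-medium aberration, Zernike expansions (OSA/ANSI, orthonormal),
vortex and half-moon masks, apodisation `cosθ`, Gaussian envelope, Fresnel
transmission products — apply to either parameterisation.

## Worked example

A high-NA vectorial PSF with circular polarisation:

```r
library(rwpsf)

setup <- optical_setup(na = 1.3, wavelength = 632, n_sample = 1.5)
str(derived_quantities(setup))
#> List of 3
#>  $ k        : num 0.0149    # rad/nm
#>  $ s_max    : num 0.867
#>  $ theta_max: num 1.05      # rad (60.1 deg)

grid <- sampling_grid(pupil_size = 257, out_size = 101, pixel_size = 20,
                      z_planes = c(-500, 0, 500))
pupil <- far_field_pupil(apply_polarisation(uniform_pupil(setup, grid)))
psf <- vectorial_cartesian(pupil, grid)
psf
#> <focal_field> vectorial_cartesian: 3 z-plane(s), 3 channel(s), 101x101 @ 20 nm
#>   z range [-500, 500] nm, peak |E| = 1.385e+04

i <- intensity(psf)           # (z, x, y) array, channel-summed |E|^2
save_stack(psf, "psf.tif", format = "tiff", mode = "amplitude")
```

`k` is the wavenumber in the sample medium, `s_max` the pupil cut-off
`NA/n_i`, `theta_max = asin(s_max)` the aperture half-angle (here 60.1°).
The peak `|E|` carries the physical `-ifk/2π` prefactor; use
`normalise_field(psf, "max")` for unit-peak output. The TIFF holds 9 pages
(z-major, then channel) normalised to `[0, 1]`, with pixel size, z-planes
and the peak scale in `psf.tif.meta.json`.

The same computation runs from a YAML config (see
`inst/extdata/example-config.yaml`) via `run_from_config(read_run_config(...))`,
or from the shell through the thin CLI at `inst/scripts/psfgen`
(verbs `generate`, `benchmark`, `gallery`).

Checking the spherical parameterisation against the Airy limit:

```r
setup <- optical_setup(na = 0.5, wavelength = 632)
airy_benchmark("spherical", "simpson", c(51, 101, 201, 401, 801),
               setup, sampling_grid(out_size = 201, pixel_size = 150))
#> <convergence_report> scalar_spherical / simpson
#>   fitted order 4.022 over 5 densities (h in [0.000654, 0.0105])
```

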