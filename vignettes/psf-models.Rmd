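---
title: "PSF models from the Richards–Wolf integral: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSF models from the Richards-Wolf integral: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwpsf)
```

## The model

A microscope objective converts a planar incident field `einc` (the pupil
function, a disk of radius `s_max = NA/n_i` in direction-cosine space) into
a converging spherical wave `e∞` on the Gaussian reference sphere. The
focal field is the coherent sum of the plane waves propagating along every
direction `s = (sinθ cosϕ, sinθ sinϕ, cosθ)` inside the aperture cone:

$$E(\boldsymbol\rho) = -\frac{ifk}{2\pi} \iint_\Omega a(\mathbf s)\,
e^{iW(\mathbf s)}\, \mathbf e_\infty(\mathbf s)\,
e^{ik \mathbf s\cdot\boldsymbol\rho}\, d\Omega ,$$

with `k = 2πn/λ` the wavenumber in the propagation medium, `f` the focal
length (which only scales the result), and `a`, `W` optional amplitude and
phase correction factors. Defocus enters through the angular-spectrum
factor `exp(i k s_z z)`, which models free-space propagation of each plane
wave to the plane `z`.

Everything in this package is a parameterisation of this one integral:

* **Cartesian** (`scalar_cartesian()`, `vectorial_cartesian()`): with
  `dΩ = ds_x ds_y / s_z` the focal plane is the 2D inverse Fourier
  transform of `e∞ exp(i k s_z z)/s_z` over the pupil disk. This form
  accepts arbitrary pupils — Zernike aberrations, vortex or half-moon
  masks, imported phase masks.
* **Spherical** (`scalar_spherical()`, `vectorial_spherical()`): when the
  pupil depends only on θ, the ϕ-integral closes into Bessel functions.
  The scalar field reduces to a single `J0`-kernel integral over
  `[0, θ_max]`; the vectorial field to six integrals `I0/I1/I2` per
  transverse incident component, with kernels `sinθ(q_s + q_p cosθ) J0`,
  `q_p sin²θ J1` and `sinθ(q_p cosθ − q_s) J2`, assembled with `cos 2φ`,
  `sin 2φ`, `cos φ`, `sin φ` azimuthal weights. With unit Fresnel
  coefficients these reduce to the classic `(cosθ+1)`, `sinθ`, `(cosθ−1)`
  kernels; the generalised forms follow from carrying `q_s`, `q_p` through
  the basis change and are the package's own extension of the spherical
  path (they default to 1).

The vectorial models differ from the scalar ones only by the basis change
`far_field_from_incident()`, a rotation of the transverse Jones field onto
the reference sphere that is the identity at θ = 0 — which is why scalar
models, valid at low NA, skip it. Fields are stored `(z, channel, x, y)`,
computed plane-by-plane in z, with 1 channel (scalar) or 3 (vectorial).

Because the two parameterisations discretise the *same* integral, their
outputs must agree wherever both apply (axisymmetric pupils). This
equivalence — including the absolute scale: the `2π` absorbed by the
explicit ϕ-integration exactly compensates the prefactor difference — is
enforced by tests rather than assumed; see below.

## Conventions and parameters

* **Units.** All lengths in nm internally (wavelength, pixel size, z,
  layer thicknesses); focal length in mm, converted once inside the
  prefactor. Working in nm keeps `k·ρ` products well-scaled.
* **Sign convention.** The transform uses `exp(+i k s·ρ)` everywhere.
  Focal azimuth φ is measured from +x, counter-clockwise; array dimension
  3 is x, dimension 4 is y; TIFF pages are written with y increasing
  upward. The half-moon fixture (a π step across `s_x = 0`) pins this
  down: its lobes split along x.
* **Media.** `n_sample` enters `k`; `n_immersion` sets the cut-off
  `s_max = NA/n_i`. The default `n_immersion = n_sample` describes one
  homogeneous medium, with stratified-layer physics entering only through
  the Gibson–Lanni and Fresnel correction factors. When the two indices
  are set differently the wavenumber keeps `n_sample`; this choice is
  deliberate and documented here because either convention can be argued
  for the defocus factor.
* **Grids.** Pupil sides and image sides are odd, so one sample sits
  exactly on the optical axis and the θ-line has the even interval count
  composite Simpson needs. Pupil samples run
  `s_i = -s_max + 2 i s_max/(N-1)`. Defaults: pupil 513, θ-line 1001,
  image 201×201 at 20 nm — a few-µm field of view around focus at the
  package's two reference settings (NA 0.5 in air; NA 1.3 with n = 1.5),
  both at λ = 632 nm with circular polarisation for vectorial models.
* **`1/s_z` singularity.** `na < n_immersion` is enforced at construction,
  so `s_z ≥ √(1 − s_max²) > 0` on the disk and the Cartesian kernel needs
  no regularisation.

## Correction factors

All corrections are amplitude factors `a(s)` or phase factors `W(s)`
multiplied into the pupil *before* propagation (`apply_corrections()`),
composed into a single multiplier first so that factor ordering cannot
change the result bit-for-bit. They are available to both
parameterisations when axisymmetric; `run_config()` refuses
non-axisymmetric ones (vortex, half-moon, non-radial Zernike, custom
masks) on the spherical path.

* **Gibson–Lanni** (`gibson_lanni_phase()`): the optical-path mismatch
  between the actual sample/immersion/coverslip stack and the objective's
  design stack,
  `W = (2π/λ) Σ ± t_layer √(n_layer² − n_i² sin²θ)`, with design (starred)
  terms subtracted. The immersion thickness is usually unknown and is
  derived from the refocusing condition
  `t_i = t_s + n_i(−t_s/n_s − t_g/n_g + t_g*/n_g* + t_i*/n_i*)`
  (`immersion_thickness_from_focus()`); this grouping is the only one that
  returns `t_i = t_i*` under fully matched conditions, which is how the
  package fixes the expression. Supercritical angles (a lower-index layer
  beyond its critical angle) give imaginary square roots; the phase is
  kept complex so `exp(iW)` produces the physical evanescent decay instead
  of a clipped discontinuity. Note the sample-depth term `t_s` has no
  starred counterpart: the design condition places the emitter at the
  coverslip, so the exact null `W ≡ 0` requires `t_s = 0` along with
  matched starred values.
* **Zernike expansions** (`zernike_phase()`): OSA/ANSI single indexing,
  orthonormal normalisation (`(1/π)∫ Z_j Z_k dA = δ_jk`), pupil radius
  mapped to the unit disk. Coefficients are radians by default, with a
  `waves` unit option (×2π). The indexing and normalisation are stated
  here precisely because several conventions circulate; the test suite
  verifies the Gram matrix numerically.
* **Apodisation** (`apodisation()`): `A = cosθ` by default, the energy
  projection factor for the plane-to-sphere basis change in the focusing
  direction. The classic `√cosθ` convention is reachable via
  `exponent = 0.5`; the package never substitutes it silently, because the
  two differ measurably at high NA.
* **Gaussian envelope** (`gaussian_envelope()`):
  `A = exp(−sin²θ/s_env²)` for non-uniform illumination.
* **Fresnel transmission** (`fresnel_coefficients()`): per-polarisation
  amplitude transmission products over a layer stack with Snell-chained
  angles, complex (evanescent) past critical angles; the empty stack gives
  the `q_s = q_p = 1` defaults used everywhere else.

## Numerics

* **Sized Fourier transform** (`sized_ft_2d()`): focal pixel sizes in
  localisation microscopy (tens of nm) are far below the natural FFT
  sampling `1/(N·Δs)`, so the package evaluates the pupil sum on an
  arbitrary centred output grid with a Bluestein chirp-Z transform: one
  complex convolution carried by three FFTs, zero-padded to the next power
  of two at or above `N + M − 1` (only the valid convolution range is
  kept). Cost stays `O(L log L)` per axis; agreement with the brute-force
  double sum is at machine precision (~1e−15 relative), tested against an
  independent `O(N²M²)` oracle.
* **Quadrature** (`integrate_1d()`): composite Simpson (fourth order, the
  default) and left Riemann (first order, kept for the convergence
  benchmark). Simpson with an even sample count is an error, never a
  silent fallback. Bessel kernels come from `besselJ`; tests cross-check
  them against an independent power series.
* **Radial evaluation.** Spherical propagators evaluate the θ-integrals
  once per *unique* radius of the output grid (keyed exactly on the
  integer lattice `i² + j²`) and scatter to 2D, so pixels at equal radius
  are bit-identical and the cost drops by roughly the image's eightfold
  symmetry.
* **Degenerate inputs.** Zero pupils propagate to zero fields; `ρ = 0`
  uses the series limits `J1(0) = J2(0) = 0` (so the longitudinal channel
  vanishes on axis) and `airy_disk(0) = 1`; a zero-norm Jones vector is
  rejected at construction.

## Validation design

`airy_benchmark()` measures each scalar propagator against the analytic
Airy amplitude `2J1(ρ)/ρ`. An extra `cosθ` factor is applied to the
uniform pupil, cancelling the `1/s_z` kernel so the continuum limit of the
computation is *exactly* the Fourier transform of a flat disk at any NA —
the benchmark therefore isolates discretisation error. Errors are L2 over
a 1D radial line through the centre after rescaling by the on-axis value
(the choice of line versus plane shifts constants, not orders), and the
order is the least-squares log-log slope over the densest decade of step
sizes, discarding points below the 1e−12 floating-point floor. Measured
orders at the defaults (NA 0.5, 201-pixel line at 150 nm): Riemann 1.0,
Simpson 4.0, Cartesian ≈1.5 — the Cartesian path is limited by the jagged
binary disk edge, which is kept deliberately (an anti-aliased edge would
contaminate exactly these measurements).

The cross-parameterisation equivalence fixtures run at NA 0.5 (air,
λ = 632 nm, default grids, z = 0) on uniform and Gaussian-envelope
(`s_env = 1/3`) circularly polarised pupils. That setting is chosen
because the residual discrepancy is the Cartesian edge error, which grows
with the dimensionless field extent `k·s_max·FOV`; at the default
sampling the scalar and vectorial discrepancies are ~5×10⁻⁴ (uniform) and
~1×10⁻⁴ (Gaussian), and both shrink as the samplings refine. The
scalar-versus-vectorial comparison is a separate, intensity-level check:
~0.8% relative L2 at NA 0.2 and ~20% at NA 1.3, quantifying where the
scalar approximation stops being adequate.

Problem sizes throughout the tests and the acceptance script (pupils up to
513, θ-lines up to 1601, images up to 201²) were chosen so the full
validation reruns in well under a minute on one CPU while still sitting in
the asymptotic regime of every convergence fit.

## Output formats

The archive format (`save_stack(..., format = "rds")`) serialises the
complete complex stack plus metadata and round-trips bit-exactly. TIFF
output is multi-page 32-bit float, pages z-major then channel, but carries
only peak-normalised values in `[0, 1]` because the TIFF writer used
clamps that range and stores no tags; pixel size, z-planes and the peak
scale factor therefore go to a JSON sidecar (`<stack>.tif.meta.json`).
Complex fields cannot be written to TIFF — choose amplitude or intensity
mode, or the archive.

## Known limitations

* Emission (dipole-to-camera) PSFs via reciprocity are not implemented —
  the package computes focusing fields only.
* No dispersion or multi-wavelength stacks; one wavelength per run.
* Fresnel factors model transmission amplitude products only: no
  absorbing layers, multiple reflections, or coverslip tilt.
* The spherical path requires axisymmetry and refuses anything else; the
  Cartesian path is the general fallback.
* Pupils imported from TIFF are taken as-is on the pupil grid; there is
  no phase retrieval or resampling.
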