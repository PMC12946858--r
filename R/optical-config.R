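#' Optical system parameters
#'
#' Bundles the physical constants shared by every propagator: numerical
#' aperture, vacuum wavelength, refractive indices of the propagation and
#' immersion media, focal length and the Jones vector of the incident
#' polarisation. All lengths are in nanometres except the focal length,
#' which enters only through the constant prefactor \eqn{-ifk/(2\pi)} and is
#' given in millimetres.
#'
#' The constraint `na < n_immersion` guarantees that the pupil cut-off
#' `s_max = na / n_immersion` is strictly below 1, so the axial direction
#' cosine \eqn{s_z = \sqrt{1 - s_x^2 - s_y^2}} stays real and positive on
#' the pupil disk and the \eqn{1/s_z} kernel of the Cartesian propagators
#' never becomes singular.
#'
#' @param na numerical aperture (dimensionless), `0 < na < n_immersion`.
#' @param wavelength vacuum wavelength in nm.
#' @param n_sample refractive index of the propagation medium (enters the
#'   wavenumber `k = 2 pi n_sample / wavelength`).
#' @param n_immersion refractive index of the immersion medium (sets the
#'   cut-off `s_max = na / n_immersion`). Defaults to `n_sample`: a single
#'   homogeneous medium, with stratified-layer effects entering only through
#'   correction factors.
#' @param focal_length focal length in mm.
#' @param polarisation complex length-2 Jones vector `(ex, ey)` of the
#'   incident field; normalised to unit norm on construction.
#' @return An object of class `optical_setup`.
#' @examples
#' setup <- optical_setup(na = 1.3, wavelength = 632, n_sample = 1.5)
#' derived_quantities(setup)
#' @export
optical_setup <- function(na, wavelength, n_sample = 1.0,
                          n_immersion = n_sample, focal_length = 3.0,
                          polarisation = jones_circular()) {
  stopifnot(is.numeric(na), length(na) == 1L, na >= 0,
            is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(n_sample), n_sample >= 1 || n_sample > 0,
            is.numeric(n_immersion), n_immersion > 0,
            is.numeric(focal_length), focal_length > 0,
            length(polarisation) == 2L)
  if (na >= n_immersion)
    stop("`na` must be strictly smaller than `n_immersion` (s_max < 1)")
  nrm <- sqrt(sum(Mod(polarisation)^2))
  if (nrm == 0) stop("polarisation Jones vector must be non-zero")
  structure(
    list(na = na, wavelength = wavelength, n_sample = n_sample,
         n_immersion = n_immersion, focal_length = focal_length,
         polarisation = as.complex(polarisation) / nrm),
    class = "optical_setup"
  )
}

#' Common Jones vectors
#'
#' Convenience constructors for the incident polarisation state:
#' `jones_circular()` is the left-circular state \eqn{(1, i)/\sqrt 2},
#' `jones_linear(angle)` is linear polarisation at `angle` radians from the
#' +x axis.
#'
#' @param angle orientation of the linear polarisation in radians.
#' @return Complex length-2 unit Jones vector.
#' @export
jones_circular <- function() complex(real = c(1, 0), imaginary = c(0, 1)) / sqrt(2)

#' @rdname jones_circular
#' @export
jones_linear <- function(angle = 0) as.complex(c(cos(angle), sin(angle)))

#' @export
print.optical_setup <- function(x, ...) {
  d <- derived_quantities(x)
  cat("<optical_setup>\n")
  cat(sprintf("  NA %.3g | lambda %g nm | n %g / ni %g | f %g mm\n",
              x$na, x$wavelength, x$n_sample, x$n_immersion, x$focal_length))
  cat(sprintf("  k = %.6g rad/nm, s_max = %.6g, theta_max = %.6g rad\n",
              d$k, d$s_max, d$theta_max))
  cat(sprintf("  polarisation (%.3g%+.3gi, %.3g%+.3gi)\n",
              Re(x$polarisation[1]), Im(x$polarisation[1]),
              Re(x$polarisation[2]), Im(x$polarisation[2])))
  invisible(x)
}

#' Derived optical quantities
#'
#' Computes the wavenumber `k = 2 pi n_sample / wavelength` (rad/nm), the
#' pupil cut-off `s_max = na / n_immersion`, and the maximal focusing
#' half-angle `theta_max = asin(s_max)` (rad) inside the immersion medium.
#'
#' @param setup an [optical_setup()].
#' @return A list with elements `k`, `s_max`, `theta_max`.
#' @export
derived_quantities <- function(setup) {
  stopifnot(inherits(setup, "optical_setup"))
  s_max <- setup$na / setup$n_immersion
  list(k = 2 * pi * setup$n_sample / setup$wavelength,
       s_max = s_max,
       theta_max = asin(s_max))
}

#' Sampling specification for pupil and focal planes
#'
#' @param pupil_size odd integer: samples per pupil axis for the Cartesian
#'   parameterisation, or number of theta samples for the spherical one.
#'   Odd size puts one sample exactly on the optical axis and gives the even
#'   interval count required by composite Simpson quadrature.
#' @param out_size odd integer side of the output image, so one pixel sits
#'   exactly at rho = 0.
#' @param pixel_size focal-plane sampling step in nm.
#' @param z_planes numeric vector of signed defocus distances in nm.
#' @return An object of class `sampling_grid`.
#' @examples
#' sampling_grid(pupil_size = 129, out_size = 101, pixel_size = 50)
#' @export
sampling_grid <- function(pupil_size = 513, out_size = 201, pixel_size = 20,
                          z_planes = 0) {
  stopifnot(is.numeric(pupil_size), length(pupil_size) == 1L,
            is.numeric(out_size), length(out_size) == 1L,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(z_planes), length(z_planes) >= 1L)
  pupil_size <- as.integer(pupil_size)
  out_size <- as.integer(out_size)
  if (pupil_size < 3L || pupil_size %% 2L == 0L)
    stop("`pupil_size` must be an odd integer >= 3")
  if (out_size < 1L || out_size %% 2L == 0L)
    stop("`out_size` must be an odd integer >= 1")
  structure(
    list(pupil_size = pupil_size, out_size = out_size,
         pixel_size = pixel_size, z_planes = as.numeric(z_planes)),
    class = "sampling_grid"
  )
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat("<sampling_grid>\n")
  cat(sprintf("  pupil %d | image %dx%d @ %g nm | %d z-plane(s)\n",
              x$pupil_size, x$out_size, x$out_size, x$pixel_size,
              length(x$z_planes)))
  invisible(x)
}

# Direction-cosine axis of an odd Cartesian pupil grid:
# s_i = -s_max + i * 2 s_max/(N-1), centre sample exactly on axis.
pupil_axis <- function(s_max, n) {
  if (n == 1L) return(0)
  seq(-s_max, s_max, length.out = n)
}

# Centered focal-plane axis in nm for an odd image side.
focal_axis <- function(out_size, pixel_size) {
  (seq_len(out_size) - 1 - (out_size - 1) / 2) * pixel_size
}
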