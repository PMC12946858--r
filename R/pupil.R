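#' Sampled pupil field
#'
#' A pupil field holds the sampled incident (or far) field on either a
#' Cartesian direction-cosine grid `(sx, sy)` covering
#' `[-s_max, s_max]^2` or a 1D spherical theta-line on `[0, theta_max]`.
#' Channels follow the field layout: 1 channel for scalar fields, 3
#' (x, y, z components) for vectorial ones. Cartesian values are identically
#' zero outside the pupil disk `sx^2 + sy^2 <= s_max^2`; the spherical
#' parameterisation is only defined for axisymmetric fields.
#'
#' @param values complex array: `(channels, N, N)` for Cartesian,
#'   `(channels, n_theta)` for spherical.
#' @param parameterisation `"cartesian"` or `"spherical"`.
#' @param setup the [optical_setup()] the sampling refers to.
#' @param axisymmetric logical flag; must be `TRUE` for spherical fields.
#' @return An object of class `pupil_field`.
#' @export
pupil_field <- function(values, parameterisation = c("cartesian", "spherical"),
                        setup, axisymmetric = FALSE) {
  parameterisation <- match.arg(parameterisation)
  stopifnot(inherits(setup, "optical_setup"))
  if (!is.complex(values)) values <- array(as.complex(values), dim = dim(values))
  if (parameterisation == "cartesian") {
    stopifnot(length(dim(values)) == 3L, dim(values)[2] == dim(values)[3])
  } else {
    if (is.null(dim(values))) values <- array(values, dim = c(1L, length(values)))
    stopifnot(length(dim(values)) == 2L)
    if (!axisymmetric)
      stop("spherical parameterisation requires an axisymmetric field")
  }
  ch <- dim(values)[1]
  if (!ch %in% c(1L, 3L))
    stop("pupil fields carry 1 (scalar) or 3 (vectorial) channels")
  structure(
    list(values = values, parameterisation = parameterisation,
         setup = setup, axisymmetric = isTRUE(axisymmetric)),
    class = "pupil_field"
  )
}

#' @export
print.pupil_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pupil_field> %s, %d channel(s), %s%s\n",
              x$parameterisation, d[1],
              if (x$parameterisation == "cartesian")
                sprintf("%dx%d grid", d[2], d[3])
              else sprintf("%d theta samples", d[2]),
              if (x$axisymmetric) ", axisymmetric" else ""))
  invisible(x)
}

#' Coordinates of the Cartesian pupil grid
#'
#' Direction cosines, radius, axial cosine, azimuth and in-disk mask for an
#' odd `n x n` pupil grid over `[-s_max, s_max]^2`; the place to sample
#' amplitude/phase correction factors for Cartesian pupils (e.g.
#' `gaussian_envelope(pupil_coords(setup, n)$sr, s_env)`).
#'
#' @param setup an [optical_setup()].
#' @param n grid side (odd).
#' @return List with the 1D axis `s`, matrices `sx`, `sy`, `sr`
#'   (`sin(theta)`), `sz` (`cos(theta)`), `phi`, logical `inside`, and the
#'   grid `step`.
#' @export
pupil_coords <- function(setup, n) {
  d <- derived_quantities(setup)
  s <- pupil_axis(d$s_max, n)
  sx <- matrix(s, n, n)                 # varies along rows (dim 1)
  sy <- matrix(s, n, n, byrow = TRUE)   # varies along columns (dim 2)
  sr2 <- sx^2 + sy^2
  inside <- sr2 <= d$s_max^2 + 1e-12 * d$s_max^2
  sr <- sqrt(pmin(sr2, 1))
  list(s = s, sx = sx, sy = sy, sr = sr, sz = sqrt(pmax(1 - sr2, 0)),
       phi = atan2(sy, sx), inside = inside, step = if (n > 1) s[2] - s[1] else 0)
}

#' Uniform (flat) pupil
#'
#' The canonical test pupil: unit amplitude and zero phase inside the
#' aperture disk (Cartesian) or constant 1 over `[0, theta_max]`
#' (spherical). The disk edge is a hard binary mask; no anti-aliasing, so
#' convergence-order measurements against the perfect circular aperture are
#' not contaminated by edge smoothing.
#'
#' @param setup an [optical_setup()].
#' @param grid a [sampling_grid()].
#' @param parameterisation `"cartesian"` or `"spherical"`.
#' @return A scalar (1-channel) axisymmetric [pupil_field()].
#' @examples
#' setup <- optical_setup(na = 0.5, wavelength = 632)
#' p <- uniform_pupil(setup, sampling_grid(pupil_size = 65))
#' @export
uniform_pupil <- function(setup, grid,
                          parameterisation = c("cartesian", "spherical")) {
  parameterisation <- match.arg(parameterisation)
  stopifnot(inherits(grid, "sampling_grid"))
  n <- grid$pupil_size
  if (parameterisation == "cartesian") {
    pc <- pupil_coords(setup, n)
    v <- array(as.complex(ifelse(pc$inside, 1, 0)), dim = c(1L, n, n))
    pupil_field(v, "cartesian", setup, axisymmetric = TRUE)
  } else {
    v <- array(as.complex(rep(1, n)), dim = c(1L, n))
    pupil_field(v, "spherical", setup, axisymmetric = TRUE)
  }
}

#' Apply a polarisation state to a scalar pupil
#'
#' Lifts a 1-channel scalar profile `p` to the 3-channel incident field
#' `(ex p, ey p, 0)` with Jones coefficients `(ex, ey)`; the incident field
#' has no longitudinal component before focusing. Circular polarisation
#' `(1, i)/sqrt(2)` is the usual choice for vectorial models.
#'
#' @param pupil a scalar (1-channel) [pupil_field()].
#' @param jones complex length-2 unit Jones vector; defaults to the
#'   polarisation stored in the pupil's setup.
#' @param tol tolerance on `| ||jones|| - 1 |`.
#' @return A 3-channel [pupil_field()] on the same parameterisation.
#' @export
apply_polarisation <- function(pupil, jones = pupil$setup$polarisation,
                               tol = 1e-8) {
  stopifnot(inherits(pupil, "pupil_field"))
  if (dim(pupil$values)[1] != 1L)
    stop("`pupil` must be a scalar (1-channel) field")
  jones <- as.complex(jones)
  if (length(jones) != 2L || abs(sqrt(sum(Mod(jones)^2)) - 1) > tol)
    stop("`jones` must be a unit-norm complex 2-vector")
  d <- dim(pupil$values)
  out <- array(complex(real = 0), dim = c(3L, d[-1]))
  if (pupil$parameterisation == "cartesian") {
    out[1L, , ] <- jones[1] * pupil$values[1L, , ]
    out[2L, , ] <- jones[2] * pupil$values[1L, , ]
  } else {
    out[1L, ] <- jones[1] * pupil$values[1L, ]
    out[2L, ] <- jones[2] * pupil$values[1L, ]
  }
  pupil_field(out, pupil$parameterisation, pupil$setup,
              axisymmetric = pupil$axisymmetric)
}

# Group in-disk samples of a Cartesian grid by radius (keyed on the squared
# integer lattice distance, exact in floating point for moderate N).
radial_bins <- function(n) {
  i <- seq_len(n) - 1 - (n - 1) / 2
  r2 <- outer(i^2, i^2, `+`)            # (2/(N-1))^2 s_max^2 units
  key <- as.integer(round(r2 * 4))      # 4 r2 is integer for half-int i
  list(key = key, radius = sqrt(r2) * 2 / (n - 1))  # radius in s_max units
}

#' Test a Cartesian pupil for axisymmetry
#'
#' A pupil is axisymmetric when its value depends only on the radius
#' (equivalently on theta), which is the condition under which the 1D
#' Bessel (spherical) parameterisation applies. The check groups in-disk
#' samples into exact radial bins of the integer lattice and requires the
#' standard deviation of the complex values within every bin to stay below
#' `tol` times the maximum amplitude of the pupil.
#'
#' @param pupil a Cartesian [pupil_field()].
#' @param tol relative tolerance; the default `1e-9` accepts exactly
#'   symmetric programmatic pupils up to rounding.
#' @return `TRUE` or `FALSE`.
#' @export
is_axisymmetric <- function(pupil, tol = 1e-9) {
  stopifnot(inherits(pupil, "pupil_field"))
  if (pupil$parameterisation != "cartesian")
    return(TRUE)
  n <- dim(pupil$values)[2]
  pc <- pupil_coords(pupil$setup, n)
  rb <- radial_bins(n)
  amax <- max(Mod(pupil$values))
  if (amax == 0) return(TRUE)
  for (ch in seq_len(dim(pupil$values)[1])) {
    v <- pupil$values[ch, , ][pc$inside]
    key <- rb$key[pc$inside]
    mu_re <- tapply(Re(v), key, mean)
    mu_im <- tapply(Im(v), key, mean)
    mu <- complex(real = mu_re, imaginary = mu_im)[match(key, as.integer(names(mu_re)))]
    dev <- sqrt(tapply(Mod(v - mu)^2, key, mean))
    if (any(dev > tol * amax)) return(FALSE)
  }
  TRUE
}

#' Collapse an axisymmetric Cartesian pupil to a spherical theta-profile
#'
#' Averages the Cartesian samples over exact radial bins and resamples the
#' resulting radial profile at `sin(theta)` for `n_theta` equally spaced
#' theta values on `[0, theta_max]`, interpolating linearly in
#' `sin(theta)`. Refuses non-axisymmetric pupils.
#'
#' @param pupil an axisymmetric Cartesian [pupil_field()].
#' @param n_theta number of theta samples of the output profile.
#' @param tol axisymmetry tolerance passed to [is_axisymmetric()].
#' @return A spherical [pupil_field()] with the same channel count.
#' @export
cartesian_to_spherical_profile <- function(pupil, n_theta = 1001, tol = 1e-9) {
  stopifnot(inherits(pupil, "pupil_field"))
  if (pupil$parameterisation != "cartesian")
    stop("`pupil` must use the cartesian parameterisation")
  if (!is_axisymmetric(pupil, tol = tol))
    stop("pupil is not axisymmetric; spherical parameterisation undefined")
  n <- dim(pupil$values)[2]
  ch <- dim(pupil$values)[1]
  d <- derived_quantities(pupil$setup)
  pc <- pupil_coords(pupil$setup, n)
  rb <- radial_bins(n)
  key <- rb$key[pc$inside]
  r_smax <- rb$radius[pc$inside]        # radius in units of s_max
  theta <- seq(0, d$theta_max, length.out = n_theta)
  st <- sin(theta) / d$s_max            # target radii, s_max units
  out <- array(complex(real = 0), dim = c(ch, n_theta))
  for (c_i in seq_len(ch)) {
    v <- pupil$values[c_i, , ][pc$inside]
    mu_re <- tapply(Re(v), key, mean)
    mu_im <- tapply(Im(v), key, mean)
    r_u <- tapply(r_smax, key, mean)
    o <- order(r_u)
    out[c_i, ] <- complex(
      real = stats::approx(r_u[o], mu_re[o], xout = st, rule = 2)$y,
      imaginary = stats::approx(r_u[o], mu_im[o], xout = st, rule = 2)$y)
  }
  pupil_field(out, "spherical", pupil$setup, axisymmetric = TRUE)
}

#' Import a custom pupil from a single-page TIFF
#'
#' Reads a single-page float TIFF and interprets it on the
#' `[-s_max, s_max]^2` pupil grid, either as an amplitude mask or as a
#' phase mask in radians (applied as `exp(1i * W)`). Values outside the
#' aperture disk are zeroed (amplitude) or ignored (phase).
#'
#' @param path path to a single-page TIFF whose side matches
#'   `grid$pupil_size`.
#' @param setup,grid optical setup and sampling specification.
#' @param what `"amplitude"` or `"phase"`.
#' @return A scalar Cartesian [pupil_field()].
#' @export
pupil_from_tiff <- function(path, setup, grid,
                            what = c("amplitude", "phase")) {
  what <- match.arg(what)
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  n <- grid$pupil_size
  if (!all(dim(img) == n))
    stop(sprintf("TIFF is %dx%d but pupil grid is %dx%d",
                 dim(img)[1], dim(img)[2], n, n))
  pc <- pupil_coords(setup, n)
  v <- if (what == "amplitude") as.complex(img * pc$inside)
       else as.complex(exp(1i * img) * pc$inside)
  pupil_field(array(v, dim = c(1L, n, n)), "cartesian", setup,
              axisymmetric = FALSE)
}
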