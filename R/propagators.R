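#' Focal field stack
#'
#' Container for the complex electric field near focus with fixed layout
#' `(z, channel, x, y)`: one channel for scalar propagators, three (x, y, z
#' field components) for vectorial ones. The focal azimuth phi is measured
#' from the +x axis, counter-clockwise; the first spatial dimension indexes
#' x, the second y.
#'
#' @param data complex 4D array `(z, channel, x, y)`.
#' @param pixel_size focal-plane sampling in nm.
#' @param z_planes defocus distances in nm, one per z slice.
#' @param propagator name of the propagator that produced the field.
#' @param setup the [optical_setup()] snapshot.
#' @return An object of class `focal_field`.
#' @export
focal_field <- function(data, pixel_size, z_planes, propagator = "unknown",
                        setup = NULL) {
  stopifnot(length(dim(data)) == 4L, dim(data)[1] == length(z_planes),
            dim(data)[2] %in% c(1L, 3L))
  structure(
    list(data = data, pixel_size = pixel_size, z_planes = z_planes,
         propagator = propagator, setup = setup),
    class = "focal_field"
  )
}

#' @export
print.focal_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<focal_field> %s: %d z-plane(s), %d channel(s), %dx%d @ %g nm\n",
              x$propagator, d[1], d[2], d[3], d[4], x$pixel_size))
  cat(sprintf("  z range [%g, %g] nm, peak |E| = %.4g\n",
              min(x$z_planes), max(x$z_planes), max(Mod(x$data))))
  invisible(x)
}

#' Intensity (or amplitude) of a focal field
#'
#' Sums `|E_c|^2` over the channel dimension, collapsing scalar and
#' vectorial stacks alike to a real `(z, x, y)` array; `amplitude = TRUE`
#' returns its square root.
#'
#' @param field a [focal_field()].
#' @param amplitude return `sqrt(sum |E_c|^2)` instead of the intensity.
#' @return Real array `(z, x, y)`.
#' @export
intensity <- function(field, amplitude = FALSE) {
  stopifnot(inherits(field, "focal_field"))
  d <- dim(field$data)
  out <- array(0, dim = d[c(1, 3, 4)])
  for (ch in seq_len(d[2])) {
    sl <- field$data[, ch, , , drop = FALSE]
    dim(sl) <- d[c(1, 3, 4)]
    out <- out + Mod(sl)^2
  }
  if (amplitude) sqrt(out) else out
}

#' Normalise a focal field
#'
#' `"none"` leaves the physical scale (including the `-ifk/(2 pi)`
#' prefactor) untouched, `"max"` rescales to unit peak amplitude, and
#' `"energy"` rescales so the summed intensity over the whole stack is 1.
#'
#' @param field a [focal_field()].
#' @param mode `"none"`, `"max"` or `"energy"`.
#' @return The rescaled [focal_field()].
#' @export
normalise_field <- function(field, mode = c("none", "max", "energy")) {
  mode <- match.arg(mode)
  if (mode == "none") return(field)
  sc <- switch(mode,
    max = max(Mod(field$data)),
    energy = sqrt(sum(Mod(field$data)^2)))
  if (sc > 0) field$data <- field$data / sc
  field
}

#' Basis change from the incident field to the far field
#'
#' Rotates the planar incident Jones field `(einc_x, einc_y, 0)` onto the
#' Gaussian reference sphere, producing the three Cartesian components of
#' the far field. Fresnel transmission coefficients `q_s`, `q_p` weight the
#' s- and p-polarised parts; with `q_s = q_p = 1` the matrix is a pure
#' rotation (norm-preserving) and reduces to the identity at `theta = 0`,
#' which is why scalar models skip the basis change altogether.
#'
#' @param einc_x,einc_y complex arrays of incident-field components.
#' @param sin_theta,cos_theta direction sines/cosines, same shape.
#' @param phi azimuth on the pupil, radians, same shape.
#' @param q_s,q_p Fresnel transmission coefficients (scalar or same shape).
#' @return List of complex components `ex`, `ey`, `ez`.
#' @export
far_field_from_incident <- function(einc_x, einc_y, sin_theta, cos_theta,
                                    phi, q_s = 1, q_p = 1) {
  einc_x <- as.complex(einc_x); einc_y <- as.complex(einc_y)
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  m11 <- (q_s * (1 - c2) + q_p * (1 + c2) * cos_theta) / 2
  m12 <- (-q_s + q_p * cos_theta) * s2 / 2
  m21 <- m12
  m22 <- (q_s * (1 + c2) + q_p * (1 - c2) * cos_theta) / 2
  m31 <- -q_p * cos(phi) * sin_theta
  m32 <- -q_p * sin(phi) * sin_theta
  list(ex = m11 * einc_x + m12 * einc_y,
       ey = m21 * einc_x + m22 * einc_y,
       ez = m31 * einc_x + m32 * einc_y)
}

#' Far field of a 3-channel Cartesian pupil
#'
#' Applies [far_field_from_incident()] across a Cartesian pupil grid,
#' turning an incident 3-channel pupil (z channel zero) into the far field
#' fed to [vectorial_cartesian()].
#'
#' @param pupil a 3-channel Cartesian [pupil_field()].
#' @param q_s,q_p Fresnel coefficients, scalar or `N x N` arrays (e.g. from
#'   [fresnel_coefficients()] evaluated on the grid angles).
#' @return A 3-channel Cartesian [pupil_field()] (generally not
#'   axisymmetric channel-by-channel).
#' @export
far_field_pupil <- function(pupil, q_s = 1, q_p = 1) {
  stopifnot(inherits(pupil, "pupil_field"),
            pupil$parameterisation == "cartesian",
            dim(pupil$values)[1] == 3L)
  n <- dim(pupil$values)[2]
  pc <- pupil_coords(pupil$setup, n)
  ff <- far_field_from_incident(pupil$values[1, , ], pupil$values[2, , ],
                                pc$sr, pc$sz, pc$phi, q_s, q_p)
  out <- array(complex(real = 0), dim = c(3L, n, n))
  out[1, , ] <- ff$ex; out[2, , ] <- ff$ey; out[3, , ] <- ff$ez
  pupil_field(out, "cartesian", pupil$setup, axisymmetric = FALSE)
}

# Constant focal-field prefactor -i f k / (2 pi), f converted mm -> nm.
rw_prefactor <- function(setup, k) {
  -1i * (setup$focal_length * 1e6) * k / (2 * pi)
}

# Shared Cartesian-propagator core: per z-plane multiply each channel by
# exp(i k sz z)/sz inside the disk and run the sized chirp-Z transform.
propagate_cartesian <- function(pupil, grid, extra_sz_power = 0) {
  setup <- pupil$setup
  d <- derived_quantities(setup)
  n <- dim(pupil$values)[2]
  stopifnot(n == grid$pupil_size)
  ch <- dim(pupil$values)[1]
  pc <- pupil_coords(setup, n)
  m <- grid$out_size
  nz <- length(grid$z_planes)
  # sz >= sqrt(1 - s_max^2) > 0 on the disk since na < n_immersion
  inv_sz <- ifelse(pc$inside, pc$sz^(extra_sz_power - 1), 0)
  pref <- rw_prefactor(setup, d$k) * pc$step^2
  out <- array(complex(real = 0), dim = c(nz, ch, m, m))
  for (iz in seq_len(nz)) {
    defocus <- exp(1i * d$k * pc$sz * grid$z_planes[iz]) * inv_sz
    for (c_i in seq_len(ch)) {
      g <- pupil$values[c_i, , ] * defocus
      out[iz, c_i, , ] <- pref *
        sized_ft_2d(g, pc$step, grid$pixel_size, m, d$k)
    }
  }
  out
}

#' Scalar Cartesian propagator
#'
#' Computes the focal field of a scalar pupil as the sized 2D Fourier
#' transform of `e(sx, sy) exp(i k sz z)/sz` over the pupil disk,
#' plane-by-plane along z, with the constant prefactor `-ifk/(2 pi)` and
#' the pupil-step area weight included so both parameterisations agree in
#' absolute value.
#'
#' @param pupil a scalar (1-channel) Cartesian [pupil_field()].
#' @param grid a [sampling_grid()].
#' @param normalisation passed to [normalise_field()].
#' @return A `(z, 1, x, y)` [focal_field()].
#' @examples
#' setup <- optical_setup(na = 0.5, wavelength = 632)
#' grid <- sampling_grid(pupil_size = 65, out_size = 41, pixel_size = 200)
#' psf <- scalar_cartesian(uniform_pupil(setup, grid), grid)
#' @export
scalar_cartesian <- function(pupil, grid, normalisation = "none") {
  stopifnot(inherits(pupil, "pupil_field"),
            pupil$parameterisation == "cartesian",
            dim(pupil$values)[1] == 1L)
  data <- propagate_cartesian(pupil, grid)
  normalise_field(
    focal_field(data, grid$pixel_size, grid$z_planes, "scalar_cartesian",
                pupil$setup),
    normalisation)
}

#' Vectorial Cartesian propagator
#'
#' Transforms the three far-field components independently with the same
#' `exp(i k sz z)/sz` defocus kernel and sized Fourier transform as the
#' scalar case. The input must already be a far field, i.e. have passed
#' through [far_field_pupil()] (the basis change is not applied here).
#'
#' @param pupil a 3-channel Cartesian [pupil_field()] (far field).
#' @param grid a [sampling_grid()].
#' @param normalisation passed to [normalise_field()].
#' @return A `(z, 3, x, y)` [focal_field()].
#' @export
vectorial_cartesian <- function(pupil, grid, normalisation = "none") {
  stopifnot(inherits(pupil, "pupil_field"),
            pupil$parameterisation == "cartesian",
            dim(pupil$values)[1] == 3L)
  data <- propagate_cartesian(pupil, grid)
  normalise_field(
    focal_field(data, grid$pixel_size, grid$z_planes, "vectorial_cartesian",
                pupil$setup),
    normalisation)
}

# Unique radial distances of the centred output grid, with the map from
# pixels to unique-radius indices (keyed on exact integer lattice r^2) and
# the focal azimuth per pixel.
focal_radii <- function(grid) {
  m <- grid$out_size
  i <- seq_len(m) - 1 - (m - 1) / 2
  r2key <- outer(i^2, i^2, `+`)
  x <- matrix(i, m, m) * grid$pixel_size
  y <- matrix(i, m, m, byrow = TRUE) * grid$pixel_size
  keys <- sort(unique(as.vector(r2key)))
  idx <- matrix(match(as.vector(r2key), keys), m, m)
  list(r_unique = sqrt(keys) * grid$pixel_size, idx = idx,
       phi = atan2(y, x))
}

# J_order(k r sin theta) sampled as an (radii x theta) matrix.
bessel_matrix <- function(order, k, radii, theta) {
  matrix(bessel_j(order, outer(radii, sin(theta)) * k),
         length(radii), length(theta))
}

# Radial Bessel-kernel integral evaluated at given radii for one z-plane:
# integral over theta of prof * kernel(theta) * J_order(k r sin theta)
# * exp(i k z cos theta) dtheta, via the requested composite rule.
bessel_integral <- function(prof_kernel, theta, k, radii, z, order, rule,
                            bmat = bessel_matrix(order, k, radii, theta)) {
  h <- if (length(theta) > 1) theta[2] - theta[1] else 1
  w <- quadrature_weights(length(theta), h, rule)
  fz <- w * prof_kernel * exp(1i * k * z * cos(theta))
  as.vector(bmat %*% fz)
}

#' Scalar spherical (Bessel) propagator
#'
#' For an axisymmetric pupil the azimuthal integral of the focal-field
#' integral closes to a Bessel function, leaving the 1D theta-line integral
#' \deqn{E(\rho, z) = -ifk \int_0^{\theta_{max}} e(\theta)
#'   J_0(k\rho\sin\theta) e^{ikz\cos\theta} \sin\theta \, d\theta,}
#' computed here by composite quadrature at the unique radii of the output
#' grid and scattered onto the 2D image by radial symmetry, batched over
#' z-planes. Pixels at equal radius are bit-identical by construction.
#'
#' @param pupil a scalar spherical [pupil_field()] (theta-profile), e.g.
#'   from [uniform_pupil()] or [cartesian_to_spherical_profile()].
#' @param grid a [sampling_grid()].
#' @param rule a [quadrature_rule()] or rule name; the profile length fixes
#'   `n_points`.
#' @param normalisation passed to [normalise_field()].
#' @return A `(z, 1, x, y)` [focal_field()].
#' @export
scalar_spherical <- function(pupil, grid, rule = "simpson",
                             normalisation = "none") {
  stopifnot(inherits(pupil, "pupil_field"),
            pupil$parameterisation == "spherical",
            dim(pupil$values)[1] == 1L)
  name <- if (inherits(rule, "quadrature_rule")) rule$name
          else match.arg(rule, c("simpson", "riemann"))
  setup <- pupil$setup
  d <- derived_quantities(setup)
  n_theta <- dim(pupil$values)[2]
  theta <- seq(0, d$theta_max, length.out = n_theta)
  fr <- focal_radii(grid)
  m <- grid$out_size
  nz <- length(grid$z_planes)
  pref <- -1i * (setup$focal_length * 1e6) * d$k
  prof <- pupil$values[1, ] * sin(theta)
  b0 <- bessel_matrix(0L, d$k, fr$r_unique, theta)
  out <- array(complex(real = 0), dim = c(nz, 1L, m, m))
  for (iz in seq_len(nz)) {
    e_u <- pref * bessel_integral(prof, theta, d$k, fr$r_unique,
                                  grid$z_planes[iz], 0L, name, b0)
    out[iz, 1L, , ] <- matrix(e_u[fr$idx], m, m)
  }
  normalise_field(
    focal_field(out, grid$pixel_size, grid$z_planes, "scalar_spherical",
                setup),
    normalisation)
}

#' Vectorial spherical (Bessel) propagator
#'
#' For an axisymmetric incident field the basis change and azimuthal
#' integration close analytically into six radial integrals
#' `I0a, I1a, I2a` (`a` in x, y) with kernels
#' `sin(theta)(q_s + q_p cos(theta)) J0`, `q_p sin^2(theta) J1` and
#' `sin(theta)(q_p cos(theta) - q_s) J2`, which assemble into
#' \deqn{E_x = -\tfrac{ifk}{2}(I_{0x} - I_{2x}\cos 2\varphi
#'    - I_{2y}\sin 2\varphi)}
#' \deqn{E_y = -\tfrac{ifk}{2}(-I_{2x}\sin 2\varphi + I_{0y}
#'    + I_{2y}\cos 2\varphi)}
#' \deqn{E_z = -\tfrac{ifk}{2}(-2i I_{1x}\cos\varphi
#'    - 2i I_{1y}\sin\varphi).}
#' With unit Fresnel coefficients (the default) the kernels reduce to the
#' classic `(cos theta + 1)`, `sin theta`, `(cos theta - 1)` forms. On the
#' optical axis `J1(0) = J2(0) = 0`, so the longitudinal component vanishes
#' at `rho = 0`.
#'
#' @param pupil a 3-channel spherical [pupil_field()] holding the incident
#'   x/y theta-profiles (z channel zero), e.g. from [apply_polarisation()]
#'   on a spherical scalar pupil.
#' @param grid a [sampling_grid()].
#' @param rule quadrature rule or name.
#' @param q_s,q_p Fresnel transmission coefficients, scalar or length
#'   `n_theta` vectors over the theta-line.
#' @param normalisation passed to [normalise_field()].
#' @return A `(z, 3, x, y)` [focal_field()].
#' @export
vectorial_spherical <- function(pupil, grid, rule = "simpson",
                                q_s = 1, q_p = 1, normalisation = "none") {
  stopifnot(inherits(pupil, "pupil_field"),
            pupil$parameterisation == "spherical",
            dim(pupil$values)[1] == 3L)
  if (any(Mod(pupil$values[3, ]) > 0))
    stop("incident field must have a zero longitudinal (z) channel")
  name <- if (inherits(rule, "quadrature_rule")) rule$name
          else match.arg(rule, c("simpson", "riemann"))
  setup <- pupil$setup
  d <- derived_quantities(setup)
  n_theta <- dim(pupil$values)[2]
  theta <- seq(0, d$theta_max, length.out = n_theta)
  st <- sin(theta); ct <- cos(theta)
  fr <- focal_radii(grid)
  m <- grid$out_size
  nz <- length(grid$z_planes)
  pref <- -1i * (setup$focal_length * 1e6) * d$k / 2
  k0 <- st * (q_s + q_p * ct)       # J0 kernel
  k1 <- q_p * st^2                  # J1 kernel
  k2 <- st * (q_p * ct - q_s)       # J2 kernel
  c2 <- cos(2 * fr$phi); s2 <- sin(2 * fr$phi)
  c1 <- cos(fr$phi); s1 <- sin(fr$phi)
  b0 <- bessel_matrix(0L, d$k, fr$r_unique, theta)
  b1 <- bessel_matrix(1L, d$k, fr$r_unique, theta)
  b2 <- bessel_matrix(2L, d$k, fr$r_unique, theta)
  out <- array(complex(real = 0), dim = c(nz, 3L, m, m))
  for (iz in seq_len(nz)) {
    z <- grid$z_planes[iz]
    ex <- pupil$values[1, ]; ey <- pupil$values[2, ]
    i0x <- bessel_integral(ex * k0, theta, d$k, fr$r_unique, z, 0L, name, b0)[fr$idx]
    i1x <- bessel_integral(ex * k1, theta, d$k, fr$r_unique, z, 1L, name, b1)[fr$idx]
    i2x <- bessel_integral(ex * k2, theta, d$k, fr$r_unique, z, 2L, name, b2)[fr$idx]
    i0y <- bessel_integral(ey * k0, theta, d$k, fr$r_unique, z, 0L, name, b0)[fr$idx]
    i1y <- bessel_integral(ey * k1, theta, d$k, fr$r_unique, z, 1L, name, b1)[fr$idx]
    i2y <- bessel_integral(ey * k2, theta, d$k, fr$r_unique, z, 2L, name, b2)[fr$idx]
    out[iz, 1L, , ] <- pref * (i0x - i2x * c2 - i2y * s2)
    out[iz, 2L, , ] <- pref * (-i2x * s2 + i0y + i2y * c2)
    out[iz, 3L, , ] <- pref * (-2i * i1x * c1 - 2i * i1y * s1)
  }
  normalise_field(
    focal_field(out, grid$pixel_size, grid$z_planes, "vectorial_spherical",
                setup),
    normalisation)
}
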