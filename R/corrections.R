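#' Stratified sample--coverslip--immersion medium
#'
#' Describes the layered geometry behind index-mismatch (Gibson--Lanni)
#' spherical aberration: refractive indices and thicknesses of the sample,
#' immersion and coverslip-glass layers under the actual imaging condition
#' and under the design condition of the objective (starred values).
#'
#' @param n_s,n_i,n_g refractive indices of sample, immersion, glass.
#' @param t_s,t_i,t_g thicknesses in nm; `t_i = NULL` means "derive it from
#'   the focusing condition" via [immersion_thickness_from_focus()].
#' @param n_i_star,n_g_star,t_i_star,t_g_star design-condition
#'   counterparts; indices default to the actual values.
#' @return An object of class `layered_medium`.
#' @examples
#' layered_medium(n_s = 1.3, n_i = 1.5, n_g = 1.5,
#'                t_s = 1e3, t_g = 170e3,
#'                t_i_star = 100e3, t_g_star = 170e3)
#' @export
layered_medium <- function(n_s, n_i, n_g, t_s = 0, t_i = NULL, t_g = 0,
                           n_i_star = n_i, n_g_star = n_g,
                           t_i_star = 0, t_g_star = t_g) {
  idx <- c(n_s, n_i, n_g, n_i_star, n_g_star)
  if (any(idx < 1)) stop("refractive indices must be >= 1")
  th <- c(t_s, t_g, t_i_star, t_g_star, if (!is.null(t_i)) t_i)
  if (any(th < 0)) stop("thicknesses must be >= 0")
  structure(
    list(n_s = n_s, n_i = n_i, n_g = n_g,
         t_s = t_s, t_i = t_i, t_g = t_g,
         n_i_star = n_i_star, n_g_star = n_g_star,
         t_i_star = t_i_star, t_g_star = t_g_star),
    class = "layered_medium"
  )
}

#' Immersion thickness from the focusing condition
#'
#' The immersion thickness is rarely known: it is set implicitly when the
#' microscopist refocuses on an emitter at depth `t_s`. That focusing
#' condition fixes
#' \deqn{t_i = t_s + n_i(-t_s/n_s - t_g/n_g + t_g^*/n_g^* + t_i^*/n_i^*),}
#' which reproduces `t_i = t_i*` exactly under matched conditions.
#'
#' @param medium a [layered_medium()].
#' @return Immersion thickness in nm.
#' @export
immersion_thickness_from_focus <- function(medium) {
  stopifnot(inherits(medium, "layered_medium"))
  m <- medium
  if (any(c(m$n_s, m$n_g, m$n_g_star, m$n_i_star) == 0))
    stop("refractive indices must be non-zero")
  m$t_s + m$n_i * (-m$t_s / m$n_s - m$t_g / m$n_g +
                   m$t_g_star / m$n_g_star + m$t_i_star / m$n_i_star)
}

#' Gibson--Lanni index-mismatch aberration phase
#'
#' Optical-path-difference phase accumulated by a ray at angle theta
#' through the stratified stack, relative to the design condition:
#' \deqn{W(\theta) = \frac{2\pi}{\lambda}\Big[
#'   t_s\sqrt{n_s^2 - n_i^2\sin^2\theta}
#'   + t_i\sqrt{n_i^2 - n_i^2\sin^2\theta}
#'   - t_i^*\sqrt{n_i^{*2} - n_i^2\sin^2\theta}
#'   + t_g\sqrt{n_g^2 - n_i^2\sin^2\theta}
#'   - t_g^*\sqrt{n_g^{*2} - n_i^2\sin^2\theta}\Big].}
#' Where a square-root argument turns negative (a supercritical angle into
#' a lower-index layer) the term is kept complex: its imaginary part
#' produces the physically expected evanescent amplitude decay through
#' `exp(iW)` instead of a hard clip.
#'
#' @param medium a [layered_medium()]; a `NULL` `t_i` is filled in via
#'   [immersion_thickness_from_focus()].
#' @param setup an [optical_setup()] (provides the vacuum wavelength).
#' @param sin_theta numeric vector/array of `sin(theta)` values.
#' @return Complex phase W in radians, same shape as `sin_theta` (real
#'   whenever every layer index exceeds `n_i sin(theta)`).
#' @export
gibson_lanni_phase <- function(medium, setup, sin_theta) {
  stopifnot(inherits(medium, "layered_medium"), inherits(setup, "optical_setup"))
  m <- medium
  t_i <- if (is.null(m$t_i)) immersion_thickness_from_focus(m) else m$t_i
  u2 <- (m$n_i * sin_theta)^2
  csqrt <- function(a) sqrt(as.complex(a))
  w <- m$t_s * csqrt(m$n_s^2 - u2) +
       t_i * csqrt(m$n_i^2 - u2) -
       m$t_i_star * csqrt(m$n_i_star^2 - u2) +
       m$t_g * csqrt(m$n_g^2 - u2) -
       m$t_g_star * csqrt(m$n_g_star^2 - u2)
  w <- 2 * pi / setup$wavelength * w
  if (!is.null(dim(sin_theta))) dim(w) <- dim(sin_theta)
  w
}

#' Vortex (spiral) phase mask
#'
#' Azimuthal phase ramp `W = charge * phi` wrapped to `[0, 2 pi)`, the
#' pupil mask producing the donut PSF used in STED; `charge = 0` is the
#' identity.
#'
#' @param setup,grid optical setup and sampling specification (Cartesian
#'   pupil grid).
#' @param charge integer topological charge.
#' @return Real `N x N` phase matrix in radians.
#' @export
vortex_phase <- function(setup, grid, charge = 1L) {
  stopifnot(charge == round(charge))
  pc <- pupil_coords(setup, grid$pupil_size)
  (charge * pc$phi) %% (2 * pi)
}

#' Half-moon (pi-step) phase mask
#'
#' A pi phase jump across the `sx = 0` line of the pupil, splitting the
#' focal spot into two lobes along x.
#'
#' @param setup,grid optical setup and sampling specification.
#' @return Real `N x N` phase matrix (0 or pi).
#' @export
half_moon_phase <- function(setup, grid) {
  pc <- pupil_coords(setup, grid$pupil_size)
  pi * (pc$sx > 0)
}

#' Apodisation amplitude factor
#'
#' Energy-conserving amplitude rescaling for the change of basis from the
#' planar incident field to the Gaussian reference sphere,
#' `A = cos(theta)^exponent`. The default exponent is 1 (`A = cos theta`);
#' the classic square-root convention is available via `exponent = 0.5` and
#' is never substituted silently.
#'
#' @param sin_theta numeric vector/array of `sin(theta)`.
#' @param exponent power applied to `cos(theta)`.
#' @return Real amplitude factor, same shape as `sin_theta`.
#' @export
apodisation <- function(sin_theta, exponent = 1) {
  ct <- sqrt(pmax(1 - sin_theta^2, 0))
  a <- ct^exponent
  if (!is.null(dim(sin_theta))) dim(a) <- dim(sin_theta)
  a
}

#' Gaussian beam envelope
#'
#' Amplitude profile `A = exp(-sin^2(theta)/s_env^2)` of an incident beam
#' that is Gaussian rather than a uniform plane wave; `s_env` sets the
#' envelope size in direction-cosine units.
#'
#' @param sin_theta numeric vector/array of `sin(theta)`.
#' @param s_env envelope width, `> 0`.
#' @return Real amplitude factor, same shape as `sin_theta`.
#' @export
gaussian_envelope <- function(sin_theta, s_env) {
  if (!is.numeric(s_env) || length(s_env) != 1L || s_env <= 0)
    stop("`s_env` must be a positive scalar")
  exp(-sin_theta^2 / s_env^2)
}

#' Fresnel transmission coefficients through a layer stack
#'
#' Product of the per-interface amplitude transmission coefficients for s-
#' and p-polarisation along a stack of planar layers. Angles in successive
#' layers follow Snell's law `n_m sin(theta_m) = n_1 sin(theta_1)`;
#' supercritical transmission into a lower-index layer yields a complex
#' `cos(theta)` and hence complex (evanescent) coefficients, returned as
#' such. A single layer is the empty product `q_s = q_p = 1`.
#'
#' @param indices ordered refractive indices `n_1..n_L` along propagation.
#' @param theta_1 incidence angle(s) in the first medium, radians.
#' @return List with complex components `q_s`, `q_p` shaped like `theta_1`.
#' @examples
#' fresnel_coefficients(c(1.0, 1.5), 0)  # q_s = q_p = 0.8
#' @export
fresnel_coefficients <- function(indices, theta_1) {
  stopifnot(length(indices) >= 1L, all(indices > 0))
  u <- indices[1] * sin(theta_1)               # conserved transverse component
  q_s <- q_p <- array(1 + 0i, dim = if (is.null(dim(theta_1))) length(theta_1)
                                    else dim(theta_1))
  L <- length(indices)
  if (L >= 2L) {
    for (m in seq_len(L - 1L)) {
      n1 <- indices[m]; n2 <- indices[m + 1L]
      c1 <- sqrt(as.complex(1 - (u / n1)^2))
      c2 <- sqrt(as.complex(1 - (u / n2)^2))
      q_s <- q_s * 2 * n1 * c1 / (n1 * c1 + n2 * c2)
      q_p <- q_p * 2 * n1 * c1 / (n2 * c1 + n1 * c2)
    }
  }
  if (is.null(dim(theta_1))) { dim(q_s) <- NULL; dim(q_p) <- NULL }
  list(q_s = q_s, q_p = q_p)
}

#' Apply amplitude and phase correction factors to a pupil
#'
#' Multiplies the pupil values by `prod(a) * exp(1i * sum(W))` for any
#' number of amplitude factors `a` and phase factors `W` sampled on the
#' pupil's own parameterisation. All factors are composed into a single
#' multiplier before application, so the result is independent of factor
#' ordering bit for bit. Phases may be complex (evanescent terms from
#' supercritical angles).
#'
#' @param pupil a [pupil_field()].
#' @param amplitude list (or single array) of amplitude factors.
#' @param phase list (or single array) of phase factors in radians.
#' @return The corrected [pupil_field()].
#' @export
apply_corrections <- function(pupil, amplitude = list(), phase = list()) {
  stopifnot(inherits(pupil, "pupil_field"))
  if (!is.list(amplitude)) amplitude <- list(amplitude)
  if (!is.list(phase)) phase <- list(phase)
  d <- dim(pupil$values)
  shape <- d[-1]
  mult <- array(1 + 0i, dim = shape)
  for (a in amplitude) {
    if (!all(dim(as.array(a)) == shape) && length(a) != prod(shape))
      stop("amplitude factor shape does not match the pupil sampling")
    mult <- mult * as.complex(a)
  }
  wsum <- array(0 + 0i, dim = shape)
  for (w in phase) {
    if (!all(dim(as.array(w)) == shape) && length(w) != prod(shape))
      stop("phase factor shape does not match the pupil sampling")
    wsum <- wsum + as.complex(w)
  }
  mult <- mult * exp(1i * wsum)
  out <- pupil$values
  for (ch in seq_len(d[1])) {
    if (pupil$parameterisation == "cartesian") out[ch, , ] <- out[ch, , ] * mult
    else out[ch, ] <- out[ch, ] * mult
  }
  axi <- pupil$axisymmetric
  p2 <- pupil_field(out, pupil$parameterisation, pupil$setup,
                    axisymmetric = axi || pupil$parameterisation == "spherical")
  if (p2$parameterisation == "cartesian")
    p2$axisymmetric <- is_axisymmetric(p2)
  p2
}
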