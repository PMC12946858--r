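#' Zernike polynomials (OSA/ANSI single index, orthonormal)
#'
#' Evaluates the Zernike polynomial with OSA/ANSI single index `j` on polar
#' coordinates of the unit disk. The index maps to radial degree `n` and
#' azimuthal frequency `m` through `j = (n(n+2) + m)/2`; negative `m` pairs
#' with `sin(|m| phi)`, positive with `cos(m phi)`. Normalisation is
#' orthonormal with respect to the area-averaged inner product
#' `(1/pi) int_disk Zj Zk dA = delta_jk`: the radial polynomial is scaled
#' by `sqrt(n+1)` for `m = 0` and `sqrt(2(n+1))` otherwise. `j = 0` is
#' piston (constant 1), `j = 4` defocus, `j = 3`/`j = 5` oblique/vertical
#' astigmatism.
#'
#' @param j OSA/ANSI index, `j >= 0`.
#' @param rho radius in `[0, 1]` (values outside return 0).
#' @param phi azimuth in radians.
#' @return Numeric vector/array of polynomial values.
#' @export
zernike <- function(j, rho, phi) {
  stopifnot(j >= 0, j == round(j))
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  am <- abs(m)
  r <- numeric(length(rho))
  for (s in 0:((n - am) / 2)) {
    r <- r + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + am) / 2 - s) * factorial((n - am) / 2 - s)) *
      rho^(n - 2 * s)
  }
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0) cos(am * phi) else if (m < 0) sin(am * phi) else 1
  out <- norm * r * ang
  out[rho > 1] <- 0
  if (!is.null(dim(rho))) dim(out) <- dim(rho)
  out
}

#' Aberration specification
#'
#' Bundles a Zernike expansion and an optional fixed phase mask into one
#' pupil phase `W = sum_k c_k Z_k + W0`. Coefficients are interpreted in
#' radians by default; set `unit = "waves"` to scale by `2 pi`.
#'
#' @param zernike_coeffs list of `c(index, coefficient)` pairs, or a 2-column
#'   matrix; OSA/ANSI indexing.
#' @param custom_phase optional phase mask in radians matching the pupil
#'   grid.
#' @param unit `"radians"` (default) or `"waves"`.
#' @return An object of class `aberration_spec`.
#' @examples
#' aberration_spec(list(c(5, 1.2)))  # vertical astigmatism, 1.2 rad
#' @export
aberration_spec <- function(zernike_coeffs = list(), custom_phase = NULL,
                            unit = c("radians", "waves")) {
  unit <- match.arg(unit)
  if (is.matrix(zernike_coeffs))
    zernike_coeffs <- lapply(seq_len(nrow(zernike_coeffs)),
                             function(i) zernike_coeffs[i, ])
  for (p in zernike_coeffs)
    if (length(p) != 2L || p[1] < 0 || p[1] != round(p[1]))
      stop("each Zernike term must be a c(index, coefficient) pair")
  structure(list(zernike_coeffs = zernike_coeffs, custom_phase = custom_phase,
                 unit = unit),
            class = "aberration_spec")
}

#' Pupil phase from a Zernike expansion plus a fixed mask
#'
#' Assembles `W = sum_k c_k Z_k(rho_unit, phi) + W0` on the Cartesian pupil
#' grid, mapping the pupil radius `s_max` to the unit radius of the Zernike
#' disk. General (non-axisymmetric) Zernike terms only make sense on the
#' Cartesian parameterisation; the spherical propagators refuse them
#' upstream.
#'
#' @param spec an [aberration_spec()].
#' @param setup,grid optical setup and sampling specification.
#' @return Real `N x N` phase matrix in radians.
#' @export
zernike_phase <- function(spec, setup, grid) {
  stopifnot(inherits(spec, "aberration_spec"))
  n <- grid$pupil_size
  d <- derived_quantities(setup)
  pc <- pupil_coords(setup, n)
  rho <- pc$sr / d$s_max
  scale <- if (spec$unit == "waves") 2 * pi else 1
  w <- matrix(0, n, n)
  for (p in spec$zernike_coeffs)
    w <- w + scale * p[2] * zernike(p[1], rho, pc$phi)
  if (!is.null(spec$custom_phase)) {
    if (!all(dim(spec$custom_phase) == c(n, n)))
      stop("`custom_phase` must match the pupil grid")
    w <- w + spec$custom_phase
  }
  w
}
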