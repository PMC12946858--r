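#' Analytic Airy pattern
#'
#' Amplitude of the paraxial diffraction pattern of a uniform circular
#' aperture, `F(rho) = 2 J1(rho)/rho` with `F(0) = 1` by the series limit,
#' on the dimensionless radial coordinate `rho = k s_max rho_phys`. Its
#' first zero sits at the first root of J1, ~3.8317.
#'
#' @param rho non-negative dimensionless radii.
#' @return Real vector of amplitudes, peak 1 at the origin.
#' @export
airy_disk <- function(rho) {
  stopifnot(all(rho >= 0))
  out <- ifelse(rho < 1e-8, 1 - rho^2 / 8, 2 * bessel_j(1L, rho) / rho)
  if (!is.null(dim(rho))) dim(out) <- dim(rho)
  out
}

#' L2 error between a field and a reference
#'
#' Plain Euclidean norm of the difference, `delta = ||E - F||_2`, over
#' arrays of identical shape. Symmetric in its arguments; any peak
#' normalisation is the caller's responsibility (the Airy benchmark
#' rescales both sides to unit peak first).
#'
#' @param field,reference numeric or complex arrays of the same shape.
#' @return Non-negative scalar.
#' @export
l2_error <- function(field, reference) {
  if (!identical(dim(field), dim(reference)) ||
      length(field) != length(reference))
    stop("`field` and `reference` must have the same shape")
  sqrt(sum(Mod(field - reference)^2))
}

#' Convergence report
#'
#' Pairs of (integration step size, L2 error against the analytic Airy
#' disk) with the least-squares log-log slope over the densest decade of
#' step sizes, discarding densities where the error has hit the
#' floating-point floor (`delta < 1e-12`), which would flatten the slope.
#'
#' @param h strictly decreasing step sizes.
#' @param errors positive L2 errors, one per step size.
#' @param propagator,rule labels for the benchmarked method.
#' @return An object of class `convergence_report` with a `fitted_order`
#'   element.
#' @export
convergence_report <- function(h, errors, propagator, rule = NA_character_) {
  stopifnot(length(h) == length(errors), all(errors > 0))
  if (any(diff(h) >= 0))
    stop("step sizes `h` must be strictly decreasing")
  keep <- errors > 1e-12
  hk <- h[keep]; ek <- errors[keep]
  dec <- hk <= 10 * min(hk)
  if (sum(dec) < 3L)
    stop("need at least 3 usable densities to fit a convergence order")
  fit <- stats::lm(log10(ek[dec]) ~ log10(hk[dec]))
  structure(
    list(h = h, errors = errors, fitted_order = unname(coef(fit)[2]),
         propagator = propagator, rule = rule),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s%s\n", x$propagator,
              if (!is.na(x$rule)) paste0(" / ", x$rule) else ""))
  cat(sprintf("  fitted order %.3f over %d densities (h in [%.3g, %.3g])\n",
              x$fitted_order, length(x$h), min(x$h), max(x$h)))
  invisible(x)
}

#' @export
plot.convergence_report <- function(x, ...) {
  graphics::plot(x$h, x$errors, log = "xy", type = "b", pch = 19,
                 xlab = "step size h", ylab = "L2 error",
                 main = sprintf("%s%s: order %.2f", x$propagator,
                                if (!is.na(x$rule)) paste0(" / ", x$rule) else "",
                                x$fitted_order), ...)
  invisible(x)
}

#' Write a convergence report as JSON
#'
#' @param report a [convergence_report()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(
    list(propagator = report$propagator, rule = report$rule,
         h = report$h, errors = report$errors,
         fitted_order = report$fitted_order),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Airy-disk accuracy benchmark
#'
#' Measures how fast each scalar propagator converges to the analytic Airy
#' amplitude on a uniform circular aperture. An extra `cos(theta)`
#' amplitude factor is applied to the pupil, cancelling the `1/sz`
#' propagation kernel so that the continuum limit is exactly the Fourier
#' transform of the flat disk (the paraxial Airy pattern) at every NA. For
#' each sampling density the focal plane at `z = 0` is computed, the field
#' on a 1D radial line through the centre is rescaled by its on-axis value,
#' and the L2 error against `airy_disk(k s_max rho)` is recorded; the
#' convergence order is the log-log slope of error versus step size.
#'
#' The spherical propagator inherits the order of the quadrature rule
#' (1 for left Riemann, 4 for composite Simpson); the Cartesian propagator
#' is limited by the jagged discretisation of the disk boundary to an
#' order between 1 and 2.
#'
#' @param parameterisation `"spherical"` or `"cartesian"`.
#' @param rule quadrature rule name (spherical only).
#' @param n_points integer vector of sampling densities: theta samples for
#'   spherical, pupil sides for Cartesian; at least 3, each odd.
#' @param setup an [optical_setup()].
#' @param grid a [sampling_grid()]; only `out_size` and `pixel_size` are
#'   used (single plane at `z = 0`).
#' @return A [convergence_report()].
#' @examples
#' setup <- optical_setup(na = 0.5, wavelength = 632)
#' grid <- sampling_grid(out_size = 101, pixel_size = 150)
#' airy_benchmark("spherical", "simpson", c(51, 101, 201), setup, grid)
#' @export
airy_benchmark <- function(parameterisation = c("spherical", "cartesian"),
                           rule = "simpson", n_points, setup, grid) {
  parameterisation <- match.arg(parameterisation)
  if (length(n_points) < 3L)
    stop("need at least 3 sampling densities to fit a convergence order")
  d <- derived_quantities(setup)
  half <- (grid$out_size - 1) / 2
  radii <- (0:half) * grid$pixel_size
  ref <- airy_disk(d$k * d$s_max * radii)
  hs <- errs <- numeric(length(n_points))
  for (i in seq_along(n_points)) {
    n <- as.integer(n_points[i])
    if (parameterisation == "spherical") {
      theta <- seq(0, d$theta_max, length.out = n)
      e_line <- bessel_integral(cos(theta) * sin(theta), theta, d$k,
                                radii, 0, 0L, rule)
      hs[i] <- d$theta_max / (n - 1)
    } else {
      g_n <- sampling_grid(pupil_size = n, out_size = grid$out_size,
                           pixel_size = grid$pixel_size, z_planes = 0)
      pup <- uniform_pupil(setup, g_n)
      data <- propagate_cartesian(pup, g_n, extra_sz_power = 1)
      cidx <- half + 1
      e_line <- data[1, 1, cidx:grid$out_size, cidx]
      hs[i] <- 2 * d$s_max / (n - 1)
    }
    e_norm <- e_line / e_line[1]
    errs[i] <- l2_error(e_norm, ref)
  }
  convergence_report(hs, errs, paste0("scalar_", parameterisation),
                     if (parameterisation == "spherical") rule else NA_character_)
}
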