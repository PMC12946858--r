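#' Full run configuration
#'
#' Gathers everything one PSF computation needs: the optical setup, the
#' sampling specification, the propagator choice (scalar/vectorial crossed
#' with cartesian/spherical), optional correction factors, and the output
#' disposition. Validation collects every problem before failing, and
#' refuses non-axisymmetric corrections (non-radial Zernike terms, vortex
#' and half-moon masks, custom masks) on the spherical parameterisation,
#' where only theta-dependent pupils are defined.
#'
#' @param setup an [optical_setup()].
#' @param grid a [sampling_grid()].
#' @param model `"scalar"` or `"vectorial"`.
#' @param parameterisation `"cartesian"` or `"spherical"`.
#' @param gibson_lanni optional [layered_medium()] enabling index-mismatch
#'   aberration.
#' @param aberration optional [aberration_spec()] (Cartesian only unless
#'   purely radial).
#' @param vortex_charge integer vortex charge, 0 = off (Cartesian only).
#' @param half_moon logical, pi-step mask (Cartesian only).
#' @param apodisation_on logical; apply the `cos(theta)^apodisation_exponent`
#'   factor.
#' @param apodisation_exponent exponent of the apodisation factor.
#' @param gaussian_s_env optional Gaussian envelope width (direction-cosine
#'   units), `NULL` = off.
#' @param output_path optional file path for [save_stack()].
#' @param output_format `"tiff"` or `"rds"`.
#' @param output_mode `"complex"`, `"amplitude"` or `"intensity"`.
#' @param normalisation `"none"`, `"max"` or `"energy"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(setup, grid,
                       model = c("scalar", "vectorial"),
                       parameterisation = c("cartesian", "spherical"),
                       gibson_lanni = NULL, aberration = NULL,
                       vortex_charge = 0L, half_moon = FALSE,
                       apodisation_on = FALSE, apodisation_exponent = 1,
                       gaussian_s_env = NULL,
                       output_path = NULL, output_format = "rds",
                       output_mode = "complex",
                       normalisation = c("none", "max", "energy")) {
  model <- match.arg(model)
  parameterisation <- match.arg(parameterisation)
  normalisation <- match.arg(normalisation)
  problems <- character()
  if (!inherits(setup, "optical_setup"))
    problems <- c(problems, "`setup` must be an optical_setup")
  if (!inherits(grid, "sampling_grid"))
    problems <- c(problems, "`grid` must be a sampling_grid")
  if (!is.null(gibson_lanni) && !inherits(gibson_lanni, "layered_medium"))
    problems <- c(problems, "`gibson_lanni` must be a layered_medium")
  if (!is.null(aberration) && !inherits(aberration, "aberration_spec"))
    problems <- c(problems, "`aberration` must be an aberration_spec")
  if (parameterisation == "spherical") {
    if (vortex_charge != 0)
      problems <- c(problems,
                    "vortex masks are not axisymmetric: cartesian only")
    if (half_moon)
      problems <- c(problems,
                    "half-moon masks are not axisymmetric: cartesian only")
    if (!is.null(aberration)) {
      radial <- vapply(aberration$zernike_coeffs, function(p) {
        n <- ceiling((-3 + sqrt(9 + 8 * p[1])) / 2)
        (2 * p[1] - n * (n + 2)) == 0
      }, logical(1))
      if (length(radial) && !all(radial))
        problems <- c(problems,
          "non-radial Zernike terms are not axisymmetric: cartesian only")
      if (!is.null(aberration$custom_phase))
        problems <- c(problems, "custom phase masks: cartesian only")
    }
  }
  if (output_mode == "complex" && output_format == "tiff")
    problems <- c(problems,
                  "complex output requires format 'rds' (TIFF is real-valued)")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(
    list(setup = setup, grid = grid, model = model,
         parameterisation = parameterisation,
         gibson_lanni = gibson_lanni, aberration = aberration,
         vortex_charge = as.integer(vortex_charge), half_moon = half_moon,
         apodisation_on = apodisation_on,
         apodisation_exponent = apodisation_exponent,
         gaussian_s_env = gaussian_s_env,
         output_path = output_path, output_format = output_format,
         output_mode = output_mode, normalisation = normalisation),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] / [optical_setup()] / [sampling_grid()]
#' argument names one-to-one; `overrides` (e.g. parsed command-line flags)
#' take precedence over file values. Zernike terms are given as a list of
#' `[index, value]` pairs under `zernike`, an optional `zernike_unit` of
#' `"waves"` scales them by 2 pi.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!is.null(path) && !file.exists(path))
    stop("config file not found: ", path)
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  get_or <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  pol <- get_or("polarisation", "circular")
  jones <- if (is.character(pol)) {
    switch(pol, circular = jones_circular(),
           x = jones_linear(0), y = jones_linear(pi / 2),
           stop("unknown polarisation preset: ", pol))
  } else as.complex(unlist(pol))
  setup <- optical_setup(
    na = get_or("na", 0.5),
    wavelength = get_or("wavelength", 632),
    n_sample = get_or("n_sample", 1.0),
    n_immersion = get_or("n_immersion", get_or("n_sample", 1.0)),
    focal_length = get_or("focal_length", 3.0),
    polarisation = jones)
  grid <- sampling_grid(
    pupil_size = get_or("pupil_size", 513),
    out_size = get_or("out_size", 201),
    pixel_size = get_or("pixel_size", 20),
    z_planes = get_or("z_planes", 0))
  gl <- NULL
  if (!is.null(cfg$gibson_lanni)) {
    g <- cfg$gibson_lanni
    gl <- layered_medium(
      n_s = g$n_s, n_i = g$n_i, n_g = g$n_g,
      t_s = if (is.null(g$t_s)) 0 else g$t_s,
      t_i = g$t_i,
      t_g = if (is.null(g$t_g)) 0 else g$t_g,
      n_i_star = if (is.null(g$n_i_star)) g$n_i else g$n_i_star,
      n_g_star = if (is.null(g$n_g_star)) g$n_g else g$n_g_star,
      t_i_star = if (is.null(g$t_i_star)) 0 else g$t_i_star,
      t_g_star = if (is.null(g$t_g_star)) g$t_g else g$t_g_star)
  }
  ab <- NULL
  if (!is.null(cfg$zernike)) {
    ab <- aberration_spec(
      zernike_coeffs = lapply(cfg$zernike, unlist),
      unit = get_or("zernike_unit", "radians"))
  }
  run_config(
    setup = setup, grid = grid,
    model = get_or("model", "scalar"),
    parameterisation = get_or("parameterisation", "cartesian"),
    gibson_lanni = gl, aberration = ab,
    vortex_charge = get_or("vortex_charge", 0L),
    half_moon = isTRUE(cfg$half_moon),
    apodisation_on = isTRUE(cfg$apodisation_on),
    apodisation_exponent = get_or("apodisation_exponent", 1),
    gaussian_s_env = cfg$gaussian_s_env,
    output_path = cfg$output_path,
    output_format = get_or("output_format", "rds"),
    output_mode = get_or("output_mode", "complex"),
    normalisation = get_or("normalisation", "none"))
}

#' Run a full PSF computation from a configuration
#'
#' The deterministic pipeline behind the command-line front end: build the
#' pupil on the requested parameterisation, apply the enabled correction
#' factors, dispatch the chosen propagator plane-by-plane over z, normalise
#' and (optionally) save. There is no randomness anywhere: repeated runs of
#' the same configuration are bit-identical.
#'
#' @param config a [run_config()].
#' @param verbose print the resolved parameters and dispatched propagator.
#' @return The computed [focal_field()] (invisibly if saved).
#' @export
run_from_config <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  setup <- config$setup
  grid <- config$grid
  d <- derived_quantities(setup)
  par <- config$parameterisation
  pupil <- uniform_pupil(setup, grid, par)
  # correction factors, sampled on the pupil's own parameterisation
  sin_th <- if (par == "cartesian") {
    pc <- pupil_coords(setup, grid$pupil_size)
    ifelse(pc$inside, pc$sr, 0)
  } else sin(seq(0, d$theta_max, length.out = grid$pupil_size))
  amps <- list(); phases <- list()
  if (!is.null(config$gaussian_s_env))
    amps <- c(amps, list(gaussian_envelope(sin_th, config$gaussian_s_env)))
  if (config$apodisation_on)
    amps <- c(amps, list(apodisation(sin_th, config$apodisation_exponent)))
  if (!is.null(config$gibson_lanni))
    phases <- c(phases,
                list(gibson_lanni_phase(config$gibson_lanni, setup, sin_th)))
  if (!is.null(config$aberration))
    phases <- c(phases, list(zernike_phase(config$aberration, setup, grid)))
  if (config$vortex_charge != 0)
    phases <- c(phases, list(vortex_phase(setup, grid, config$vortex_charge)))
  if (config$half_moon)
    phases <- c(phases, list(half_moon_phase(setup, grid)))
  if (length(amps) || length(phases))
    pupil <- apply_corrections(pupil, amps, phases)
  if (config$model == "vectorial")
    pupil <- apply_polarisation(pupil, setup$polarisation)
  field <- if (config$model == "scalar" && par == "cartesian")
    scalar_cartesian(pupil, grid, config$normalisation)
  else if (config$model == "scalar")
    scalar_spherical(pupil, grid, "simpson", config$normalisation)
  else if (par == "cartesian")
    vectorial_cartesian(far_field_pupil(pupil), grid, config$normalisation)
  else
    vectorial_spherical(pupil, grid, "simpson",
                        normalisation = config$normalisation)
  if (verbose) {
    message(sprintf(
      "dispatched %s_%s: NA=%g lambda=%g nm n=%g/%g pupil=%d image=%d@%g nm %d z-plane(s)",
      config$model, par, setup$na, setup$wavelength, setup$n_sample,
      setup$n_immersion, grid$pupil_size, grid$out_size, grid$pixel_size,
      length(grid$z_planes)))
  }
  if (!is.null(config$output_path)) {
    save_stack(field, config$output_path, config$output_format,
               config$output_mode)
    if (verbose) message("saved ", config$output_path)
    return(invisible(field))
  }
  field
}
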