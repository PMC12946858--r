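#' Save a focal field stack
#'
#' Two on-disk forms are supported. `"rds"` is the archive format: the
#' whole `focal_field` object (complex data plus metadata) is serialised
#' with R's native serialization and round-trips bit-exactly. `"tiff"`
#' writes a multi-page 32-bit float TIFF, pages ordered z-major then
#' channel; since TIFF pages here carry values in `[0, 1]`, the stack is
#' divided by its peak before writing and the scale factor plus pixel size
#' are recorded in the page description tag. Complex data cannot go to
#' TIFF directly: pick `mode = "amplitude"` or `"intensity"`, or use the
#' archive format.
#'
#' @param field a [focal_field()].
#' @param path output file path.
#' @param format `"tiff"` or `"rds"`.
#' @param mode what to write: `"complex"` (rds only), `"amplitude"` or
#'   `"intensity"`.
#' @return The path, invisibly.
#' @export
save_stack <- function(field, path, format = c("tiff", "rds"),
                       mode = c("complex", "amplitude", "intensity")) {
  stopifnot(inherits(field, "focal_field"))
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (format == "rds") {
    obj <- field
    if (mode != "complex") {
      dat <- intensity(field, amplitude = (mode == "amplitude"))
      d <- dim(dat)
      obj$data <- array(as.complex(dat), dim = c(d[1], 1L, d[2], d[3]))
      obj$mode <- mode
    }
    saveRDS(obj, path, version = 3)
    return(invisible(path))
  }
  if (mode == "complex")
    stop("TIFF cannot hold complex fields; use mode = 'amplitude', ",
         "'intensity', or format = 'rds'")
  # amplitude keeps one page per channel (z-major, then channel);
  # intensity collapses channels to a single page per z
  if (mode == "intensity") {
    dat <- intensity(field)
    d <- dim(dat)
    dat <- array(dat, dim = c(d[1], 1L, d[2], d[3]))
  } else {
    dat <- Mod(field$data)
  }
  nz <- dim(dat)[1]; nch <- dim(dat)[2]
  peak <- max(dat)
  if (peak == 0) peak <- 1
  pages <- vector("list", nz * nch)
  for (iz in seq_len(nz)) for (ic in seq_len(nch)) {
    # page rows = y increasing upward, columns = x
    pg <- t(matrix(dat[iz, ic, , ], dim(dat)[3], dim(dat)[4]))[dim(dat)[4]:1, ]
    pages[[(iz - 1L) * nch + ic]] <- pg / peak
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  # TIFF pages carry only peak-normalised data; physical metadata goes to a
  # JSON sidecar next to the stack
  jsonlite::write_json(
    list(mode = mode, pixel_size_nm = field$pixel_size,
         z_planes_nm = field$z_planes, scale = peak,
         n_z = nz, n_channel = nch, propagator = field$propagator),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a focal field stack saved as an archive
#'
#' @param path path to an `"rds"` archive written by [save_stack()].
#' @return The stored [focal_field()].
#' @export
load_stack <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "focal_field"))
    stop("`path` does not hold a focal_field archive")
  obj
}
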