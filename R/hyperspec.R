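#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

## Central containers: a wavenumber axis shared by all spectra of a map,
## single spectra, rectangular hyperspectral maps, and single-spot time
## courses. Pixel coordinates are 0-based, row-major, y increasing downward;
## physical x/y in micrometres are index * pixel_size.

rr_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ramanredox_error")))
}

#' Validate and create a wavenumber axis
#'
#' A wavenumber axis is a strictly increasing numeric vector (cm^-1) of
#' length at least 2. Spacing may be non-uniform but must be positive
#' everywhere.
#'
#' @param values Numeric vector of wavenumbers in cm^-1.
#' @return A numeric vector of class `wn_axis`.
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    rr_error("wavenumber axis needs at least 2 points", "rr_axis_error")
  if (anyNA(values) || any(diff(values) <= 0))
    rr_error("wavenumber axis must be strictly increasing and free of NA",
             "rr_axis_error")
  structure(values, class = "wn_axis")
}

#' Create a single spectrum
#'
#' @param axis A [wn_axis()] (or numeric vector coerced to one).
#' @param intensities Numeric vector, same length as `axis`. Raw spectra are
#'   non-negative counts; baseline-corrected spectra may be negative.
#' @return An object of class `spectrum`: list with `axis` and `intensities`.
#' @export
spectrum <- function(axis, intensities) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis))
    rr_error("intensities length must equal axis length", "rr_shape_error")
  structure(list(axis = axis, intensities = intensities), class = "spectrum")
}

#' Create a hyperspectral map
#'
#' The map holds one spectrum per pixel of a `height x width` grid, all
#' sharing one wavenumber axis. Internally the data live in a
#' `height x width x n_wavenumbers` array (`cube`).
#'
#' @param axis A [wn_axis()].
#' @param cube Numeric array `height x width x length(axis)`.
#' @param pixel_size Micrometres per pixel (default 1).
#' @return Object of class `hyperspec_map` with fields `axis`, `cube`,
#'   `pixel_size`. Coordinates are 0-based, row-major, y downward.
#' @export
hyperspec_map <- function(axis, cube, pixel_size = 1) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  if (length(dim(cube)) != 3L || dim(cube)[3] != length(axis))
    rr_error("cube must be height x width x length(axis)", "rr_shape_error")
  if (dim(cube)[1] < 1L || dim(cube)[2] < 1L)
    rr_error("map must have height, width >= 1", "rr_shape_error")
  structure(list(axis = axis, cube = cube, pixel_size = pixel_size),
            class = "hyperspec_map")
}

#' @export
dim.hyperspec_map <- function(x) dim(x$cube)[1:2]

#' Extract one pixel spectrum from a map
#'
#' @param map A [hyperspec_map()].
#' @param row,col 1-based grid indices (row 1 is the top scan line).
#' @return A [spectrum()].
#' @export
pixel_spectrum <- function(map, row, col) {
  spectrum(map$axis, map$cube[row, col, ])
}

#' Flatten a map to a pixel-by-wavenumber matrix
#'
#' Rows are pixels in row-major order (y, then x); columns are wavenumbers.
#' @param map A [hyperspec_map()].
#' @return Numeric matrix `(height*width) x n_wavenumbers`.
#' @export
map_matrix <- function(map) {
  d <- dim(map$cube)
  ## aperm so that pixel order is row-major (fix row, run over columns)
  m <- matrix(aperm(map$cube, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  m
}

## inverse of map_matrix
matrix_to_cube <- function(m, height, width) {
  aperm(array(m, dim = c(width, height, ncol(m))), c(2, 1, 3))
}

#' Create a single-spot time course record
#'
#' @param times Minutes from the first acquisition; strictly increasing.
#'   Rebased so `times[1] == 0`.
#' @param spectra List of [spectrum()] objects sharing one axis.
#' @param condition `"treated"` or `"control"`.
#' @return Object of class `timecourse_record`.
#' @export
timecourse_record <- function(times, spectra, condition = c("treated", "control")) {
  condition <- match.arg(condition)
  times <- as.numeric(times)
  if (length(times) != length(spectra))
    rr_error("times and spectra lengths differ", "rr_shape_error")
  if (length(times) > 1 && any(diff(times) <= 0))
    rr_error("times must be strictly increasing", "rr_shape_error")
  ax <- spectra[[1]]$axis
  for (s in spectra)
    if (length(s$axis) != length(ax) || any(s$axis != ax))
      rr_error("all spectra in a time course must share one axis",
               "rr_axis_mismatch")
  times <- times - times[1]
  structure(list(times = times, spectra = spectra, condition = condition),
            class = "timecourse_record")
}

#' @export
print.hyperspec_map <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyperspec_map> %d x %d pixels, %d wavenumbers (%.0f..%.0f cm^-1), %.2g um/px\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis), x$pixel_size))
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f..%.0f cm^-1\n",
              length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}
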