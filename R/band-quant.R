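## Band/peak intensity extraction and ratio maps -- the semi-quantitative
## redox readout. Reduced b- and c-type cytochromes carry the 750 and
## 1125 cm^-1 bands; oxygenated myoglobin carries the 1640 cm^-1 nu10 band
## used as the internal normalization reference, so I750/I1640 and
## I1125/I1640 track the amount of reduced cytochromes and I750/I1125 the
## balance between the c- and b-type pools.

#' Define a Raman band
#'
#' @param name Band name (e.g. `"750"`).
#' @param center Band center, cm^-1.
#' @param half_width Half window width, cm^-1 (default 8): the quantifier
#'   window is `[center - half_width, center + half_width]`.
#' @param quantifier `"band-mean"` (average intensity over the window; the
#'   default, used for images and ratios alike) or `"peak-height"`
#'   (maximum in the window).
#' @param assignment Free-text note on contributing chromophores.
#' @return A list of class `band_def`.
#' @export
band_def <- function(name, center, half_width = 8,
                     quantifier = c("band-mean", "peak-height"),
                     assignment = "") {
  quantifier <- match.arg(quantifier)
  if (half_width <= 0) rr_error("half_width must be > 0", "rr_band_error")
  structure(list(name = as.character(name), center = center,
                 half_width = half_width, quantifier = quantifier,
                 assignment = assignment),
            class = "band_def")
}

#' The shipped band registry
#'
#' The four analysis bands (750, 1125, 1585, 1640 cm^-1), the further
#' assignment-table bands (1170, 1297, 1303, 1335, 1372 cm^-1) and the
#' myoglobin deoxygenation marker (1603 cm^-1).
#'
#' @return Named list of [band_def()]s.
#' @export
default_bands <- function() {
  mk <- function(name, center, assignment)
    band_def(name, center, assignment = assignment)
  list(
    `750`  = mk("750", 750,  "heme breathing; reduced cytochromes c, c1"),
    `1125` = mk("1125", 1125, "reduced cytochromes b"),
    `1170` = mk("1170", 1170, "asymmetric pyrrol half-ring"),
    `1297` = mk("1297", 1297, "all heme bonds; oMb"),
    `1303` = mk("1303", 1303, "all heme bonds; cytochromes"),
    `1335` = mk("1335", 1335, "all heme bonds; cytochromes"),
    `1372` = mk("1372", 1372, "symmetric pyrrol half-ring; oMb"),
    `1585` = mk("1585", 1585, "reduced cytochromes + oMb"),
    `1603` = mk("1603", 1603, "nu10 of deoxygenated Mb"),
    `1640` = mk("1640", 1640, "nu10 of oMb (internal reference)"))
}

band_window_idx <- function(axis, band) {
  lo <- band$center - band$half_width
  hi <- band$center + band$half_width
  if (lo < min(axis) || hi > max(axis))
    rr_error(sprintf("band %s window [%.0f, %.0f] outside axis [%.0f, %.0f]",
                     band$name, lo, hi, min(axis), max(axis)), "rr_band_error")
  which(axis >= lo & axis <= hi)
}

#' Quantify one band on one spectrum
#'
#' @param spec Baseline-corrected [spectrum()].
#' @param band A [band_def()].
#' @return Scalar intensity: window mean (`"band-mean"`) or window maximum
#'   (`"peak-height"`).
#' @export
band_intensity <- function(spec, band) {
  idx <- band_window_idx(spec$axis, band)
  v <- spec$intensities[idx]
  if (band$quantifier == "band-mean") mean(v) else max(v)
}

#' Per-pixel band intensity image
#'
#' @param map Baseline-corrected [hyperspec_map()].
#' @param band A [band_def()].
#' @param mask A [mask_cells()] result or logical matrix; pixels outside
#'   the mask are `NA`.
#' @return List of class `band_map`: `band`, `values` (height x width,
#'   `NA` outside mask), `mask`.
#' @export
band_map <- function(map, band, mask = NULL) {
  idx <- band_window_idx(map$axis, band)
  sub <- map$cube[, , idx, drop = FALSE]
  vals <- if (band$quantifier == "band-mean") {
    apply(sub, c(1, 2), mean)
  } else {
    apply(sub, c(1, 2), max)
  }
  m <- mask_matrix(mask, dim(map$cube)[1:2])
  vals[!m] <- NA_real_
  structure(list(band = band, values = vals, mask = m), class = "band_map")
}

mask_matrix <- function(mask, dims) {
  if (is.null(mask)) return(matrix(TRUE, dims[1], dims[2]))
  m <- if (inherits(mask, "pixel_mask")) mask$mask else mask
  if (!all(dim(m) == dims))
    rr_error("mask shape does not match map", "rr_shape_error")
  m
}

#' Per-pixel band ratio image
#'
#' Quotient of two band intensities at every masked pixel. Pixels where the
#' denominator is <= 0 (or outside the mask) are flagged invalid (`NA`) and
#' excluded from all downstream summaries.
#'
#' @param map Baseline-corrected [hyperspec_map()].
#' @param num,den Numerator and denominator [band_def()]s.
#' @param mask Optional [mask_cells()] result or logical matrix.
#' @return List of class `ratio_map`: `num`, `den`, `values`
#'   (height x width, `NA` where invalid), `valid` (logical matrix).
#' @export
ratio_map <- function(map, num, den, mask = NULL) {
  if (identical(num$center, den$center))
    warning("numerator and denominator bands are identical; ratio is 1")
  bn <- band_map(map, num, mask)
  bd <- band_map(map, den, mask)
  valid <- !is.na(bd$values) & bd$values > 0 & !is.na(bn$values)
  vals <- bn$values / bd$values
  vals[!valid] <- NA_real_
  structure(list(num = num, den = den, values = vals, valid = valid),
            class = "ratio_map")
}

#' Normalize a time course of band intensities
#'
#' Band intensities are computed per time point on baseline-corrected
#' spectra (same procedure as for maps), then normalized either to the
#' value at time zero (`"to_t0"`: each band series divided by its own t=0
#' value, so every series starts at 1) or point-wise to the 1640 cm^-1 oMb
#' reference series (`"to_1640"`: removes any per-time common-mode factor
#' exactly).
#'
#' @param record A [timecourse_record()] of raw spectra.
#' @param bands List of [band_def()]s (default: the 750, 1125 and
#'   1640 cm^-1 analysis bands).
#' @param mode `"to_t0"` or `"to_1640"`.
#' @param baseline A [baseline_config()] applied per spectrum; `NULL`
#'   skips baseline subtraction (for already-corrected records).
#' @return List of class `normalized_timecourse`: `times`, `mode`,
#'   `values` (time x band matrix), `raw` (unnormalized intensities).
#' @export
normalize_timecourse <- function(record, bands = default_bands()[c("750", "1125", "1640")],
                                 mode = c("to_t0", "to_1640"),
                                 baseline = baseline_config()) {
  mode <- match.arg(mode)
  specs <- record$spectra
  if (!is.null(baseline))
    specs <- lapply(specs, function(s) subtract_baseline(s, baseline)$corrected)
  raw <- vapply(specs, function(s)
    vapply(bands, function(b) band_intensity(s, b), 0.0),
    numeric(length(bands)))
  raw <- t(matrix(raw, nrow = length(bands)))  # time x band
  colnames(raw) <- vapply(bands, `[[`, "", "name")
  vals <- raw
  if (mode == "to_t0") {
    t0 <- raw[1, ]
    if (any(t0 == 0))
      rr_error(sprintf("zero intensity at time %g for band %s",
                       record$times[1], colnames(raw)[which(t0 == 0)[1]]),
               "rr_norm_error")
    vals <- sweep(raw, 2, t0, "/")
  } else {
    ref_band <- default_bands()[["1640"]]
    ref <- vapply(specs, function(s) band_intensity(s, ref_band), 0.0)
    if (any(ref == 0))
      rr_error(sprintf("zero 1640 cm^-1 intensity at time %g",
                       record$times[which(ref == 0)[1]]), "rr_norm_error")
    vals <- sweep(raw, 1, ref, "/")
  }
  structure(list(times = record$times, mode = mode, values = vals, raw = raw),
            class = "normalized_timecourse")
}
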