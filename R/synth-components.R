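## Heme component spectra for the synthetic generator.
##
## Each component is a list of Lorentzian lines (center, half-width at half
## maximum, relative amplitude) plus an overall cross-section scale. Line
## positions follow the band-assignment table for cardiomyocyte spectra;
## within-component relative amplitudes are free phenomenological
## parameters fixed once here (only ratios *between* bands matter
## downstream, and those are set by calibration). Constraints honoured by
## construction:
##   - reduced : oxidized cytochrome c integrated intensity = redox_contrast
##     (default 10);
##   - oMb carries the 1640 cm^-1 nu10 line and no 750/1125 lines;
##   - dMb lacks 1640 but carries the deoxygenation marker at 1603 cm^-1,
##     and (like metMb) only minor 750/1125 components.

lorentzian <- function(axis, center, hwhm, amplitude) {
  amplitude * hwhm^2 / ((as.numeric(axis) - center)^2 + hwhm^2)
}

line_list <- function(centers, amplitudes, hwhm) {
  data.frame(center = centers, hwhm = hwhm, amplitude = amplitudes)
}

#' The shipped heme component library
#'
#' Six components: reduced/oxidized cytochrome c (the reduced c-type pool,
#' 750 cm^-1 dominant), reduced cytochrome b (1125 cm^-1 dominant), and
#' oxygenated, deoxygenated and met myoglobin.
#'
#' @param redox_contrast Ratio of integrated intensity of the reduced to
#'   the oxidized cytochrome c component (default 10).
#' @param hwhm Lorentzian half-width at half maximum, cm^-1 (default 6).
#' @return Named list of components, each a list with `name`, `lines`
#'   (data.frame `center`, `hwhm`, `amplitude`) and `scale`.
#' @export
component_library <- function(redox_contrast = 10, hwhm = 6) {
  comp <- function(name, centers, amplitudes, scale = 1)
    list(name = name, lines = line_list(centers, amplitudes, hwhm),
         scale = scale)
  red <- comp("cyt_c_reduced",
              c(750, 1125, 1170, 1305, 1335, 1585),
              c(1.00, 0.60, 0.15, 0.25, 0.20, 0.50))
  ## oxidized: same heme skeleton, weak scattering, nu10 present at 1640
  ox_amp <- c(0.06, 0.04, 0.08, 0.05, 0.07)
  ox_cen <- c(750, 1125, 1374, 1585, 1640)
  ## scale so integrated intensities (pi * sum(A * hwhm)) are in exact ratio
  s_ox <- sum(red$lines$amplitude * red$lines$hwhm) /
    (redox_contrast * sum(ox_amp * hwhm))
  list(
    cyt_c_reduced = red,
    cyt_c_oxidized = comp("cyt_c_oxidized", ox_cen, ox_amp, scale = s_ox),
    cyt_b_reduced = comp("cyt_b_reduced",
                         c(750, 1125, 1170, 1301, 1335, 1585),
                         c(0.35, 1.00, 0.12, 0.20, 0.20, 0.45)),
    oMb  = comp("oMb",  c(1297, 1372, 1585, 1640), c(0.25, 0.30, 0.80, 1.00)),
    dMb  = comp("dMb",  c(750, 1125, 1305, 1585, 1603),
                c(0.05, 0.04, 0.10, 0.40, 0.90)),
    metMb = comp("metMb", c(750, 1125, 1372, 1585, 1608),
                 c(0.05, 0.04, 0.50, 0.35, 0.30)))
}

#' Render one component spectrum on an axis
#'
#' Sum of the component's Lorentzian lines times its cross-section scale.
#' Errors if the axis does not cover every line center.
#'
#' @param component One element of [component_library()].
#' @param axis A [wn_axis()].
#' @return A [spectrum()].
#' @export
render_component <- function(component, axis) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  out_of_range <- component$lines$center < min(axis) |
    component$lines$center > max(axis)
  if (any(out_of_range))
    rr_error(sprintf("axis does not cover %s line at %.0f cm^-1",
                     component$name,
                     component$lines$center[which(out_of_range)[1]]),
             "rr_axis_error")
  y <- rep(0, length(axis))
  for (i in seq_len(nrow(component$lines)))
    y <- y + lorentzian(axis, component$lines$center[i],
                        component$lines$hwhm[i], component$lines$amplitude[i])
  spectrum(axis, y * component$scale)
}

#' Default smooth fluorescence-like baseline
#'
#' `b(nu) = b0 * exp(-(nu - min(axis)) / tau) + b1` -- a decaying
#' autofluorescence pedestal of roughly 30% of the strongest Raman peak at
#' the default counts scale.
#'
#' @param b0 Amplitude in counts (default 3000).
#' @param tau Decay constant in cm^-1 (default 700).
#' @param b1 Constant offset in counts (default 500).
#' @return List of class `baseline_params`.
#' @export
baseline_params <- function(b0 = 3000, tau = 700, b1 = 500) {
  structure(list(b0 = b0, tau = tau, b1 = b1), class = "baseline_params")
}

eval_baseline <- function(params, axis, scale = 1) {
  if (is.null(params)) return(rep(0, length(axis)))
  nu <- as.numeric(axis)
  scale * (params$b0 * exp(-(nu - nu[1]) / params$tau) + params$b1)
}

#' Render a noisy linear mixture of components
#'
#' `sum_i c_i * component_i + baseline + noise`, with additive Gaussian
#' noise whose standard deviation follows a shot-noise proxy,
#' `noise_scale * sqrt(signal + dark_floor)`. Noiseless when
#' `noise_scale = 0`.
#'
#' @param concentrations Named non-negative vector; names must exist in
#'   `library`.
#' @param axis A [wn_axis()].
#' @param library A [component_library()].
#' @param baseline A [baseline_params()] or `NULL` for none.
#' @param noise_scale Noise multiplier (0 = noiseless).
#' @param dark_floor Dark-signal variance floor, counts (default 100).
#' @param seed Seed used when noise is drawn; `NULL` leaves the RNG state
#'   alone (for callers managing their own stream).
#' @return A [spectrum()].
#' @export
render_mixture <- function(concentrations, axis, library = component_library(),
                           baseline = NULL, noise_scale = 0, dark_floor = 100,
                           seed = NULL) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  if (any(concentrations < 0))
    rr_error("concentrations must be non-negative", "rr_synth_error")
  unknown <- setdiff(names(concentrations), names(library))
  if (length(unknown))
    rr_error(sprintf("unknown component '%s'", unknown[1]), "rr_synth_error")
  y <- rep(0, length(axis))
  for (nm in names(concentrations)) {
    if (concentrations[[nm]] == 0) next
    y <- y + concentrations[[nm]] * render_component(library[[nm]], axis)$intensities
  }
  y <- y + eval_baseline(baseline, axis)
  if (noise_scale > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0,
                          noise_scale * sqrt(pmax(y, 0) + dark_floor))
  }
  spectrum(axis, y)
}

#' Default resting-cardiomyocyte mixture and its dithionite-reduced state
#'
#' The resting mixture holds a unit c-type and unit b-type cytochrome pool
#' of which `reduced_fraction` is reduced (the rest pooled under the weak
#' oxidized spectrum), plus oxymyoglobin at `mb_factor` times the total
#' cytochrome concentration. The sodium-dithionite (SDT) counterpart has
#' every cytochrome reduced and myoglobin deoxygenated.
#'
#' @param reduced_fraction Fraction of each cytochrome pool reduced at rest
#'   (default 0.2).
#' @param mb_factor Myoglobin-to-total-cytochrome concentration factor
#'   (default 7, the literature lower bound).
#' @return List with `resting` and `sdt` named concentration vectors.
#' @export
resting_mixture <- function(reduced_fraction = 0.2, mb_factor = 7) {
  f <- reduced_fraction
  cyt_total <- 2  # one c-type + one b-type pool
  list(
    resting = c(cyt_c_reduced = f, cyt_b_reduced = f,
                cyt_c_oxidized = (1 - f) * cyt_total,
                oMb = mb_factor * cyt_total),
    sdt = c(cyt_c_reduced = 1, cyt_b_reduced = 1,
            dMb = mb_factor * cyt_total))
}

#' The default 600-1800 cm^-1 axis at 1 cm^-1 spacing
#' @return A [wn_axis()].
#' @export
default_axis <- function() wn_axis(seq(600, 1800, by = 1))
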