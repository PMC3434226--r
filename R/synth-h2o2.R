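## Hydrogen-peroxide time-course simulation: single-spot spectra of a
## resting rod-shaped cell whose cytochrome bands stay flat for a lag
## period and then decline exponentially, the oMb band declining at half
## the total amount; controls stay flat (optional drift).

#' Describe an H2O2 time-course simulation
#'
#' Defaults emulate the published narrative: 0-20 min sampled every
#' 2.5 min, a 10 min lag, then exponential decline of the reduced
#' cytochrome pool reaching ~60% total loss at 20 min, with the oMb
#' (1640 cm^-1) amplitude losing half as much (~30%).
#'
#' @param times Sampling times, minutes (default `seq(0, 20, 2.5)`).
#' @param lag Lag before decline, minutes (default 10).
#' @param k_cyt Post-lag decline rate of the reduced cytochrome pool,
#'   1/min (default `log(2.5)/10`, i.e. 60% loss over the last 10 min).
#' @param k_omb Post-lag decline rate of the oMb amplitude (default
#'   `log(10/7)/10`, 30% loss over the last 10 min).
#' @param control_drift Fractional decline per minute of the control
#'   (default 0).
#' @param n_replicates Cells per condition (default 10).
#' @param reduced_fraction,mb_factor Resting mixture, see
#'   [resting_mixture()].
#' @param counts_scale,noise_scale,dark_floor,baseline,axis As in
#'   [phantom_spec()].
#' @return List of class `h2o2_spec`.
#' @export
h2o2_spec <- function(times = seq(0, 20, by = 2.5), lag = 10,
                      k_cyt = log(2.5) / 10, k_omb = log(10 / 7) / 10,
                      control_drift = 0, n_replicates = 10,
                      reduced_fraction = 0.2, mb_factor = 7,
                      counts_scale = 10000, noise_scale = 1,
                      dark_floor = 100, baseline = baseline_params(),
                      axis = default_axis()) {
  if (lag < 0 || k_cyt < 0 || k_omb < 0)
    rr_error("lag and decline rates must be >= 0", "rr_synth_error")
  structure(list(times = times, lag = lag, k_cyt = k_cyt, k_omb = k_omb,
                 control_drift = control_drift, n_replicates = n_replicates,
                 reduced_fraction = reduced_fraction, mb_factor = mb_factor,
                 counts_scale = counts_scale, noise_scale = noise_scale,
                 dark_floor = dark_floor, baseline = baseline, axis = axis),
            class = "h2o2_spec")
}

decline_factor <- function(t, lag, k) ifelse(t <= lag, 1, exp(-k * (t - lag)))

#' Simulate treated and control H2O2 time courses
#'
#' @param spec An [h2o2_spec()].
#' @param seed Integer seed; output is deterministic in `(spec, seed)`.
#' @return List with `treated` and `control` (each a list of
#'   `n_replicates` [timecourse_record()]s of raw, baseline-bearing
#'   spectra) and `truth` (lag, rates, expected amplitude factors per
#'   time).
#' @export
simulate_h2o2_course <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "h2o2_spec"))
  lib <- component_library()
  mix <- resting_mixture(spec$reduced_fraction, spec$mb_factor)$resting
  axis <- spec$axis
  comp_sig <- lapply(names(mix)[mix > 0], function(nm)
    mix[[nm]] * render_component(lib[[nm]], axis)$intensities *
      spec$counts_scale)
  names(comp_sig) <- names(mix)[mix > 0]
  cyt_sig <- comp_sig$cyt_c_reduced + comp_sig$cyt_b_reduced
  ox_sig <- comp_sig$cyt_c_oxidized
  omb_sig <- comp_sig$oMb
  bl <- eval_baseline(spec$baseline, axis)
  set.seed(seed)
  one_record <- function(condition) {
    specs <- lapply(spec$times, function(t) {
      if (condition == "treated") {
        dc <- decline_factor(t, spec$lag, spec$k_cyt)
        dm <- decline_factor(t, spec$lag, spec$k_omb)
      } else {
        dc <- dm <- max(0, 1 - spec$control_drift * t)
      }
      ## oxidative damage hits the whole cytochrome heme pool (reduced and
      ## oxidized alike), myoglobin declines at its own slower rate
      y <- dc * (cyt_sig + ox_sig) + dm * omb_sig + bl
      if (spec$noise_scale > 0)
        y <- y + stats::rnorm(length(y), 0, spec$noise_scale *
                                sqrt(pmax(y, 0) + spec$dark_floor))
      spectrum(axis, y)
    })
    timecourse_record(spec$times, specs, condition)
  }
  treated <- replicate(spec$n_replicates, one_record("treated"),
                       simplify = FALSE)
  control <- replicate(spec$n_replicates, one_record("control"),
                       simplify = FALSE)
  tt <- spec$times
  list(treated = treated, control = control,
       truth = list(lag = spec$lag, k_cyt = spec$k_cyt, k_omb = spec$k_omb,
                    times = tt,
                    cyt_factor = decline_factor(tt, spec$lag, spec$k_cyt),
                    omb_factor = decline_factor(tt, spec$lag, spec$k_omb)))
}
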