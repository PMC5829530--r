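#' Simulation configuration for synthetic grip-lift trials
#'
#' Bundles the physical and behavioural parameters of the synthetic trial
#' generator. Defaults reproduce the apparatus and task conditions of the
#' centrifuge grip-lift protocol: a 0.13 kg instrumented object sampled at
#' 120 Hz, force-channel noise inside the stated +/-0.1 N sensor accuracy,
#' per-trial Gz jitter matching the observed phase-level standard
#' deviations (~0.07 g), a load-force peak overshooting its plateau by 12%,
#' and a grip-force safety margin that is larger on the first trial after a
#' gravity transition.
#'
#' @param mass object mass, kg.
#' @param fs sampling frequency, Hz.
#' @param g0 standard gravity, m/s^2.
#' @param noise_sd additive white Gaussian noise SD on each force channel, N.
#' @param az_noise_sd noise SD on the accelerometer channel, m/s^2
#'   (stated sensor accuracy +/-0.2 m/s^2).
#' @param g_jitter_sd per-trial SD of the realized gravity level around the
#'   programmed one, in multiples of g.
#' @param grip_gain target grip/load force ratio (dimensionless gain).
#' @param base_margin constant grip-force safety margin present in every
#'   trial, N.
#' @param first_trial_margin additional safety margin applied to the
#'   grip-force peak on trial 1 after a transition, N. Default 1.44 N, the
#'   1 g uncertainty margin of the prediction model.
#' @param overshoot_frac fractional overshoot of the load-force peak above
#'   its plateau (>= 0).
#' @param peak_margin transient grip-force overshoot at the peak beyond
#'   proportional load tracking, N; it relaxes away with `decay_tau` and,
#'   being additive, cancels in switching indices. Default 0.7 N, sized so
#'   that the first-trial peak regression intercept (`peak_margin +
#'   first_trial_margin`) is ~2.1 N, the magnitude reported for this task.
#' @param decay_tau time constant of the post-peak exponential grip-force
#'   relaxation, s.
#' @param preload_ms preload-phase duration (grip onset to load onset) for
#'   trials 2-4, ms.
#' @param preload_ms_trial1 preload-phase duration on trial 1, ms (longer,
#'   reflecting the extra haptic encoding time observed on first trials).
#' @param loading_ms duration of the load-force rise from onset to peak, ms.
#' @param settle_s duration of the post-peak load-force settling to its
#'   plateau, s.
#' @param hold_s stationary hold duration, s (the task holds ~2 s).
#' @param release_rate mean magnitude of the load-force release ramp, N/s;
#'   must exceed 2 N/s so that the trial-end rule (rate below -2 N/s
#'   sustained 125 ms) can fire.
#' @param lag_samples imposed grip-load lag as an integer number of samples;
#'   positive values shift the grip-force profile earlier (grip leads).
#' @param baseline_s quiet baseline before grip-force onset, s.
#' @param tail_s recording tail after the object is set down, s.
#'
#' @return An object of class `grip_sim_config` (validated named list).
#' @examples
#' cfg <- sim_config(noise_sd = 0)
#' @export
sim_config <- function(mass = 0.13,
                       fs = 120,
                       g0 = 9.81,
                       noise_sd = 0.05,
                       az_noise_sd = 0.1,
                       g_jitter_sd = 0.07,
                       grip_gain = 1.5,
                       base_margin = 0,
                       first_trial_margin = 1.44,
                       overshoot_frac = 0.12,
                       peak_margin = 0.7,
                       decay_tau = 0.55,
                       preload_ms = 47,
                       preload_ms_trial1 = 71,
                       loading_ms = 300,
                       settle_s = 0.25,
                       hold_s = 2,
                       release_rate = 6,
                       lag_samples = 0L,
                       baseline_s = 0.5,
                       tail_s = 0.4) {
  cfg <- list(
    mass = mass, fs = fs, g0 = g0, noise_sd = noise_sd,
    az_noise_sd = az_noise_sd, g_jitter_sd = g_jitter_sd,
    grip_gain = grip_gain, base_margin = base_margin,
    first_trial_margin = first_trial_margin,
    overshoot_frac = overshoot_frac, peak_margin = peak_margin,
    decay_tau = decay_tau,
    preload_ms = preload_ms, preload_ms_trial1 = preload_ms_trial1,
    loading_ms = loading_ms, settle_s = settle_s, hold_s = hold_s,
    release_rate = release_rate, lag_samples = lag_samples,
    baseline_s = baseline_s, tail_s = tail_s
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num1 <- function(field, lo = -Inf, strict_lo = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      gl_config_error(field, "must be a finite numeric scalar")
    if (strict_lo && v <= lo)
      gl_config_error(field, sprintf("must be > %s", lo))
    if (!strict_lo && v < lo)
      gl_config_error(field, sprintf("must be >= %s", lo))
    v
  }
  num1("mass", 0, TRUE)
  num1("fs", 0, TRUE)
  num1("g0", 0, TRUE)
  num1("noise_sd", 0)
  num1("az_noise_sd", 0)
  num1("g_jitter_sd", 0)
  num1("grip_gain", 0, TRUE)
  num1("base_margin", 0)
  num1("first_trial_margin", 0)
  num1("overshoot_frac", 0)
  num1("peak_margin", 0)
  num1("decay_tau", 0, TRUE)
  num1("preload_ms", 0, TRUE)
  num1("preload_ms_trial1", 0, TRUE)
  num1("loading_ms", 0, TRUE)
  num1("settle_s", 0)
  num1("hold_s", 0.1, TRUE)
  num1("release_rate", 2, TRUE)
  num1("baseline_s", 0.1, TRUE)
  num1("tail_s", 0)
  lg <- cfg$lag_samples
  if (!is.numeric(lg) || length(lg) != 1 || !is.finite(lg) ||
      lg != round(lg) || abs(lg) > 12)
    gl_config_error("lag_samples", "must be an integer with |lag| <= 12 samples")
  cfg$lag_samples <- as.integer(lg)
  structure(cfg, class = "grip_sim_config")
}

#' @export
print.grip_sim_config <- function(x, ...) {
  cat("<grip_sim_config> mass", x$mass, "kg, fs", x$fs, "Hz, gain",
      x$grip_gain, ", margins", x$base_margin, "+",
      x$first_trial_margin, "N (trial 1), tau", x$decay_tau, "s, noise",
      x$noise_sd, "N\n")
  invisible(x)
}
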