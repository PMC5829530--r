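# Landmark detection: force onsets, trial end, peaks, weight crossing,
# plateau means and phase durations.

#' Detect a force onset from its rate signal
#'
#' The onset is the first sample from which the rate stays strictly above
#' `threshold` for at least `ceiling(min_duration * fs)` contiguous samples
#' (0.4 N/s sustained for 125 ms by default). Brief suprathreshold bursts
#' shorter than the minimum run are rejected.
#'
#' @param rate force-rate signal, N/s (uniform grid starting at t = 0).
#' @param fs sampling frequency, Hz.
#' @param threshold onset threshold, N/s (strict >).
#' @param min_duration minimum suprathreshold duration, s.
#' @param search_start earliest time considered, s.
#' @return Onset time in seconds from record start.
#' @examples
#' r <- c(rep(0, 60), rep(1, 60))
#' detect_onset(r, fs = 120)  # 0.5 s
#' @export
detect_onset <- function(rate, fs = 120, threshold = 0.4,
                         min_duration = 0.125, search_start = 0) {
  n <- length(rate)
  i0 <- floor(search_start * fs) + 1
  if (i0 > n)
    gl_stop("search_start lies beyond the record", "griplift_error_domain")
  nmin <- ceiling(min_duration * fs)
  above <- rate[i0:n] > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= nmin)
  if (!length(ok))
    gl_stop(sprintf(
      "no onset: rate never exceeded %g N/s for %g ms", threshold,
      1000 * min_duration), "griplift_error_onset_not_found")
  idx <- i0 - 1 + starts[ok[1]]
  (idx - 1) / fs
}

#' Detect the analysis end of a trial from the load-force rate
#'
#' Finds the first time the load-force rate stays strictly below
#' `threshold` (-2 N/s) for at least `min_duration` (125 ms) and subtracts
#' `backoff` (250 ms) to define the end of the trial, i.e. the end of the
#' stationary hold before the release movement.
#'
#' @param lf_rate load-force rate, N/s.
#' @param fs sampling frequency, Hz.
#' @param threshold release threshold, N/s (strict <).
#' @param min_duration minimum sub-threshold duration, s.
#' @param backoff time subtracted from the detected release start, s.
#' @param after if supplied, the computed end must not precede this time
#'   (typically the lift-off time); violation raises an inconsistent-trial
#'   error.
#' @return Trial end time in seconds from record start.
#' @export
detect_trial_end <- function(lf_rate, fs = 120, threshold = -2,
                             min_duration = 0.125, backoff = 0.250,
                             after = NULL) {
  nmin <- ceiling(min_duration * fs)
  below <- lf_rate < threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= nmin)
  if (!length(ok))
    gl_stop(sprintf(
      "no trial end: rate never fell below %g N/s for %g ms", threshold,
      1000 * min_duration), "griplift_error_end_not_found")
  t_end <- (starts[ok[1]] - 1) / fs - backoff
  if (!is.null(after) && t_end < after)
    gl_stop(sprintf(
      "inconsistent trial: computed end %.3f s precedes lift-off %.3f s",
      t_end, after), "griplift_error_inconsistent_trial")
  t_end
}

#' Locate grip- and load-force peaks
#'
#' Global maxima within the analysis window(s); ties are broken by the
#' earliest time. The grip-force window usually spans grip onset to trial
#' end and the load-force window load onset to trial end.
#'
#' @param gf grip force, N.
#' @param lf load force, N (merged channel).
#' @param t time grid, s.
#' @param gf_window numeric length-2, `[start, end]` window for the grip
#'   force peak, s.
#' @param lf_window window for the load-force peak; defaults to `gf_window`.
#' @return List with `tGFmax`, `GFmax`, `tLFmax`, `LFmax`.
#' @export
detect_peaks <- function(gf, lf, t, gf_window, lf_window = gf_window) {
  pk <- function(x, w, lab) {
    idx <- which(t >= w[1] & t <= w[2])
    if (!length(idx))
      gl_stop(paste("empty", lab, "peak window"), "griplift_error_domain")
    j <- idx[which.max(x[idx])]
    list(t = t[j], v = x[j])
  }
  g <- pk(gf, gf_window, "grip-force")
  l <- pk(lf, lf_window, "load-force")
  list(tGFmax = g$t, GFmax = g$v, tLFmax = l$t, LFmax = l$v)
}

#' Time at which load force reaches the object's weight
#'
#' First time at or after `after` where the load force meets or exceeds
#' `weight`, linearly interpolated between the bracketing samples. This is
#' the lift-off landmark ending the loading phase.
#'
#' @param lf load force, N.
#' @param t time grid, s.
#' @param weight object weight, N (> 0).
#' @param after earliest time considered, s (typically the load onset).
#' @return Crossing time, s.
#' @examples
#' t <- (0:120) / 120
#' weight_crossing_time(2 * t, t, weight = 1, after = 0)  # 0.5 s
#' @export
weight_crossing_time <- function(lf, t, weight, after = 0) {
  if (!is.numeric(weight) || weight <= 0)
    gl_stop("weight must be > 0", "griplift_error_domain")
  cand <- which(t >= after & lf >= weight)
  if (!length(cand))
    gl_stop(sprintf("lift failure: load force never reached %.3f N", weight),
            "griplift_error_lift_failure")
  i <- cand[1]
  if (i == 1 || lf[i - 1] >= weight || t[i - 1] < after) return(t[i])
  t[i - 1] + (weight - lf[i - 1]) / (lf[i] - lf[i - 1]) * (t[i] - t[i - 1])
}

#' Plateau forces over the final hold second
#'
#' Arithmetic means of grip and load force over `[tEnd - window_s, tEnd]`,
#' the stationary holding period preceding the release.
#'
#' @param gf grip force, N.
#' @param lf load force, N.
#' @param t time grid, s.
#' @param tEnd trial end time, s.
#' @param window_s averaging window length, s.
#' @param tLFw optional lift-off time; if the window starts before it, an
#'   inconsistent-trial error is raised.
#' @return List with `gf_plateau` and `lf_plateau`, N.
#' @export
plateau_means <- function(gf, lf, t, tEnd, window_s = 1.0, tLFw = NULL) {
  w0 <- tEnd - window_s
  if (!is.null(tLFw) && w0 < tLFw)
    gl_stop(sprintf(
      "inconsistent trial: plateau window start %.3f s precedes lift-off %.3f s",
      w0, tLFw), "griplift_error_inconsistent_trial")
  idx <- which(t >= w0 & t <= tEnd)
  if (!length(idx))
    gl_stop("empty plateau window", "griplift_error_domain")
  list(gf_plateau = mean(gf[idx]), lf_plateau = mean(lf[idx]))
}

#' Construct and validate a set of trial landmark times
#'
#' @param tGFo grip-force onset, s.
#' @param tLFo load-force onset, s.
#' @param tLFw weight-crossing (lift-off), s.
#' @param tGFmax grip-force peak time, s.
#' @param tLFmax load-force peak time, s.
#' @param tEnd analysis end, s.
#' @return Object of class `trial_events`.
#' @export
trial_events <- function(tGFo, tLFo, tLFw, tGFmax, tLFmax, tEnd) {
  ev <- list(tGFo = tGFo, tLFo = tLFo, tLFw = tLFw,
             tGFmax = tGFmax, tLFmax = tLFmax, tEnd = tEnd)
  if (any(!vapply(ev, function(x) is.numeric(x) && is.finite(x), TRUE)))
    gl_stop("event times must be finite numbers", "griplift_error_domain")
  if (!(tGFo <= tLFo && tLFo < tLFw && tLFw <= tEnd))
    gl_stop(sprintf(
      "inconsistent event ordering: tGFo=%.3f tLFo=%.3f tLFw=%.3f tEnd=%.3f",
      tGFo, tLFo, tLFw, tEnd), "griplift_error_inconsistent_trial")
  structure(ev, class = "trial_events")
}

#' Preload and loading phase durations
#'
#' Preload is the delay between grip-force and load-force onsets
#' (`tLFo - tGFo`); loading the delay between load-force onset and the
#' moment load force equals the object's weight (`tLFw - tLFo`).
#'
#' @param events a [trial_events()] object (or compatible list).
#' @return List with `preload` and `loading`, s.
#' @examples
#' phase_durations(trial_events(1.00, 1.07, 1.30, 1.35, 1.33, 4))
#' @export
phase_durations <- function(events) {
  if (!all(c("tGFo", "tLFo", "tLFw") %in% names(events)))
    gl_stop("events must carry tGFo, tLFo, tLFw", "griplift_error_domain")
  preload <- events$tLFo - events$tGFo
  loading <- events$tLFw - events$tLFo
  if (preload < 0 || loading <= 0)
    gl_stop("inconsistent event ordering for phase durations",
            "griplift_error_inconsistent_trial")
  list(preload = preload, loading = loading)
}

#' @export
print.trial_events <- function(x, ...) {
  cat(sprintf(
    "<trial_events> tGFo=%.3f tLFo=%.3f tLFw=%.3f tGFmax=%.3f tLFmax=%.3f tEnd=%.3f s\n",
    x$tGFo, x$tLFo, x$tLFw, x$tGFmax, x$tLFmax, x$tEnd))
  invisible(x)
}
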