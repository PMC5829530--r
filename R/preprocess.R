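# Signal conditioning: zero-phase low-pass filtering, finite-difference
# force rates, and reconstruction of load force after lift-off from the
# accelerometer channel.

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (effective fourth order, zero phase shift), -3 dB at `cutoff`. The input
#' is extended by odd reflection at both ends before filtering so that the
#' recursive filter's edge transients fall outside the returned segment.
#'
#' @param x numeric signal; all values must be finite.
#' @param fs sampling frequency, Hz.
#' @param cutoff low-pass cutoff, Hz; must be below the Nyquist frequency.
#' @return Filtered signal, same length as `x`.
#' @examples
#' lowpass_filter(sin(2 * pi * 5 * (0:119) / 120), fs = 120)
#' @export
lowpass_filter <- function(x, fs = 120, cutoff = 20) {
  if (any(!is.finite(x)))
    gl_stop("signal contains non-finite samples", "griplift_error_nonfinite")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    gl_stop("cutoff must lie in (0, fs/2)", "griplift_error_domain")
  n <- length(x)
  if (n < 16)
    gl_stop(sprintf("signal too short to filter stably (%d < 16 samples)", n),
            "griplift_error_short_signal")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  np <- min(n - 1L, as.integer(round(fs / 2)))
  left <- 2 * x[1] - x[(np + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(np + 1):(np + n)]
}

#' Finite-difference force rate
#'
#' Central differences in the interior, one-sided differences at the two
#' boundary samples.
#'
#' @param x numeric signal (N); all values must be finite.
#' @param fs sampling frequency, Hz.
#' @return Rate signal in N/s, same length as `x`.
#' @examples
#' force_rate(3 * (0:119) / 120, fs = 120)  # constant 3 N/s inside
#' @export
force_rate <- function(x, fs = 120) {
  if (any(!is.finite(x)))
    gl_stop("signal contains non-finite samples", "griplift_error_nonfinite")
  n <- length(x)
  if (n < 3)
    gl_stop("signal too short for finite differences (need >= 3 samples)",
            "griplift_error_short_signal")
  r <- numeric(n)
  r[1] <- (x[2] - x[1]) * fs
  r[n] <- (x[n] - x[n - 1]) * fs
  r[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  r
}

#' Merge stand-sensor and accelerometer-derived load force
#'
#' The stand sensor measures load force only until lift-off; afterwards the
#' load on the digits equals object mass times the combined gravitational
#' and kinematic acceleration. Returns the merged channel: `lf_stand`
#' before `t_liftoff`, `mass * az` at and after it. The splice must be
#' continuous to within sensor noise.
#'
#' @param lf_stand stand-sensor load force, N.
#' @param az combined gravito-inertial acceleration along the object axis,
#'   m/s^2 (same length as `lf_stand`).
#' @param mass object mass, kg (> 0).
#' @param t_liftoff lift-off time, s from record start. Values beyond the
#'   record leave the stand channel untouched.
#' @param fs sampling frequency, Hz.
#' @param max_jump largest tolerated discontinuity at the splice, N.
#' @return Merged load-force signal, N.
#' @export
compute_load_force <- function(lf_stand, az, mass, t_liftoff, fs = 120,
                               max_jump = 0.5) {
  if (mass <= 0) gl_stop("mass must be > 0", "griplift_error_domain")
  if (length(lf_stand) != length(az))
    gl_stop("lf_stand and az must have the same length", "griplift_error_domain")
  if (any(!is.finite(lf_stand)) || any(!is.finite(az)))
    gl_stop("signal contains non-finite samples", "griplift_error_nonfinite")
  n <- length(lf_stand)
  t <- (seq_len(n) - 1L) / fs
  if (t_liftoff > t[n]) return(lf_stand)
  i0 <- which(t >= t_liftoff)[1]
  out <- lf_stand
  out[i0:n] <- mass * az[i0:n]
  if (i0 > 1 && abs(out[i0] - lf_stand[i0 - 1]) > max_jump)
    gl_stop(sprintf(
      "discontinuous splice at lift-off (%.3f N jump > %.3f N tolerance)",
      abs(out[i0] - lf_stand[i0 - 1]), max_jump),
      "griplift_error_splice")
  out
}

# Validate a trial_recording: channel lengths, uniform grid, finite values.
validate_recording <- function(rec) {
  need <- c("t", "gf", "lf_stand", "az", "fs")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    gl_stop(paste("recording lacks field(s):", paste(miss, collapse = ", ")),
            "griplift_error_format")
  n <- length(rec$t)
  if (n < 2 || length(rec$gf) != n || length(rec$lf_stand) != n ||
      length(rec$az) != n)
    gl_stop("recording channels must share a common length >= 2",
            "griplift_error_format")
  for (ch in c("t", "gf", "lf_stand", "az")) {
    bad <- which(!is.finite(rec[[ch]]))
    if (length(bad))
      gl_stop(sprintf("non-finite value in channel '%s' at row %d", ch, bad[1]),
              "griplift_error_nonfinite")
  }
  dt <- diff(rec$t)
  if (any(abs(dt - 1 / rec$fs) > 1e-9))
    gl_stop("time grid is not uniform at 1/fs spacing",
            "griplift_error_format")
  invisible(rec)
}
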