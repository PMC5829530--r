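# Per-trial dynamic and temporal metrics: exponential grip-force decay,
# grip-load rate coupling, ratios, peak rates, and the composed per-trial
# analysis.

#' Fit the post-peak exponential grip-force decay
#'
#' Nonlinear least squares of `GF(t) = a + b * exp(-c * (t - tGFmax))` on
#' the segment between the grip-force peak and the trial end. Parameter `a`
#' estimates the grip-force plateau, `b` the decay amplitude and `c` (1/s)
#' the relaxation rate (`tau = 1/c`). Initialization: `a0` = mean grip
#' force over the final second, `b0 = GF(tGFmax) - a0`, `c0 = 2/s`; the
#' fit is restarted with rescaled `c0` values if it fails to converge, and
#' parameters are bounded (`a, b >= 0`, `c` in [1e-3, 50] 1/s).
#'
#' @param gf grip force, N.
#' @param t time grid, s.
#' @param tGFmax grip-force peak time, s.
#' @param tEnd trial end time, s.
#' @return Object of class `decay_fit`: list with `a`, `b`, `c`, `tau`,
#'   `rmse`, `n`.
#' @examples
#' t <- (0:300) / 120
#' gf <- 2 + 1.5 * exp(-2.5 * t)
#' fit_gf_decay(gf, t, 0, max(t))
#' @export
fit_gf_decay <- function(gf, t, tGFmax, tEnd) {
  idx <- which(t >= tGFmax & t <= tEnd)
  if (length(idx) < 10)
    gl_stop(sprintf("decay segment too short (%d < 10 samples)", length(idx)),
            "griplift_error_short_signal")
  ts <- t[idx] - tGFmax
  y <- gf[idx]

  last_s <- which(t >= tEnd - 1 & t <= tEnd)
  a0 <- if (length(last_s)) mean(gf[last_s]) else mean(tail(y, 10))
  b0 <- max(y[1] - a0, 0)

  if (sd(y) < 1e-8) {
    fit <- list(a = mean(y), b = 0, c = 1e-3, tau = 1000, rmse = 0,
                n = length(y))
    class(fit) <- "decay_fit"
    return(fit)
  }

  best <- NULL
  for (mult in c(1, 0.5, 2, 0.1, 10)) {
    res <- tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ a + b * exp(-cc * ts),
        start = list(a = max(a0, 0), b = max(b0, 1e-6), cc = 2 * mult),
        lower = c(0, 0, 1e-3), upper = c(Inf, Inf, 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      p <- coef(m)
      rmse <- sqrt(mean(residuals(m)^2))
      list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["cc"]),
           rmse = rmse)
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$rmse < best$rmse)) best <- res
    if (!is.null(best) && best$rmse < 1e-10) break
  }
  if (is.null(best))
    gl_stop("exponential decay fit failed to converge",
            "griplift_error_fit_failure")
  fit <- list(a = best$a, b = best$b, c = best$c, tau = 1 / best$c,
              rmse = best$rmse, n = length(y))
  class(fit) <- "decay_fit"
  fit
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> a=%.3f N, b=%.3f N, c=%.3f 1/s (tau=%.0f ms), rmse=%.4f N (n=%d)\n",
    x$a, x$b, x$c, 1000 * x$tau, x$rmse, x$n))
  invisible(x)
}

#' Grip-load rate coupling by lagged cross-correlation
#'
#' Pearson correlation between the load-force rate (reference signal) over
#' the loading phase `[tLFo, tLFw]` and the grip-force rate shifted by
#' every integer-sample lag within `+/-max_lag` (150 ms, i.e. +/-18 samples
#' at 120 Hz). Returns the largest correlation and the lag at which it
#' occurs; a positive lag means grip force rate leads load force rate.
#' Ties on the correlation are broken towards the smallest |lag|.
#'
#' @param gf_rate grip-force rate, N/s (full record).
#' @param lf_rate load-force rate, N/s (full record, same grid).
#' @param t time grid, s.
#' @param tLFo load-force onset, s.
#' @param tLFw weight-crossing time, s.
#' @param max_lag maximum absolute lag, s.
#' @return Object of class `coupling_stats`: list with `r_max`, `lag`
#'   (s), `lag_samples`.
#' @export
xcorr_rates <- function(gf_rate, lf_rate, t, tLFo, tLFw, max_lag = 0.150) {
  if (length(gf_rate) != length(lf_rate) || length(gf_rate) != length(t))
    gl_stop("rate signals and time grid must share a length",
            "griplift_error_domain")
  fs <- 1 / median(diff(t))
  win <- which(t >= tLFo & t <= tLFw)
  if (length(win) < 8)
    gl_stop(sprintf("loading window too short (%d < 8 samples)", length(win)),
            "griplift_error_short_signal")
  if (var(lf_rate[win]) < 1e-12)
    gl_stop("zero-variance load-force rate segment",
            "griplift_error_undefined_correlation")
  K <- floor(max_lag * fs + 1e-9)
  n <- length(gf_rate)
  lags <- -K:K
  r <- rep(NA_real_, length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    src <- win - k
    if (src[1] < 1 || src[length(src)] > n) next
    g <- gf_rate[src]
    if (var(g) < 1e-12) next
    r[j] <- cor(lf_rate[win], g)
  }
  if (all(is.na(r)))
    gl_stop("zero-variance grip-force rate segment at every lag",
            "griplift_error_undefined_correlation")
  rmax <- max(r, na.rm = TRUE)
  cand <- which(!is.na(r) & abs(r - rmax) < 1e-15)
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  out <- list(r_max = r[best], lag = lags[best] / fs,
              lag_samples = lags[best])
  class(out) <- "coupling_stats"
  out
}

#' @export
print.coupling_stats <- function(x, ...) {
  cat(sprintf("<coupling_stats> r_max=%.3f at lag %+.1f ms (%+d samples)\n",
              x$r_max, 1000 * x$lag, x$lag_samples))
  invisible(x)
}

#' Grip/load force ratios at the load-force peak and on the plateau
#'
#' @param gf grip force, N.
#' @param lf load force, N (merged channel).
#' @param t time grid, s.
#' @param tLFmax load-force peak time, s.
#' @param plateaus list with `gf_plateau`, `lf_plateau` (see
#'   [plateau_means()]).
#' @return List with `ratio_at_LFmax` and `ratio_plateau`.
#' @export
grip_load_ratios <- function(gf, lf, t, tLFmax, plateaus) {
  i <- which.min(abs(t - tLFmax))
  if (lf[i] <= 0)
    gl_stop("nonpositive load force at its peak time", "griplift_error_domain")
  if (!is.numeric(plateaus$lf_plateau) || plateaus$lf_plateau <= 0)
    gl_stop("nonpositive load-force plateau", "griplift_error_domain")
  list(ratio_at_LFmax = gf[i] / lf[i],
       ratio_plateau = plateaus$gf_plateau / plateaus$lf_plateau)
}

#' Peak grip-force rate within a window
#'
#' Maximum of the grip-force rate over `[window[1], window[2]]`. On valid
#' lifts the rate peak precedes the force peak; if `tGFmax` is supplied and
#' the detected rate peak does not precede it, a warning is emitted.
#'
#' @param gf_rate grip-force rate, N/s.
#' @param t time grid, s.
#' @param window numeric length-2 analysis window, s.
#' @param tGFmax optional grip-force peak time for the ordering check, s.
#' @return List with `peak_gf_rate` (N/s) and `t_peak_rate` (s).
#' @export
peak_gf_rate <- function(gf_rate, t, window, tGFmax = NULL) {
  idx <- which(t >= window[1] & t <= window[2])
  if (!length(idx))
    gl_stop("empty grip-force rate window", "griplift_error_domain")
  j <- idx[which.max(gf_rate[idx])]
  if (!is.null(tGFmax) && t[j] >= tGFmax)
    warning("grip-force rate peak does not precede the force peak",
            call. = FALSE)
  list(peak_gf_rate = gf_rate[j], t_peak_rate = t[j])
}

#' Analyze one grip-lift trial
#'
#' Composes the full per-trial pipeline: zero-phase low-pass filtering of
#' all channels, finite-difference force rates, grip- and load-force onset
#' detection, object weight from the pre-lift accelerometer baseline,
#' weight-crossing (lift-off), stand/accelerometer load-force merge, trial
#' end, peaks, plateau means, phase durations, ratios, peak grip-force
#' rate, exponential decay fit and grip-load rate coupling.
#'
#' @param recording a `trial_recording` (see [simulate_trial()] or
#'   [read_trial()]).
#' @param context a `trial_context` (or named list with at least
#'   `participant`, `g_level`, `trial_index`, `phase`, `mass`).
#' @param params an [analysis_params()] list of thresholds.
#' @return Object of class `trial_metrics`: a list with `events`
#'   ([trial_events()]), forces, ratios, durations, `decay`
#'   ([fit_gf_decay()]), `coupling` ([xcorr_rates()]) and the context.
#' @export
analyze_trial <- function(recording, context, params = analysis_params()) {
  validate_recording(recording)
  if (!all(c("participant", "g_level", "trial_index", "mass") %in%
           names(context)))
    gl_stop("context lacks required fields", "griplift_error_format")
  fs <- recording$fs
  t <- recording$t

  gf_f <- lowpass_filter(recording$gf, fs, params$lowpass_cutoff)
  lfs_f <- lowpass_filter(recording$lf_stand, fs, params$lowpass_cutoff)
  az_f <- lowpass_filter(recording$az, fs, params$lowpass_cutoff)

  gf_rate <- force_rate(gf_f, fs)
  lfs_rate <- force_rate(lfs_f, fs)

  tGFo <- detect_onset(gf_rate, fs, params$onset_threshold,
                       params$onset_min_duration, search_start = 0)
  tLFo <- detect_onset(lfs_rate, fs, params$onset_threshold,
                       params$onset_min_duration, search_start = tGFo)

  base_idx <- which(t < tGFo)
  if (length(base_idx) < 5)
    gl_stop("no pre-lift baseline to estimate object weight",
            "griplift_error_inconsistent_trial")
  weight <- context$mass * mean(az_f[base_idx])

  tLFw <- weight_crossing_time(lfs_f, t, weight, after = tLFo)
  lf <- compute_load_force(lfs_f, az_f, context$mass, tLFw, fs)
  lf_rate <- force_rate(lf, fs)

  tEnd <- detect_trial_end(lf_rate, fs, params$end_threshold,
                           params$end_min_duration, params$end_backoff,
                           after = tLFw)

  peaks <- detect_peaks(gf_f, lf, t, gf_window = c(tGFo, tEnd),
                        lf_window = c(tLFo, tEnd))
  events <- trial_events(tGFo, tLFo, tLFw, peaks$tGFmax, peaks$tLFmax, tEnd)
  plateaus <- plateau_means(gf_f, lf, t, tEnd, params$plateau_window,
                            tLFw = tLFw)
  durs <- phase_durations(events)
  ratios <- grip_load_ratios(gf_f, lf, t, peaks$tLFmax, plateaus)
  pr <- peak_gf_rate(gf_rate, t, c(tGFo, tEnd), tGFmax = peaks$tGFmax)
  decay <- fit_gf_decay(gf_f, t, peaks$tGFmax, tEnd)
  coupling <- xcorr_rates(gf_rate, lf_rate, t, tLFo, tLFw, params$max_lag)

  out <- list(
    events = events,
    GFmax = peaks$GFmax, LFmax = peaks$LFmax,
    gf_plateau = plateaus$gf_plateau, lf_plateau = plateaus$lf_plateau,
    ratio_at_LFmax = ratios$ratio_at_LFmax,
    ratio_plateau = ratios$ratio_plateau,
    preload = durs$preload, loading = durs$loading,
    peak_gf_rate = pr$peak_gf_rate, t_peak_gf_rate = pr$t_peak_rate,
    weight = weight,
    decay = decay, coupling = coupling,
    context = context
  )
  class(out) <- "trial_metrics"
  out
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf(
    "<trial_metrics> %s g=%.2f trial %d: GFmax=%.2f N, LFmax=%.2f N, plateau ratio=%.2f, preload=%.0f ms, tau=%.0f ms, r=%.3f\n",
    x$context$participant %||% "?", x$context$g_level, x$context$trial_index,
    x$GFmax, x$LFmax, x$ratio_plateau, 1000 * x$preload,
    1000 * x$decay$tau, x$coupling$r_max))
  invisible(x)
}

#' Analysis thresholds and windows
#'
#' All rule parameters of the per-trial pipeline, with the protocol's
#' values as defaults: 20 Hz low-pass cutoff, 0.4 N/s onset threshold
#' sustained 125 ms, -2 N/s trial-end threshold sustained 125 ms with
#' 250 ms backoff, +/-150 ms coupling lag window, 1 s plateau window.
#'
#' @param lowpass_cutoff Hz.
#' @param onset_threshold N/s.
#' @param onset_min_duration s.
#' @param end_threshold N/s.
#' @param end_min_duration s.
#' @param end_backoff s.
#' @param max_lag s.
#' @param plateau_window s.
#' @return Named list of class `analysis_params`.
#' @export
analysis_params <- function(lowpass_cutoff = 20,
                            onset_threshold = 0.4,
                            onset_min_duration = 0.125,
                            end_threshold = -2,
                            end_min_duration = 0.125,
                            end_backoff = 0.250,
                            max_lag = 0.150,
                            plateau_window = 1.0) {
  structure(list(
    lowpass_cutoff = lowpass_cutoff,
    onset_threshold = onset_threshold,
    onset_min_duration = onset_min_duration,
    end_threshold = end_threshold,
    end_min_duration = end_min_duration,
    end_backoff = end_backoff,
    max_lag = max_lag,
    plateau_window = plateau_window
  ), class = "analysis_params")
}

#' Analyze every trial of a session into a metrics table
#'
#' Runs [analyze_trial()] on each trial; trials whose segmentation or fit
#' fails are excluded from the table, reported in the `failures` attribute
#' and summarized in a warning.
#'
#' @param session a `grip_session` from [simulate_session()], or a list of
#'   `list(recording, context)` elements.
#' @param params an [analysis_params()].
#' @return A tibble with one row per successfully analyzed trial; attribute
#'   `failures` holds a tibble of failed trials and their error messages.
#' @export
analyze_session <- function(session, params = analysis_params()) {
  rows <- list()
  fails <- list()
  for (i in seq_along(session)) {
    el <- session[[i]]
    res <- tryCatch(
      analyze_trial(el$recording, el$context, params),
      griplift_error = function(e) e
    )
    ctx <- el$context
    if (inherits(res, "griplift_error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        participant = ctx$participant %||% NA_character_,
        phase_occurrence = ctx$phase_occurrence %||% NA_integer_,
        trial_index = ctx$trial_index %||% NA_integer_,
        error = conditionMessage(res)
      )
    } else {
      rows[[length(rows) + 1]] <- metrics_row(res)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else metrics_row(NULL)
  failures <- if (length(fails)) dplyr::bind_rows(fails) else NULL
  if (!is.null(failures))
    warning(sprintf("%d trial(s) failed analysis and were excluded",
                    nrow(failures)), call. = FALSE)
  attr(out, "failures") <- failures
  out
}

metrics_row <- function(m) {
  if (is.null(m)) {
    return(tibble::tibble(
      participant = character(), phase_occurrence = integer(),
      phase = character(), g_level = numeric(), g_realized = numeric(),
      trial_index = integer(), mass = numeric(),
      GFmax = numeric(), LFmax = numeric(), tGFmax = numeric(),
      tLFmax = numeric(), gf_plateau = numeric(), lf_plateau = numeric(),
      ratio_at_LFmax = numeric(), ratio_plateau = numeric(),
      preload_s = numeric(), loading_s = numeric(),
      peak_gf_rate = numeric(), decay_a = numeric(), decay_b = numeric(),
      decay_c = numeric(), decay_tau = numeric(), decay_rmse = numeric(),
      coupling_r = numeric(), coupling_lag_s = numeric(),
      tGFo = numeric(), tLFo = numeric(), tLFw = numeric(), tEnd = numeric()
    ))
  }
  ctx <- m$context
  tibble::tibble(
    participant = ctx$participant %||% NA_character_,
    phase_occurrence = as.integer(ctx$phase_occurrence %||% NA_integer_),
    phase = ctx$phase %||% NA_character_,
    g_level = ctx$g_level,
    g_realized = ctx$g_realized %||% NA_real_,
    trial_index = as.integer(ctx$trial_index),
    mass = ctx$mass,
    GFmax = m$GFmax, LFmax = m$LFmax,
    tGFmax = m$events$tGFmax, tLFmax = m$events$tLFmax,
    gf_plateau = m$gf_plateau, lf_plateau = m$lf_plateau,
    ratio_at_LFmax = m$ratio_at_LFmax, ratio_plateau = m$ratio_plateau,
    preload_s = m$preload, loading_s = m$loading,
    peak_gf_rate = m$peak_gf_rate,
    decay_a = m$decay$a, decay_b = m$decay$b, decay_c = m$decay$c,
    decay_tau = m$decay$tau, decay_rmse = m$decay$rmse,
    coupling_r = m$coupling$r_max, coupling_lag_s = m$coupling$lag,
    tGFo = m$events$tGFo, tLFo = m$events$tLFo, tLFw = m$events$tLFw,
    tEnd = m$events$tEnd
  )
}
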