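# Synthetic grip-lift trial generator.
#
# A trial is synthesized as a continuous-time, piecewise C1 profile and then
# sampled on the 1/fs grid:
#   baseline -> grip-force rise (covering preload + loading) -> exponential
#   grip relaxation to plateau -> hold -> release; load force rises from its
#   onset through the object's weight to an overshooting peak, settles to the
#   static weight m*g*g0, holds, and is released at a mean rate steeper than
#   the -2 N/s trial-end rule. The accelerometer channel carries the
#   gravitoinertial level before lift-off and the load-equivalent
#   acceleration (lf/m) afterwards.

trial_profile_params <- function(g_level, trial_index, config) {
  m <- config$mass; g0 <- config$g0
  W <- m * g_level * g0
  LFpeak <- (1 + config$overshoot_frac) * W
  first <- if (trial_index == 1L) config$first_trial_margin else 0
  GFmax <- config$grip_gain * LFpeak + config$base_margin +
    config$peak_margin + first
  a <- config$grip_gain * W + config$base_margin
  p <- (if (trial_index == 1L) config$preload_ms_trial1 else config$preload_ms) / 1000
  L <- config$loading_ms / 1000

  tGFo <- config$baseline_s
  tLFo <- tGFo + p
  tLFmax <- tLFo + L
  tGFmax <- tLFmax                     # lag imposed later by sample shift
  # weight crossing of the rising smoothstep: solve S(s) = W / LFpeak
  frac <- W / LFpeak
  s_star <- if (frac >= 1) 1 else
    stats::uniroot(function(s) smoothstep(s) - frac, c(0, 1),
                   tol = 1e-12)$root
  tLFw <- tLFo + s_star * L
  t_settle_end <- tLFmax + config$settle_s
  t_rel <- t_settle_end + config$hold_s
  R <- W / config$release_rate         # smoothstep release, mean slope = rate
  t_end_rec <- t_rel + R + config$tail_s

  # analysis-end ground truth: first time the release rate crosses -2 N/s,
  # minus the 250 ms backoff; smoothstep slope is 6*(W/R)*s*(1-s)
  disc <- 1 - 4 * 2 / (6 * config$release_rate)
  s_lo <- (1 - sqrt(disc)) / 2
  tEnd <- t_rel + s_lo * R - 0.250

  list(W = W, LFpeak = LFpeak, GFmax = GFmax, a = a, b = GFmax - a,
       tau = config$decay_tau, p = p, L = L,
       tGFo = tGFo, tLFo = tLFo, tLFw = tLFw, tLFmax = tLFmax,
       tGFmax = tGFmax, t_settle_end = t_settle_end, t_rel = t_rel, R = R,
       tEnd = tEnd, t_end_rec = t_end_rec)
}

lf_true_at <- function(t, pp) {
  out <- numeric(length(t))
  rise <- t >= pp$tLFo & t < pp$tLFmax
  out[rise] <- pp$LFpeak * smoothstep((t[rise] - pp$tLFo) / pp$L)
  settle <- t >= pp$tLFmax & t < pp$t_settle_end
  out[settle] <- pp$W + (pp$LFpeak - pp$W) *
    (1 - smoothstep((t[settle] - pp$tLFmax) / max(pp$t_settle_end - pp$tLFmax, 1e-9)))
  hold <- t >= pp$t_settle_end & t < pp$t_rel
  out[hold] <- pp$W
  rel <- t >= pp$t_rel
  out[rel] <- pp$W * (1 - smoothstep((t[rel] - pp$t_rel) / pp$R))
  out
}

gf_true_at <- function(t, pp) {
  out <- numeric(length(t))
  rise <- t >= pp$tGFo & t < pp$tGFmax
  out[rise] <- pp$GFmax * smoothstep((t[rise] - pp$tGFo) / (pp$tGFmax - pp$tGFo))
  # exponential relaxation to the plateau offset a, held until grip release
  t_gf_rel <- pp$t_rel + pp$R          # grip released once load is down
  decay <- t >= pp$tGFmax & t < t_gf_rel
  out[decay] <- pp$a + pp$b * exp(-(t[decay] - pp$tGFmax) / pp$tau)
  rel <- t >= t_gf_rel
  gf_at_rel <- pp$a + pp$b * exp(-(t_gf_rel - pp$tGFmax) / pp$tau)
  out[rel] <- gf_at_rel * (1 - smoothstep((t[rel] - t_gf_rel) / 0.25))
  out
}

#' Simulate one synthetic grip-lift trial with ground truth
#'
#' Generates a noiseless five-segment grip-lift profile (baseline, preload,
#' loading to an overshooting load-force peak, exponential grip-force
#' relaxation to a plateau, ~2 s hold, release), imposes the configured
#' integer-sample grip-load lag by shifting the grip-force trace, adds
#' white Gaussian sensor noise, and returns both the sampled recording and
#' the full ground truth of every imposed quantity.
#'
#' Trial 1 after a transition carries `first_trial_margin` on top of
#' `base_margin` in its grip-force peak; trials 2-4 carry only
#' `base_margin`. The noiseless load-force plateau is exactly
#' `mass * g_level * g0`.
#'
#' @param g_level realized gravitoinertial level, multiples of standard
#'   gravity (> 0).
#' @param trial_index trial number within the phase, 1..4.
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list with elements `recording` (a `trial_recording`: `t`, `gf`,
#'   `lf_stand`, `az`, `fs`) and `truth` (ground-truth event times, plateau
#'   forces, decay parameters, imposed lag, gain and margins).
#' @examples
#' tr <- simulate_trial(1.5, 1, sim_config(noise_sd = 0), seed = 1)
#' tr$truth$lf_plateau  # 0.13 * 1.5 * 9.81
#' @export
simulate_trial <- function(g_level, trial_index, config = sim_config(),
                           seed = 1L) {
  config <- validate_sim_config(unclass(config))
  if (!is.numeric(g_level) || length(g_level) != 1 || !is.finite(g_level) ||
      g_level <= 0)
    gl_config_error("g_level", "must be a positive scalar")
  if (!trial_index %in% 1:4)
    gl_config_error("trial_index", "must be in 1..4")

  pp <- trial_profile_params(g_level, as.integer(trial_index), config)
  fs <- config$fs
  n <- ceiling(pp$t_end_rec * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  lf <- lf_true_at(t, pp)
  gf <- gf_true_at(t, pp)

  # imposed grip-load lag: integer sample shift, positive = grip leads
  # (grip profile moved earlier in time)
  k <- config$lag_samples
  if (k != 0L) {
    idx <- pmin(pmax(seq_len(n) + k, 1L), n)
    gf <- gf[idx]
  }

  az <- ifelse(t < pp$tLFw, g_level * config$g0, lf / config$mass)
  # the stand sensor is authoritative until lift-off; afterwards it mirrors
  # the load profile so that no step discontinuity pollutes the filtered
  # channel near the weight crossing (its post-lift-off values are never
  # used by the stand/accelerometer merge)
  lf_stand <- lf

  rec <- with_seed(seed, {
    gf_n <- gf + rnorm(n, 0, config$noise_sd)
    lfs_n <- lf_stand + rnorm(n, 0, config$noise_sd)
    az_n <- az + rnorm(n, 0, config$az_noise_sd)
    list(t = t, gf = gf_n, lf_stand = lfs_n, az = az_n, fs = fs)
  })
  class(rec) <- "trial_recording"

  shift_s <- k / fs
  t_gf_rel <- pp$t_rel + pp$R
  # analytic mean of the decay over the last-second plateau window
  w0 <- pp$tEnd - 1; w1 <- pp$tEnd
  gf_plateau_true <- pp$a + pp$b * pp$tau *
    (exp(-(w0 - pp$tGFmax) / pp$tau) - exp(-(w1 - pp$tGFmax) / pp$tau)) / (w1 - w0)

  truth <- list(
    tGFo = pp$tGFo - shift_s,
    tLFo = pp$tLFo,
    tLFw = pp$tLFw,
    tGFmax = pp$tGFmax - shift_s,
    tLFmax = pp$tLFmax,
    tEnd = pp$tEnd,
    preload = pp$tLFo - (pp$tGFo - shift_s),
    loading = pp$tLFw - pp$tLFo,
    GFmax = pp$GFmax,
    LFmax = pp$LFpeak,
    gf_plateau = gf_plateau_true,
    lf_plateau = pp$W,
    decay_a = pp$a,
    decay_b = pp$b,
    decay_c = 1 / pp$tau,
    decay_tau = pp$tau,
    lag_s = shift_s,
    peak_gf_rate = 1.5 * pp$GFmax / (pp$tGFmax - pp$tGFo),
    grip_gain = config$grip_gain,
    base_margin = config$base_margin,
    first_trial_margin = if (trial_index == 1L) config$first_trial_margin else 0,
    g_level = g_level,
    weight = pp$W,
    grip_release_time = t_gf_rel
  )
  stopifnot(truth$tGFo < truth$tLFo, truth$tLFo < truth$tLFw,
            truth$tLFw <= truth$tLFmax, truth$tLFmax < truth$tEnd)

  list(recording = rec, truth = truth)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording> ", length(x$t), " samples @ ", x$fs, " Hz (",
      round(max(x$t), 2), " s); gf [",
      round(min(x$gf), 2), ", ", round(max(x$gf), 2), "] N\n", sep = "")
  invisible(x)
}

#' Simulate a full multi-participant centrifuge session
#'
#' Generates four grip-lift trials per stable gravity phase per participant
#' under a [gravity_schedule()]. The realized gravity level of every trial
#' is perturbed around the programmed level by `g_jitter_sd`. Phases up to
#' and including the single highest level are labelled ascending, later
#' phases descending.
#'
#' @param schedule a [gravity_schedule()].
#' @param n_participants number of simulated participants (>= 1).
#' @param config a [sim_config()].
#' @param seed integer master seed; per-trial seeds are derived
#'   deterministically from it.
#' @param trials_per_phase trials per stable phase (4 in the protocol).
#' @return An object of class `grip_session`: a list of trials, each a list
#'   with `recording`, `context` (participant, g_level, g_realized,
#'   trial_index, phase, phase_occurrence, mass, fs, seed) and `truth`;
#'   attributes carry the schedule and config.
#' @examples
#' ses <- simulate_session(gravity_schedule(), 1,
#'                         sim_config(noise_sd = 0, g_jitter_sd = 0), seed = 1)
#' length(ses)  # 7 phases x 4 trials
#' @export
simulate_session <- function(schedule = gravity_schedule(),
                             n_participants = 7,
                             config = sim_config(),
                             seed = 1L,
                             trials_per_phase = 4L) {
  config <- validate_sim_config(unclass(config))
  if (!inherits(schedule, "gravity_schedule"))
    gl_config_error("schedule", "must be a gravity_schedule")
  phases <- stable_phases(schedule)
  if (nrow(phases) == 0) gl_config_error("schedule", "has no stable phases")
  if (!is.numeric(n_participants) || n_participants < 1)
    gl_config_error("n_participants", "must be >= 1")
  n_participants <- as.integer(n_participants)
  trials_per_phase <- as.integer(trials_per_phase)

  n_trials <- n_participants * nrow(phases) * trials_per_phase
  draws <- with_seed(seed, {
    list(jitter = rnorm(n_trials, 0, config$g_jitter_sd),
         seeds = sample.int(.Machine$integer.max - 1L, n_trials))
  })

  out <- vector("list", n_trials)
  i <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    for (ph in seq_len(nrow(phases))) {
      for (tr in seq_len(trials_per_phase)) {
        i <- i + 1L
        g_real <- max(phases$g_level[ph] + draws$jitter[i], 0.05)
        sim <- simulate_trial(g_real, tr, config, seed = draws$seeds[i])
        ctx <- list(
          participant = pid,
          g_level = phases$g_level[ph],
          g_realized = g_real,
          trial_index = tr,
          phase = phases$phase[ph],
          phase_occurrence = phases$phase_occurrence[ph],
          mass = config$mass,
          fs = config$fs,
          seed = draws$seeds[i]
        )
        class(ctx) <- "trial_context"
        out[[i]] <- list(recording = sim$recording, context = ctx,
                         truth = sim$truth)
      }
    }
  }
  structure(out, class = c("grip_session", "list"),
            schedule = schedule, config = config, seed = seed)
}

#' @export
print.grip_session <- function(x, ...) {
  ctx <- lapply(x, `[[`, "context")
  cat("<grip_session> ", length(x), " trials, ",
      length(unique(vapply(ctx, `[[`, "", "participant"))), " participants, ",
      length(unique(vapply(ctx, `[[`, 0L, "phase_occurrence"))), " phases\n",
      sep = "")
  invisible(x)
}
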