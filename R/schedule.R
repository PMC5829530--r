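#' Gravity schedule of a centrifuge session
#'
#' Describes the programmed Gz profile as an ordered set of stable phases
#' joined by linear transitions, bracketed by idle 1 g periods. The default
#' reproduces the seven-phase profile 1, 1.5, 2, 2.5, 2, 1.5, 1 g with
#' 18.4 s stable phases, 1.6 s fast transitions between hypergravity levels,
#' 13.4 s slow transitions between 1 and 1.5 g (to limit motion sickness)
#' and 27.4 s idle 1 g bookends.
#'
#' @param g_levels numeric vector of stable-phase levels, in multiples of
#'   standard gravity. All levels must be positive.
#' @param stable_s duration of each stable phase (s).
#' @param fast_transition_s duration of transitions between consecutive
#'   hypergravity phases (s).
#' @param slow_transition_s duration of transitions into and out of 1 g (s).
#' @param idle_s duration of the idle 1 g bookends (s).
#'
#' @return An object of class `gravity_schedule`: a list with a `segments`
#'   data frame (`type`, `g_start`, `g_end`, `t_start`, `t_end`,
#'   `phase_occurrence`) and the input parameters.
#' @examples
#' sched <- gravity_schedule()
#' gz_profile(c(0, 50, 100), sched)
#' @export
gravity_schedule <- function(g_levels = c(1, 1.5, 2, 2.5, 2, 1.5, 1),
                             stable_s = 18.4,
                             fast_transition_s = 1.6,
                             slow_transition_s = 13.4,
                             idle_s = 27.4) {
  if (length(g_levels) < 1) gl_config_error("g_levels", "must be non-empty")
  if (any(!is.finite(g_levels)) || any(g_levels <= 0))
    gl_config_error("g_levels", "must be positive and finite")
  for (f in c("stable_s", "fast_transition_s", "slow_transition_s", "idle_s")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      gl_config_error(f, "must be a positive scalar")
  }

  seg <- list()
  t <- 0
  add <- function(type, g0, g1, dur, occ = NA_integer_) {
    seg[[length(seg) + 1]] <<- data.frame(
      type = type, g_start = g0, g_end = g1,
      t_start = t, t_end = t + dur, phase_occurrence = occ
    )
    t <<- t + dur
  }

  # a transition to or from a 1 g level is the slow one
  trans_dur <- function(ga, gb) {
    if (isTRUE(all.equal(ga, 1)) || isTRUE(all.equal(gb, 1)))
      slow_transition_s else fast_transition_s
  }

  add("idle", 1, 1, idle_s)
  if (!isTRUE(all.equal(g_levels[1], 1)))
    add("transition", 1, g_levels[1], trans_dur(1, g_levels[1]))
  for (k in seq_along(g_levels)) {
    add("stable", g_levels[k], g_levels[k], stable_s, occ = k)
    if (k < length(g_levels) && !isTRUE(all.equal(g_levels[k], g_levels[k + 1])))
      add("transition", g_levels[k], g_levels[k + 1],
          trans_dur(g_levels[k], g_levels[k + 1]))
  }
  if (!isTRUE(all.equal(g_levels[length(g_levels)], 1)))
    add("transition", g_levels[length(g_levels)], 1,
        trans_dur(g_levels[length(g_levels)], 1))
  add("idle", 1, 1, idle_s)

  segments <- do.call(rbind, seg)
  slopes <- with(segments, abs(g_end - g_start) / (t_end - t_start))
  structure(
    list(segments = segments, g_levels = g_levels, stable_s = stable_s,
         fast_transition_s = fast_transition_s,
         slow_transition_s = slow_transition_s, idle_s = idle_s,
         max_slope = max(slopes), total_s = t),
    class = "gravity_schedule"
  )
}

#' Evaluate the programmed Gz profile
#'
#' Piecewise-linear interpolation of the scheduled gravitoinertial level:
#' constant during idle and stable segments, linear during transitions.
#' Times beyond the end of the profile clamp to the final 1 g level.
#'
#' @param t time, seconds from profile start (vectorized); must be >= 0.
#' @param schedule a [gravity_schedule()].
#' @return Gz in multiples of standard gravity, same length as `t`.
#' @examples
#' gz_profile(0, gravity_schedule())  # 1 g idle
#' @export
gz_profile <- function(t, schedule) {
  stopifnot(inherits(schedule, "gravity_schedule"))
  if (any(!is.finite(t)) || any(t < 0))
    gl_stop("t must be finite and >= 0", "griplift_error_domain")
  seg <- schedule$segments
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- min(t[i], schedule$total_s)
    j <- which(seg$t_start <= ti & ti <= seg$t_end)[1]
    s <- seg[j, ]
    frac <- if (s$t_end > s$t_start) (ti - s$t_start) / (s$t_end - s$t_start) else 0
    out[i] <- s$g_start + frac * (s$g_end - s$g_start)
  }
  out
}

#' Stable phases of a schedule in chronological order
#'
#' @param schedule a [gravity_schedule()].
#' @return A tibble with `phase_occurrence`, `g_level`, `phase`
#'   (ascending/descending), `t_start`, `t_end`. The single highest phase of
#'   an up-down profile is labelled ascending (it terminates the ascent).
#' @export
stable_phases <- function(schedule) {
  stopifnot(inherits(schedule, "gravity_schedule"))
  seg <- schedule$segments
  st <- seg[seg$type == "stable", ]
  g <- st$g_end
  peak <- which.max(g)[1]
  phase <- ifelse(seq_along(g) <= peak, "ascending", "descending")
  tibble::tibble(
    phase_occurrence = st$phase_occurrence,
    g_level = g, phase = phase,
    t_start = st$t_start, t_end = st$t_end
  )
}

#' @export
print.gravity_schedule <- function(x, ...) {
  cat("<gravity_schedule> ", length(x$g_levels), " stable phases: ",
      paste(x$g_levels, collapse = ", "), " g\n", sep = "")
  cat("  stable ", x$stable_s, " s; transitions ", x$fast_transition_s,
      " s (fast) / ", x$slow_transition_s, " s (slow); idle ", x$idle_s,
      " s; total ", round(x$total_s, 1), " s; max |dG/dt| ",
      signif(x$max_slope, 3), " g/s\n", sep = "")
  invisible(x)
}
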