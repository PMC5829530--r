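# Session-level aggregation: switching indices across gravity transitions,
# the prediction-model decomposition dGF = alpha * m * dg * g0 + beta,
# first-trial peak regression and condition summaries.

#' Switching indices across consecutive gravity phases
#'
#' For each participant and each pair of consecutive stable phases, the
#' grip-force switching index is the grip-force peak of the first trial in
#' the new environment minus the grip-force peak of the last trial in the
#' previous one: `dGF = GFmax(trial 1, next) - GFmax(trial 4, prev)`. The
#' load-force index `dLF` is defined identically from load-force peaks.
#' The sign of the gravity step determines the phase label (ascending /
#' descending).
#'
#' @param metrics session metrics table from [analyze_session()] (needs
#'   `participant`, `phase_occurrence`, `g_level`, `trial_index`, `GFmax`,
#'   `LFmax`).
#' @param last_trial index of the "last" trial in a phase (4 in the
#'   protocol).
#' @return A tibble with one row per participant and transition, in
#'   chronological order: `participant`, `transition`, `g_prev`, `g_next`,
#'   `delta_g`, `dGF`, `dLF`, `phase`. Transitions missing trial 1 or the
#'   last trial are skipped with a message; fewer than two phases yields an
#'   empty tibble with a warning.
#' @export
switching_indices <- function(metrics, last_trial = 4L) {
  need <- c("participant", "phase_occurrence", "g_level", "trial_index",
            "GFmax", "LFmax")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    gl_stop(paste("metrics table lacks column(s):", paste(miss, collapse = ", ")),
            "griplift_error_format")
  occs <- sort(unique(metrics$phase_occurrence))
  empty <- tibble::tibble(
    participant = character(), transition = character(),
    g_prev = numeric(), g_next = numeric(), delta_g = numeric(),
    dGF = numeric(), dLF = numeric(), phase = character()
  )
  if (length(occs) < 2) {
    warning("fewer than two phases: no transitions to index", call. = FALSE)
    return(empty)
  }
  g_of <- function(occ) metrics$g_level[metrics$phase_occurrence == occ][1]
  rows <- list()
  for (pid in unique(metrics$participant)) {
    mp <- metrics[metrics$participant == pid, ]
    for (j in seq_len(length(occs) - 1)) {
      o1 <- occs[j]; o2 <- occs[j + 1]
      prev4 <- mp[mp$phase_occurrence == o1 & mp$trial_index == last_trial, ]
      next1 <- mp[mp$phase_occurrence == o2 & mp$trial_index == 1L, ]
      if (nrow(prev4) != 1 || nrow(next1) != 1) {
        message(sprintf(
          "skipping transition %s->%s for %s: missing trial 1 or trial %d",
          g_of(o1), g_of(o2), pid, last_trial))
        next
      }
      gp <- g_of(o1); gn <- g_of(o2)
      dg <- gn - gp
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = pid,
        transition = paste0(format(gp), "-", format(gn)),
        g_prev = gp, g_next = gn, delta_g = dg,
        dGF = next1$GFmax - prev4$GFmax,
        dLF = next1$LFmax - prev4$LFmax,
        phase = if (dg > 0) "ascending" else "descending"
      )
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

#' Fixed-gain decomposition of a grip-force switching index
#'
#' Decomposes `dGF = alpha * mass * delta_g * g0 + beta` under the
#' "correct prediction" hypothesis: the predictive gain `alpha` is held
#' fixed (1.5, the mean first-trial grip/load ratio) and the safety margin
#' `beta` absorbs the remainder, `beta = dGF - alpha * mass * delta_g * g0`.
#'
#' @param dGF grip-force switching index, N (vectorized).
#' @param mass object mass, kg.
#' @param delta_g gravity step, multiples of standard gravity (vectorized).
#' @param alpha fixed predictive gain (dimensionless).
#' @param g0 standard gravity, m/s^2.
#' @return A tibble with `mode`, `alpha`, `beta`, `predictive_term`
#'   (`alpha * mass * delta_g * g0`), `dGF`, `delta_g`, `mass`, `g0`. The
#'   identity `predictive_term + beta == dGF` holds exactly.
#' @examples
#' decompose_fixed_gain(2.29, 0.13, 0.5)  # predictive term 0.96, beta 1.33
#' @export
decompose_fixed_gain <- function(dGF, mass = 0.13, delta_g = 0.5,
                                 alpha = 1.5, g0 = 9.81) {
  if (mass <= 0) gl_stop("mass must be > 0", "griplift_error_domain")
  pred <- alpha * mass * delta_g * g0
  tibble::tibble(
    mode = "fixed_gain", alpha = alpha, beta = dGF - pred,
    predictive_term = pred, dGF = dGF, delta_g = delta_g,
    mass = mass, g0 = g0
  )
}

#' Fixed-margin decomposition of a grip-force switching index
#'
#' The "incorrect prediction" hypothesis: the safety margin `beta` is held
#' at its 1 g value (1.44 N) and the predictive gain becomes variable,
#' `alpha = (dGF - beta) / (mass * delta_g * g0)`.
#'
#' @param dGF grip-force switching index, N (vectorized).
#' @param mass object mass, kg.
#' @param delta_g gravity step, multiples of standard gravity; must be
#'   nonzero (vectorized).
#' @param beta fixed safety margin, N.
#' @param g0 standard gravity, m/s^2.
#' @return A tibble with the same columns as [decompose_fixed_gain()]
#'   (`predictive_term = dGF - beta`).
#' @examples
#' decompose_fixed_margin(2.29, 0.13, 0.5)  # alpha 1.33
#' @export
decompose_fixed_margin <- function(dGF, mass = 0.13, delta_g = 0.5,
                                   beta = 1.44, g0 = 9.81) {
  if (mass <= 0) gl_stop("mass must be > 0", "griplift_error_domain")
  if (any(delta_g == 0))
    gl_stop("delta_g = 0: gain undefined under a fixed margin",
            "griplift_error_undefined_gain")
  pred <- dGF - beta
  tibble::tibble(
    mode = "fixed_margin", alpha = pred / (mass * delta_g * g0), beta = beta,
    predictive_term = pred, dGF = dGF, delta_g = delta_g,
    mass = mass, g0 = g0
  )
}

#' Transition-level summary with both prediction decompositions
#'
#' Averages the per-participant switching indices for each transition (in
#' chronological order) and applies both the fixed-gain and the
#' fixed-margin decomposition to the mean `dGF`, mirroring the worked
#' switching-analysis table: columns `dLF`, `dGF`, the fixed-gain
#' predictive term and margin (`fg_pred`, `fg_beta`), and the fixed-margin
#' predictive term, margin and gain (`fm_pred`, `fm_beta`, `fm_alpha`).
#'
#' @param switches tibble from [switching_indices()].
#' @param mass object mass, kg.
#' @param alpha fixed gain for the fixed-gain decomposition.
#' @param beta fixed margin (N) for the fixed-margin decomposition.
#' @param g0 standard gravity, m/s^2.
#' @return One row per transition.
#' @export
build_table2 <- function(switches, mass = 0.13, alpha = 1.5, beta = 1.44,
                         g0 = 9.81) {
  if (!nrow(switches)) gl_stop("empty switches table", "griplift_error_domain")
  agg <- switches |>
    dplyr::group_by(.data$transition) |>
    dplyr::summarise(
      order = min(match(.data$transition, unique(switches$transition))),
      g_prev = .data$g_prev[1], g_next = .data$g_next[1],
      delta_g = .data$delta_g[1], phase = .data$phase[1],
      dLF = mean(.data$dLF), dGF = mean(.data$dGF), n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$order) |>
    dplyr::select(-"order")
  fg <- decompose_fixed_gain(agg$dGF, mass, agg$delta_g, alpha, g0)
  fm <- decompose_fixed_margin(agg$dGF, mass, agg$delta_g, beta, g0)
  dplyr::bind_cols(
    agg,
    tibble::tibble(fg_pred = fg$predictive_term, fg_beta = fg$beta,
                   fm_pred = fm$predictive_term, fm_beta = fm$beta,
                   fm_alpha = fm$alpha)
  )
}

#' Mean switching index within a phase
#'
#' Mean and SEM of the grip-force switching index over all participant-level
#' records of one phase, with a one-sample t test against zero.
#'
#' @param switches tibble from [switching_indices()].
#' @param phase `"ascending"` or `"descending"`.
#' @return List with `mean`, `sem` (NA when n = 1), `n`, `t`, `p`.
#' @export
mean_switch_by_phase <- function(switches, phase = c("ascending", "descending")) {
  phase <- match.arg(phase)
  x <- switches$dGF[switches$phase == phase]
  if (!length(x))
    gl_stop(paste("no switching records in phase", phase),
            "griplift_error_insufficient_data")
  n <- length(x)
  if (n >= 2 && sd(x) > 0) {
    tt <- t.test(x, mu = 0)
    list(mean = mean(x), sem = sd(x) / sqrt(n), n = n,
         t = unname(tt$statistic), p = tt$p.value)
  } else {
    list(mean = mean(x), sem = NA_real_, n = n, t = NA_real_, p = NA_real_)
  }
}

#' Least-squares fit of the switching model
#'
#' Ordinary least squares of the grip-force switching index on the
#' load-force switching index (`dGF = alpha * dLF + beta`, the linear
#' grip/load coupling form) or on the expected weight step
#' (`dGF = alpha * mass * delta_g * g0 + beta`).
#'
#' @param switches tibble from [switching_indices()] (participant-level
#'   rows or transition means).
#' @param predictor `"load"` regresses on `dLF`; `"gravity"` on
#'   `mass * delta_g * g0`.
#' @param mass object mass, kg (used by the gravity predictor).
#' @param g0 standard gravity, m/s^2.
#' @return List with `alpha` (slope), `beta` (intercept, N), `r`, `n`.
#' @export
fit_switch_model <- function(switches, predictor = c("load", "gravity"),
                             mass = 0.13, g0 = 9.81) {
  predictor <- match.arg(predictor)
  if (nrow(switches) < 3)
    gl_stop("need at least 3 switching records to fit the model",
            "griplift_error_insufficient_data")
  x <- if (predictor == "load") switches$dLF else
    mass * switches$delta_g * g0
  fit <- lm(switches$dGF ~ x)
  list(alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
       r = cor(x, switches$dGF), n = nrow(switches), predictor = predictor)
}

#' First-trial peak regression
#'
#' Ordinary least squares of first-trial grip-force peaks on first-trial
#' load-force peaks over the per-phase participant means (one point per
#' gravity environment), quantifying how well grip force is scaled to load
#' from the very first lift in each environment.
#'
#' @param metrics session metrics table from [analyze_session()].
#' @param phase_filter `"pooled"` (all phases), `"ascending"` or
#'   `"descending"`.
#' @return List with `slope`, `intercept`, `r`, `p`, `n_points` and the
#'   `points` tibble (per-environment means).
#' @export
trial1_peak_regression <- function(metrics,
                                   phase_filter = c("pooled", "ascending",
                                                    "descending")) {
  phase_filter <- match.arg(phase_filter)
  m1 <- metrics[metrics$trial_index == 1L, ]
  if (phase_filter != "pooled") m1 <- m1[m1$phase == phase_filter, ]
  pts <- m1 |>
    dplyr::group_by(.data$phase_occurrence) |>
    dplyr::summarise(g_level = .data$g_level[1],
                     LFmax = mean(.data$LFmax), GFmax = mean(.data$GFmax),
                     .groups = "drop")
  if (nrow(pts) < 3)
    gl_stop(sprintf("need >= 3 environment points, got %d", nrow(pts)),
            "griplift_error_insufficient_data")
  fit <- lm(GFmax ~ LFmax, data = pts)
  ct <- cor.test(pts$LFmax, pts$GFmax)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n_points = nrow(pts),
       points = pts)
}

#' Descriptive summary per factor cell
#'
#' Mean and SEM of every numeric metric per cell of the requested factors:
#' `GRAVITY` (the stable phases in chronological order, labelled by their
#' g-level), `TRIAL` (trial index 1-4) and `PHASE` (ascending vs
#' descending). When `PHASE` is included, the single highest-g phase is
#' excluded (it belongs to both ascent terminus and descent origin and has
#' no within-phase counterpart).
#'
#' @param metrics session metrics table from [analyze_session()].
#' @param factors character subset of `c("GRAVITY", "TRIAL", "PHASE")`.
#' @return A tibble with one row per factor cell; for each metric `<m>`,
#'   columns `<m>_mean` and `<m>_sem` (SEM is NA in single-observation
#'   cells).
#' @export
condition_summary <- function(metrics, factors = "GRAVITY") {
  if (!nrow(metrics)) gl_stop("empty metrics table", "griplift_error_domain")
  known <- c(GRAVITY = "phase_occurrence", TRIAL = "trial_index",
             PHASE = "phase")
  bad <- setdiff(factors, names(known))
  if (length(bad))
    gl_config_error("factors", paste("unknown factor:",
                                     paste(bad, collapse = ", ")))
  m <- metrics
  if ("PHASE" %in% factors) {
    g_top <- max(m$g_level)
    m <- m[m$g_level < g_top, ]
  }
  group_cols <- unname(known[factors])
  metric_cols <- setdiff(
    names(m)[vapply(m, is.numeric, TRUE)],
    c("phase_occurrence", "trial_index", "g_level", "g_realized", "mass")
  )
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  out <- m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      g_level = .data$g_level[1],
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_cols),
                    list(mean = mean, sem = sem),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
  if ("phase_occurrence" %in% group_cols)
    out <- dplyr::arrange(out, .data$phase_occurrence)
  if (!"phase_occurrence" %in% group_cols) out$g_level <- NULL
  out
}
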