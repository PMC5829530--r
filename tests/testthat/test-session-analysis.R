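# Session aggregation: switching indices, prediction decompositions,
# first-trial regression and condition summaries.

fake_metrics <- function(gf_peaks, lf_peaks = NULL, participants = "P01",
                         g_levels = c(1, 1.5, 2, 2.5, 2, 1.5, 1)) {
  # build a minimal metrics table: trials 1..4 per phase per participant
  rows <- list()
  for (pid in participants) {
    for (k in seq_along(g_levels)) {
      for (ti in 1:4) {
        gf <- gf_peaks[[pid]][[k]][ti]
        lf <- if (is.null(lf_peaks)) 0.13 * g_levels[k] * 9.81 * 1.12 else
          lf_peaks[[pid]][[k]][ti]
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant = pid, phase_occurrence = k,
          phase = if (k <= which.max(g_levels)) "ascending" else "descending",
          g_level = g_levels[k], trial_index = ti,
          GFmax = gf, LFmax = lf)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("switching index subtracts last-trial from first-trial peaks", {
  peaks <- list(P01 = list(c(5.0, 4, 4, 3.0),    # 1 g: trial1 5.0, trial4 3.0
                           c(5.39, 5, 5, 4.8)))  # 1.5 g: trial1 5.39
  mt <- fake_metrics(peaks, g_levels = c(1, 1.5))
  sw <- switching_indices(mt)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$dGF, 5.39 - 3.0)    # 2.39 N
  expect_equal(sw$delta_g, 0.5)
  expect_equal(sw$phase, "ascending")
  expect_equal(sw$transition, "1-1.5")

  # identical peaks across the transition: a zero switch
  peaks0 <- list(P01 = list(rep(3, 4), rep(3, 4)))
  expect_equal(switching_indices(fake_metrics(peaks0,
                                              g_levels = c(1, 1.5)))$dGF, 0)
})

test_that("transitions come out chronologically with phase labels", {
  g <- c(1, 1.5, 2, 2.5, 2, 1.5, 1)
  peaks <- list(P01 = lapply(seq_along(g), function(k) rep(2 + k, 4)),
                P02 = lapply(seq_along(g), function(k) rep(3 + k, 4)))
  mt <- fake_metrics(peaks, participants = c("P01", "P02"), g_levels = g)
  sw <- switching_indices(mt)
  expect_equal(nrow(sw), 12)  # 6 transitions x 2 participants
  expect_equal(unique(sw$transition),
               c("1-1.5", "1.5-2", "2-2.5", "2.5-2", "2-1.5", "1.5-1"))
  expect_equal(sw$phase[sw$delta_g > 0][1], "ascending")
  expect_true(all(sw$phase[sw$delta_g < 0] == "descending"))

  # a missing trial drops that transition only, with a message
  mt2 <- mt[!(mt$participant == "P01" & mt$phase_occurrence == 2 &
                mt$trial_index == 1), ]
  expect_message(sw2 <- switching_indices(mt2), "skipping")
  expect_equal(nrow(sw2), 11)

  # single phase: nothing to index
  expect_warning(sw1 <- switching_indices(mt[mt$phase_occurrence == 1, ]),
                 "fewer than two phases")
  expect_equal(nrow(sw1), 0)
})

test_that("decomposition identity and mode duality hold exactly", {
  set.seed(12)
  dGF <- rnorm(50, 1, 1.5)
  dg <- sample(c(-0.5, 0.5), 50, replace = TRUE)
  fg <- decompose_fixed_gain(dGF, 0.13, dg)
  fm <- decompose_fixed_margin(dGF, 0.13, dg)
  expect_true(all(abs(fg$predictive_term + fg$beta - dGF) < 1e-9))
  expect_true(all(abs(fm$predictive_term + fm$beta - dGF) < 1e-9))

  # feeding the fixed-gain margin back as the fixed margin returns the gain
  rt <- decompose_fixed_margin(dGF[1], 0.13, dg[1], beta = fg$beta[1])
  expect_equal(rt$alpha, 1.5, tolerance = 1e-12)

  # no gravity step: margin absorbs everything / gain is undefined
  expect_equal(decompose_fixed_gain(1.2, 0.13, 0)$beta, 1.2)
  expect_error(decompose_fixed_margin(1.44, 0.13, 0),
               class = "griplift_error_undefined_gain")
  # a switch equal to the margin implies a zero predictive term
  z <- decompose_fixed_margin(1.44, 0.13, 0.5)
  expect_equal(z$predictive_term, 0)
  expect_equal(z$alpha, 0)
})

test_that("phase means of the switching index", {
  sw <- tibble::tibble(dGF = c(2.39, 2.29, 2.30),
                       phase = "ascending")
  out <- mean_switch_by_phase(sw, "ascending")
  expect_equal(round(out$mean, 2), 2.33)
  expect_equal(out$n, 3)
  expect_gt(out$t, 0)

  sym <- tibble::tibble(dGF = c(-1, 1, -2, 2), phase = "descending")
  expect_equal(mean_switch_by_phase(sym, "descending")$mean, 0)

  one <- tibble::tibble(dGF = 1.5, phase = "ascending")
  res <- mean_switch_by_phase(one, "ascending")
  expect_identical(res$sem, NA_real_)
  expect_equal(res$n, 1)
  expect_error(mean_switch_by_phase(one, "descending"),
               class = "griplift_error_insufficient_data")
})

test_that("first-trial peak regression on per-environment means", {
  # perfectly collinear points recover slope/intercept exactly
  g <- c(1, 1.5, 2, 2.5)
  lf1 <- 0.13 * 9.81 * g * 1.12
  peaks <- list(P01 = lapply(seq_along(g), function(k)
    rep(1.6 * lf1[k] + 2.2, 4)))
  lfp <- list(P01 = lapply(seq_along(g), function(k) rep(lf1[k], 4)))
  mt <- fake_metrics(peaks, lfp, g_levels = g)
  fit <- trial1_peak_regression(mt, "pooled")
  expect_equal(fit$slope, 1.6, tolerance = 1e-9)
  expect_equal(fit$intercept, 2.2, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 4)

  # anti-correlated constructed points give a negative r
  peaks_neg <- list(P01 = lapply(seq_along(g), function(k)
    rep(10 - 2 * lf1[k], 4)))
  expect_lt(trial1_peak_regression(fake_metrics(peaks_neg, lfp,
                                                g_levels = g))$r, 0)

  expect_error(trial1_peak_regression(fake_metrics(
    list(P01 = list(rep(1, 4), rep(2, 4))), g_levels = c(1, 1.5))),
    class = "griplift_error_insufficient_data")
})

test_that("synthetic sessions recover the generator's gain and margins", {
  cfg <- noiseless_config()
  ses <- simulate_session(gravity_schedule(), 2, cfg, seed = 8)
  keep <- vapply(ses, function(el) el$context$trial_index %in% c(1L, 4L), TRUE)
  mt <- analyze_session(ses[keep])
  sw <- switching_indices(mt)
  expect_equal(nrow(sw), 12)

  fit <- fit_switch_model(sw, predictor = "load")
  expect_equal(fit$alpha, 1.5, tolerance = 0.02)           # grip gain
  expect_equal(fit$beta, 1.44, tolerance = 0.02 * 1.44)    # trial-1 margin

  # load-force switches are symmetric between phases: exactly so in the
  # generator's ground truth, and to sample resolution through the pipeline
  truth_lfmax <- vapply(ses, function(el) el$truth$LFmax, numeric(1))
  occ <- vapply(ses, function(el) el$context$phase_occurrence, integer(1))
  tri <- vapply(ses, function(el) el$context$trial_index, integer(1))
  pid <- vapply(ses, function(el) el$context$participant, character(1))
  tru_dLF <- function(p, o) {
    truth_lfmax[pid == p & occ == o + 1 & tri == 1] -
      truth_lfmax[pid == p & occ == o & tri == 4]
  }
  expect_equal(abs(tru_dLF("P01", 1)), abs(tru_dLF("P01", 5)),
               tolerance = 1e-12)
  up <- mean(abs(sw$dLF[sw$phase == "ascending"]))
  down <- mean(abs(sw$dLF[sw$phase == "descending"]))
  expect_equal(up, down, tolerance = 1e-3)

  # first-trial regression slope recovers the grip gain
  mt_all <- analyze_session(ses)
  t1 <- trial1_peak_regression(mt_all, "pooled")
  expect_equal(t1$slope, 1.5, tolerance = 0.02)
})

test_that("condition summaries: cells, exact noiseless means, guards", {
  ses <- simulate_session(gravity_schedule(), 1, noiseless_config(), seed = 2)
  mt <- analyze_session(ses)

  byg <- condition_summary(mt, "GRAVITY")
  expect_equal(nrow(byg), 7)
  expect_equal(byg$g_level, c(1, 1.5, 2, 2.5, 2, 1.5, 1))  # chronological
  expect_equal(byg$lf_plateau_mean, 0.13 * 9.81 * byg$g_level,
               tolerance = 1e-6)

  gxt <- condition_summary(mt, c("GRAVITY", "TRIAL"))
  expect_equal(nrow(gxt), 7 * 4)
  # single-observation cells have no SEM
  expect_true(all(is.na(gxt$GFmax_sem)))

  byp <- condition_summary(mt, "PHASE")
  expect_equal(sort(byp$phase), c("ascending", "descending"))
  # the single 2.5 g phase is excluded from phase contrasts
  expect_equal(sum(byp$n), nrow(mt[mt$g_level < 2.5, ]))

  expect_error(condition_summary(mt, "WEIGHT"),
               class = "griplift_error_config")
})

test_that("mean ascending switch matches the generator arithmetic", {
  # dGF should approximate gain * m * dg * g0 + first-trial margin
  cfg <- sim_config()  # gain 1.5, first-trial margin 1.44 N
  ses <- simulate_session(gravity_schedule(), 4, cfg, seed = 13)
  keep <- vapply(ses, function(el) el$context$trial_index %in% c(1L, 4L), TRUE)
  mt <- analyze_session(ses[keep])
  sw <- switching_indices(mt)
  asc <- mean_switch_by_phase(sw, "ascending")
  expected <- 1.5 * 0.13 * 0.5 * 9.81 + 1.44
  expect_equal(asc$mean, expected, tolerance = 0.10 * expected)
})
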