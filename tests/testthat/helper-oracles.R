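# Independent brute-force oracles and shared fixtures.
# The oracles deliberately avoid the package's rle/vectorized code paths.

# Exhaustive scan: first index i (at/after the search start) whose next
# nmin samples are all strictly above the threshold.
oracle_onset <- function(rate, fs, threshold = 0.4, min_duration = 0.125,
                         search_start = 0) {
  nmin <- ceiling(min_duration * fs)
  i0 <- floor(search_start * fs) + 1
  n <- length(rate)
  for (i in i0:n) {
    if (i + nmin - 1 > n) break
    ok <- TRUE
    for (j in i:(i + nmin - 1)) {
      if (!(rate[j] > threshold)) { ok <- FALSE; break }
    }
    if (ok) return((i - 1) / fs)
  }
  NA_real_
}

oracle_trial_end <- function(lf_rate, fs, threshold = -2,
                             min_duration = 0.125, backoff = 0.250) {
  nmin <- ceiling(min_duration * fs)
  n <- length(lf_rate)
  for (i in 1:n) {
    if (i + nmin - 1 > n) break
    ok <- TRUE
    for (j in i:(i + nmin - 1)) {
      if (!(lf_rate[j] < threshold)) { ok <- FALSE; break }
    }
    if (ok) return((i - 1) / fs - backoff)
  }
  NA_real_
}

# Hand-rolled Pearson correlation and exhaustive lag loop.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

oracle_xcorr <- function(gf_rate, lf_rate, t, tLFo, tLFw, max_lag = 0.150) {
  fs <- 1 / stats::median(diff(t))
  win <- which(t >= tLFo & t <= tLFw)
  K <- floor(max_lag * fs + 1e-9)
  best_r <- -Inf; best_k <- NA_integer_
  for (k in -K:K) {
    src <- win - k
    if (src[1] < 1 || src[length(src)] > length(gf_rate)) next
    g <- gf_rate[src]
    if (stats::var(g) < 1e-12) next
    r <- oracle_pearson(lf_rate[win], g)
    better <- r > best_r + 1e-15 ||
      (abs(r - best_r) <= 1e-15 &&
         (abs(k) < abs(best_k) || (abs(k) == abs(best_k) && k < best_k)))
    if (better) { best_r <- r; best_k <- k }
  }
  list(r_max = best_r, lag_samples = best_k)
}

# Random piecewise-constant rate signal for the onset oracle checks.
random_rate_signal <- function(n_segments = 8, fs = 120) {
  lens <- sample(3:40, n_segments, replace = TRUE)
  vals <- stats::runif(n_segments, -1, 3)
  rep(vals, lens)
}

# Random smooth signal pair (summed sinusoids) for the xcorr oracle checks.
random_smooth_pair <- function(n = 120, fs = 120) {
  t <- (seq_len(n) - 1) / fs
  mk <- function() {
    f <- stats::runif(3, 0.5, 8)
    a <- stats::runif(3, 0.2, 1.5)
    ph <- stats::runif(3, 0, 2 * pi)
    a[1] * sin(2 * pi * f[1] * t + ph[1]) +
      a[2] * sin(2 * pi * f[2] * t + ph[2]) +
      a[3] * sin(2 * pi * f[3] * t + ph[3])
  }
  list(x = mk(), y = mk(), t = t)
}

noiseless_config <- function(...) {
  sim_config(noise_sd = 0, az_noise_sd = 0, g_jitter_sd = 0, ...)
}

make_context <- function(g_level = 1.5, trial_index = 1L,
                         phase = "ascending", phase_occurrence = 2L,
                         participant = "P01", mass = 0.13, fs = 120) {
  list(participant = participant, g_level = g_level,
       trial_index = as.integer(trial_index), phase = phase,
       phase_occurrence = as.integer(phase_occurrence), mass = mass, fs = fs)
}

event_names <- c("tGFo", "tLFo", "tLFw", "tGFmax", "tLFmax", "tEnd")

event_diff_samples <- function(metrics, truth, fs = 120) {
  vapply(event_names,
         function(nm) (metrics$events[[nm]] - truth[[nm]]) * fs,
         numeric(1))
}
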