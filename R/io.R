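# File formats: per-trial CSV + JSON sidecar, ground-truth JSON, session
# manifest TSV, metrics/switches/summary TSV writers and readers.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write one trial to disk
#'
#' Writes `<stem>.csv` with a unit comment line and header
#' `t,gf,lf_stand,az` (seconds, N, N, m/s^2), a JSON sidecar
#' `<stem>.json` with the trial context, and optionally
#' `<stem>_truth.json` with the generator ground truth. Numeric values are
#' written with 17 significant digits so a read-back is bit-identical.
#'
#' @param recording a `trial_recording`.
#' @param context a `trial_context` (or compatible named list).
#' @param stem path stem (no extension).
#' @param truth optional ground-truth list to write alongside.
#' @return The CSV path, invisibly.
#' @export
write_trial <- function(recording, context, stem, truth = NULL) {
  validate_recording(recording)
  csv <- paste0(stem, ".csv")
  con <- file(csv, "w")
  writeLines(c("# units: t=s, gf=N, lf_stand=N, az=m/s2",
               "t,gf,lf_stand,az"), con)
  writeLines(paste(fmt_num(recording$t), fmt_num(recording$gf),
                   fmt_num(recording$lf_stand), fmt_num(recording$az),
                   sep = ","), con)
  close(con)
  side <- context[c("participant", "g_level", "g_realized", "trial_index",
                    "phase", "phase_occurrence", "mass", "fs", "seed")]
  side <- side[!vapply(side, is.null, TRUE)]
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read one trial from disk
#'
#' Reads a `<stem>.csv` / `<stem>.json` pair written by [write_trial()],
#' validating the header columns, the uniform time grid and finiteness of
#' every sample, and the required sidecar fields.
#'
#' @param path path to the trial CSV (sidecar is found by replacing the
#'   extension).
#' @return List with `recording` (`trial_recording`) and `context`
#'   (`trial_context`).
#' @export
read_trial <- function(path) {
  if (!file.exists(path))
    gl_stop(paste("trial file not found:", path), "griplift_error_format")
  df <- read.csv(path, comment.char = "#")
  need <- c("t", "gf", "lf_stand", "az")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gl_stop(paste0("trial CSV '", basename(path), "' lacks column(s): ",
                   paste(miss, collapse = ", ")), "griplift_error_format")
  side_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(side_path))
    gl_stop(paste("sidecar not found:", side_path), "griplift_error_format")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  req <- c("participant", "g_level", "trial_index", "phase", "mass", "fs")
  miss <- setdiff(req, names(side))
  if (length(miss))
    gl_stop(paste0("sidecar '", basename(side_path), "' lacks field(s): ",
                   paste(miss, collapse = ", ")), "griplift_error_format")

  rec <- list(t = df$t, gf = df$gf, lf_stand = df$lf_stand, az = df$az,
              fs = side$fs)
  class(rec) <- "trial_recording"
  validate_recording(rec)
  ctx <- as.list(side)
  ctx$trial_index <- as.integer(ctx$trial_index)
  if (!is.null(ctx$phase_occurrence))
    ctx$phase_occurrence <- as.integer(ctx$phase_occurrence)
  class(ctx) <- "trial_context"
  list(recording = rec, context = ctx)
}

#' Write a simulated session to a directory
#'
#' One CSV + sidecar (+ ground-truth JSON) per trial, plus a
#' `manifest.tsv` listing every trial file with its context.
#'
#' @param session a `grip_session` from [simulate_session()].
#' @param dir output directory (created if missing).
#' @param write_truth also write per-trial ground-truth JSON files.
#' @return Path to the manifest, invisibly.
#' @export
write_session <- function(session, dir, write_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(session, function(el) {
    ctx <- el$context
    stem <- file.path(dir, sprintf("%s_ph%d_t%d", ctx$participant,
                                   ctx$phase_occurrence, ctx$trial_index))
    write_trial(el$recording, ctx, stem,
                truth = if (write_truth) el$truth else NULL)
    data.frame(file = paste0(basename(stem), ".csv"),
               participant = ctx$participant, g_level = ctx$g_level,
               trial_index = ctx$trial_index, phase = ctx$phase,
               phase_occurrence = ctx$phase_occurrence, mass = ctx$mass,
               fs = ctx$fs, seed = ctx$seed)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a session manifest
#'
#' @param path path to a `manifest.tsv` written by [write_session()].
#' @param check_files verify that every referenced trial file exists.
#' @return A tibble of manifest rows (with absolute `path` column).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    gl_stop(paste("manifest not found:", path), "griplift_error_format")
  mf <- read.csv(path, sep = "\t")
  need <- c("file", "participant", "g_level", "trial_index", "phase",
            "phase_occurrence", "mass", "fs")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    gl_stop(paste("manifest lacks column(s):", paste(miss, collapse = ", ")),
            "griplift_error_format")
  key <- paste(mf$participant, mf$phase_occurrence, mf$trial_index)
  if (anyDuplicated(key))
    gl_stop("manifest has duplicate (participant, phase, trial) entries",
            "griplift_error_format")
  mf$path <- file.path(dirname(path), mf$file)
  if (check_files) {
    missing <- !file.exists(mf$path)
    if (any(missing))
      gl_stop(paste("manifest references missing file(s):",
                    paste(mf$file[missing], collapse = ", ")),
              "griplift_error_format")
  }
  tibble::as_tibble(mf)
}

# Write the exact parameter set used by a run, for reproducibility.
write_run_log <- function(dir, params) {
  jsonlite::write_json(params, file.path(dir, "run_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
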