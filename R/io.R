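# Plain-text readers and writers for the package's file dialects.
#
# All times are serialized as seconds relative to lights-off; epoch indices
# are 0-based with half-open intervals; clock times are "HH:MM" labels in
# design tables. Signals travel as columnar CSV with a small '#'-prefixed
# metadata header (sampling_rate, lights_off, lights_on) — the simulator's
# dialect.

#' Write an EEG record to the columnar CSV signal dialect
#'
#' @param eeg an [eeg_record()].
#' @param path output file.
#' @export
write_signals <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate: %.10g", eeg$sampling_rate),
               sprintf("# lights_off: %.10g", eeg$lights_off),
               sprintf("# lights_on: %.10g", eeg$lights_on),
               "# units: uV"), con)
  df <- as.data.frame(eeg$channels)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
}

#' Read an EEG record from the columnar CSV signal dialect
#'
#' @param path signal CSV written by [write_signals()].
#' @return an [eeg_record()].
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop("no such signal file: ", path)
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", hit[1]))
  }
  fs <- get_meta("sampling_rate")
  if (is.null(fs)) stop("signal file lacks a sampling_rate header: ", path)
  loff <- get_meta("lights_off")
  if (is.null(loff)) stop("signal file lacks a lights_off annotation: ", path)
  lon <- get_meta("lights_on")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!nrow(df)) stop("signal file has no samples: ", path)
  eeg_record(as.list(df), sampling_rate = fs, lights_off = loff, lights_on = lon)
}

#' Read and validate an annotation table
#'
#' @param path CSV file.
#' @param kind one of "microsleep" (onset_s, duration_s), "hypnogram"
#'   (epoch_index, stage), "hypnodensity" (epoch_index, p_W..p_REM),
#'   "kss" (participant, clock_time, score), "design" (participant, cohort,
#'   treatment, day, session_time, isSiesta).
#' @return the validated data.frame (or stage character vector for
#'   hypnograms). Row-level violations are collected and reported together.
#' @export
read_annotations <- function(path, kind = c("microsleep", "hypnogram",
                                            "hypnodensity", "kss", "design")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such annotation file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  errs <- character(0)
  need <- switch(kind,
    microsleep = c("onset_s", "duration_s"),
    hypnogram = c("epoch_index", "stage"),
    hypnodensity = c("epoch_index", "p_W", "p_N1", "p_N2", "p_N3", "p_REM"),
    kss = c("participant", "clock_time", "score"),
    design = c("participant", "cohort", "treatment", "day", "session_time", "isSiesta"))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(kind, " file lacks columns: ", paste(miss, collapse = ", "))
  if (kind == "microsleep" && nrow(df)) {
    bad <- which(df$duration_s < 3 | df$duration_s >= 15)
    if (length(bad))
      errs <- c(errs, sprintf("row %d: duration %.2f s outside [3, 15)", bad, df$duration_s[bad]))
    neg <- which(df$onset_s < 0)
    if (length(neg)) errs <- c(errs, sprintf("row %d: negative onset", neg))
  }
  if (kind == "hypnogram") {
    bad <- which(!df$stage %in% c("W", "N1", "N2", "N3", "REM"))
    if (length(bad))
      errs <- c(errs, sprintf("row %d: invalid stage label '%s'", bad, df$stage[bad]))
  }
  if (kind == "hypnodensity" && nrow(df)) {
    p <- as.matrix(df[, c("p_W", "p_N1", "p_N2", "p_N3", "p_REM")])
    bad <- which(abs(rowSums(p) - 1) > 1e-3)
    if (length(bad))
      errs <- c(errs, sprintf("row %d: probabilities sum to %.4f", bad, rowSums(p)[bad]))
  }
  if (kind == "kss" && nrow(df)) {
    bad <- which(df$score < 1 | df$score > 9)
    if (length(bad)) errs <- c(errs, sprintf("row %d: KSS score %s outside [1, 9]", bad, df$score[bad]))
  }
  if (length(errs))
    stop("invalid ", kind, " file ", path, ":\n  ", paste(errs, collapse = "\n  "))
  if (kind == "hypnogram") df$stage[order(df$epoch_index)] else df
}

#' Write one simulated session's artifact files to a directory
#'
#' Writes hypnodensity, hypnogram and microsleep CSVs (and the signal CSV
#' when an EEG record is attached), using the dialects read back by
#' [read_annotations()] and [read_signals()].
#'
#' @param session a `session_record`.
#' @param dir output directory (created if needed).
#' @param stem filename stem.
#' @export
write_session <- function(session, dir, stem = "session") {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$hypnodensity,
                   file.path(dir, paste0(stem, "_hypnodensity.csv")), row.names = FALSE)
  utils::write.csv(data.frame(epoch_index = seq_along(session$hypnogram) - 1L,
                              stage = session$hypnogram),
                   file.path(dir, paste0(stem, "_hypnogram.csv")), row.names = FALSE)
  utils::write.csv(session$microsleeps,
                   file.path(dir, paste0(stem, "_microsleeps.csv")), row.names = FALSE)
  if (!is.null(session$eeg))
    write_signals(session$eeg, file.path(dir, paste0(stem, "_signals.csv")))
  invisible(dir)
}

#' Write the ground-truth ledger of a simulated study as JSON
#' @param study a `study_dataset`.
#' @param path output JSON file.
#' @export
write_ground_truth <- function(study, path) {
  stopifnot(inherits(study, "study_dataset"))
  jsonlite::write_json(study$ground_truth, path, digits = NA, dataframe = "rows")
  invisible(path)
}
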