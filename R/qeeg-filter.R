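# qEEG preprocessing: zero-phase band-pass + notch filtering and
# rule-based artifact rejection on 2-s analysis windows.

#' Filter configuration for qEEG preprocessing
#'
#' @param bandpass_lo,bandpass_hi band-pass edges in Hz (defaults 0.1 and
#'   55.0, the standard wake-EEG band).
#' @param notches numeric vector of notch center frequencies (Hz); each
#'   notch removes a 1-Hz-wide band. Notches are config-driven, never
#'   auto-applied (see [suggest_notches()]).
#' @param notch_bw notch bandwidth in Hz (default 1).
#' @return a `filter_config` object.
#' @export
filter_config <- function(bandpass_lo = 0.1, bandpass_hi = 55.0,
                          notches = numeric(0), notch_bw = 1) {
  if (!(bandpass_lo > 0 && bandpass_lo < bandpass_hi))
    stop("need 0 < bandpass_lo < bandpass_hi")
  if (length(notches) && any(notches <= bandpass_lo | notches >= bandpass_hi))
    stop("notch centers must lie inside the passband")
  structure(list(bandpass_lo = bandpass_lo, bandpass_hi = bandpass_hi,
                 notches = notches, notch_bw = notch_bw),
            class = "filter_config")
}

# Zero-phase frequency-domain filter: multiply the spectrum by a real,
# even gain function with raised-cosine transition bands. Zero-phase by
# construction and achieves arbitrary stop-band attenuation, which an IIR
# band-pass of practical order cannot at a 55->60 Hz transition.
fft_bandpass <- function(x, fs, lo, hi, notches = numeric(0), notch_bw = 1,
                         transition = 2) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                          # two-sided -> folded freq
  gain <- rep(1, n)
  # raised-cosine edges: full gain inside [lo, hi], zero beyond a transition
  ramp_up <- f < lo
  gain[ramp_up] <- 0.5 * (1 - cos(pi * pmax(0, f[ramp_up] - max(0, lo - transition)) /
                                    min(transition, lo)))
  ramp_dn <- f > hi
  gain[ramp_dn] <- 0.5 * (1 + cos(pi * pmin(transition, f[ramp_dn] - hi) / transition))
  gain[f > hi + transition] <- 0
  for (f0 in notches) {
    half <- notch_bw / 2
    gain[abs(f - f0) <= half] <- 0
  }
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Band-pass and notch filter an EEG record (zero-phase)
#'
#' Applies a zero-phase frequency-domain band-pass with raised-cosine
#' transition bands (2 Hz) and 1-Hz-wide notches at the configured centers.
#' The output has the same shape and timebase as the input.
#'
#' @param eeg an [eeg_record()].
#' @param cfg a [filter_config()].
#' @return the filtered [eeg_record()].
#' @export
preprocess_eeg <- function(eeg, cfg = filter_config()) {
  stopifnot(inherits(eeg, "eeg_record"), inherits(cfg, "filter_config"))
  nyq <- eeg$sampling_rate / 2
  if (cfg$bandpass_hi >= nyq) stop("bandpass_hi must be below the Nyquist frequency")
  n <- length(eeg$channels[[1]])
  if (n < eeg$sampling_rate) stop("channel too short to filter (< 1 s)")
  eeg$channels <- lapply(eeg$channels, function(x) {
    if (anyNA(x)) {
      # filter with gaps zero-filled, restore NA afterwards so the artifact
      # detector still sees the missing samples
      na <- !is.finite(x)
      x0 <- x; x0[na] <- 0
      y <- fft_bandpass(x0, eeg$sampling_rate, cfg$bandpass_lo, cfg$bandpass_hi,
                        cfg$notches, cfg$notch_bw)
      y[na] <- NA_real_
      y
    } else {
      fft_bandpass(x, eeg$sampling_rate, cfg$bandpass_lo, cfg$bandpass_hi,
                   cfg$notches, cfg$notch_bw)
    }
  })
  eeg
}

#' Flag candidate notch frequencies
#'
#' Scans the average spectrum for narrow peaks more than `threshold_db`
#' above the local median floor (e.g. line-interference harmonics). Purely
#' advisory: suggested frequencies are never applied automatically.
#'
#' @param eeg an [eeg_record()].
#' @param channel channel name (default: first channel).
#' @param threshold_db peak prominence threshold in dB (default 10).
#' @return numeric vector of candidate notch center frequencies (Hz).
#' @export
suggest_notches <- function(eeg, channel = names(eeg$channels)[1],
                            threshold_db = 10) {
  spec <- multitaper_spectrogram(eeg, channel)
  p <- 10 * log10(pmax(colMeans(spec$power), 1e-20))
  k <- 5  # +-2.5 Hz local window on the 0.5 Hz grid
  floor_db <- vapply(seq_along(p), function(i) {
    win <- p[max(1, i - k):min(length(p), i + k)]
    stats::median(win)
  }, numeric(1))
  spec$freqs[p - floor_db > threshold_db & spec$freqs > 1]
}

#' Rule-based artifact detection on 2-s windows
#'
#' A 2-s window is rejected iff any rule fires, with reasons assigned in
#' priority order:
#' \describe{
#'   \item{saturation}{>= 10 consecutive samples within one least-significant
#'     quantum of the record's minimum or maximum (rail-pinned signal).}
#'   \item{missing}{any non-finite sample, or a flat run of >= 0.5 s with
#'     zero sample-to-sample difference.}
#'   \item{slew}{any absolute sample-to-sample difference above `slew_max`
#'     (default 50 uV/sample at 256 Hz, scaled by 256/fs).}
#'   \item{artifact}{window peak-to-peak above `ptp_max` (default 500 uV).}
#' }
#' Saturation outranks the flat-run clause because a rail-pinned run is also
#' perfectly flat.
#'
#' @param eeg an [eeg_record()].
#' @param channel channel name.
#' @param slew_max,ptp_max thresholds in uV (slew at 256 Hz reference).
#' @return an `artifact_mask`: data.frame with `window` (0-based index),
#'   `rejected`, `reason` (NA when clean), plus attributes `window_len` (2 s)
#'   and `n_windows`.
#' @export
detect_artifacts <- function(eeg, channel = names(eeg$channels)[1],
                             slew_max = 50, ptp_max = 500) {
  stopifnot(inherits(eeg, "eeg_record"))
  x <- eeg$channels[[channel]]
  if (is.null(x)) stop("unknown channel: ", channel)
  fs <- eeg$sampling_rate
  wlen <- 2 * fs
  n_win <- floor(length(x) / wlen)
  if (n_win == 0) {
    out <- data.frame(window = integer(0), rejected = logical(0),
                      reason = character(0))
    attr(out, "window_len") <- 2; attr(out, "n_windows") <- 0L
    class(out) <- c("artifact_mask", "data.frame")
    return(out)
  }
  fin <- x[is.finite(x)]
  rng <- if (length(fin)) range(fin) else c(NA_real_, NA_real_)
  # least-significant quantum: smallest nonzero step in the record
  dx_all <- abs(diff(fin))
  quantum <- if (any(dx_all > 0)) min(dx_all[dx_all > 0]) else 1e-9
  slew_thr <- slew_max * 256 / fs
  flat_run_len <- ceiling(0.5 * fs)

  reason <- rep(NA_character_, n_win)
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1) * wlen + 1):(w * wlen)]
    d <- diff(seg)
    r <- NA_character_
    if (!anyNA(rng)) {
      at_rail <- is.finite(seg) &
        (abs(seg - rng[1]) <= quantum | abs(seg - rng[2]) <= quantum)
      if (max_run(at_rail) >= 10) r <- "saturation"
    }
    if (is.na(r)) {
      if (any(!is.finite(seg))) r <- "missing"
      else if (max_run(d == 0) >= flat_run_len - 1) r <- "missing"
    }
    if (is.na(r) && any(abs(d) > slew_thr, na.rm = TRUE)) r <- "slew"
    if (is.na(r)) {
      fseg <- seg[is.finite(seg)]
      if (length(fseg) && diff(range(fseg)) > ptp_max) r <- "artifact"
    }
    reason[w] <- r
  }
  out <- data.frame(window = seq_len(n_win) - 1L,
                    rejected = !is.na(reason), reason = reason)
  attr(out, "window_len") <- 2; attr(out, "n_windows") <- n_win
  class(out) <- c("artifact_mask", "data.frame")
  out
}

# longest run of TRUE in a logical vector (NA treated as FALSE)
max_run <- function(b) {
  b[is.na(b)] <- FALSE
  if (!any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}
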