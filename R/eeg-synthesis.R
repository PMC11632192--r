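# Surrogate EEG for simulated MWT sessions.
#
# Not an attempt at realistic EEG morphology: a pink-noise background plus an
# alpha (10 Hz) oscillator whose amplitude tracks wakefulness and a theta
# (6 Hz) oscillator tracking sleepiness, so the downstream theta/alpha chain
# has a known monotone relationship to the latent trajectory. During
# microsleep events theta is boosted and alpha suppressed (the alpha-to-theta
# shift that defines a microsleep).

#' Construct an EEG record
#'
#' @param channels named list of numeric sample vectors, microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param lights_off,lights_on seconds relative to the first sample.
#' @return an `eeg_record` object.
#' @export
eeg_record <- function(channels, sampling_rate, lights_off = 0,
                       lights_on = NULL) {
  if (!length(channels) || is.null(names(channels)))
    stop("channels must be a named list")
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1) stop("all channels must have the same length")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  dur <- n / sampling_rate
  if (is.null(lights_on)) lights_on <- dur
  if (!(lights_off < lights_on && lights_on <= dur + 1e-9))
    stop("need lights_off < lights_on <= record duration")
  structure(list(channels = channels, sampling_rate = sampling_rate,
                 lights_off = lights_off, lights_on = lights_on),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<eeg_record: %d channel(s) [%s], %g Hz, %.1f s>\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$sampling_rate, n / x$sampling_rate))
  invisible(x)
}

# 1/f ("pink") noise via spectral shaping of white noise; deterministic under
# the caller's RNG state.
pink_noise <- function(n, rms = 1) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                      # avoid dividing DC by 0
  f <- pmin(f, n - f + 1)                        # mirror for negative freqs
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Synthesize a surrogate EEG record for a simulated session
#'
#' One occipital-like channel ("O2") at `cfg$sampling_rate`:
#' pink background noise, a 10 Hz alpha oscillation with amplitude
#' proportional to wakefulness `1 - S(t)`, and a 6 Hz theta oscillation with
#' amplitude proportional to sleepiness `S(t)` (piecewise constant per fine
#' epoch). During microsleep events theta amplitude is tripled and alpha
#' suppressed to 20%. Amplitudes in microvolts; bit-reproducible under the
#' session seed.
#'
#' @param session a `session_record` from [simulate_session()].
#' @param cfg the session's [sim_session_config()].
#' @param alpha_amp,theta_amp peak amplitudes (uV) at full wakefulness /
#'   full sleepiness.
#' @param noise_rms pink-noise RMS amplitude (uV).
#' @return an [eeg_record()] with a single channel `O2`.
#' @export
synthesize_eeg <- function(session, cfg, alpha_amp = 30, theta_amp = 30,
                           noise_rms = 4) {
  stopifnot(inherits(session, "session_record"))
  fs <- cfg$sampling_rate
  if (fs < 128) stop("sampling_rate must be >= 128 Hz for 55 Hz content")
  s_fine <- session$sleepiness$values
  n <- length(s_fine) * cfg$epoch_len_fine * fs
  tt <- (seq_len(n) - 1) / fs                     # seconds from lights-off
  fine_idx <- pmin(length(s_fine), floor(tt / cfg$epoch_len_fine) + 1L)
  s_t <- s_fine[fine_idx]

  a_gain <- (1 - s_t)
  t_gain <- s_t
  if (nrow(session$microsleeps)) {
    for (i in seq_len(nrow(session$microsleeps))) {
      on <- session$microsleeps$onset_s[i]
      off <- on + session$microsleeps$duration_s[i]
      in_ev <- tt >= on & tt < off
      t_gain[in_ev] <- pmin(1, 3 * t_gain[in_ev])
      a_gain[in_ev] <- 0.2 * a_gain[in_ev]
    }
  }
  x <- with_seed(cfg$seed + 2L, {
    ph <- stats::runif(2, 0, 2 * pi)
    pink_noise(n, rms = noise_rms) +
      alpha_amp * a_gain * sin(2 * pi * 10 * tt + ph[1]) +
      theta_amp * t_gain * sin(2 * pi * 6 * tt + ph[2])
  })
  eeg_record(list(O2 = x), sampling_rate = fs,
             lights_off = 0, lights_on = n / fs)
}
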