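# Multitaper spectral estimation and theta/alpha band ratios.
#
# Spectra are computed on non-overlapping 2-s windows (the minimal window
# giving the 0.5 Hz grid), with DPSS tapers at time-bandwidth NW = 2 and
# K = 3 tapers, eigenvalue-weighted. Tapers are computed from the standard
# symmetric tridiagonal formulation and cached per (N, NW, K).

# Discrete prolate spheroidal sequences via the tridiagonal eigenproblem;
# concentration eigenvalues from the Dirichlet-kernel quadratic form.
dpss_tapers <- function(n, nw = 2, k = 3) {
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  eig <- eigen(A, symmetric = TRUE)
  tap <- eig$vectors[, seq_len(k), drop = FALSE]
  # unit energy; polarity is irrelevant for power estimates
  for (j in seq_len(k)) tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
  # concentration in [-W, W]: lambda_j = h' S h with S_ij = sin(2 pi W (i-j)) / (pi (i-j))
  d <- outer(i, i, "-")
  S <- sin(2 * pi * w * d) / (pi * d)
  S[d == 0] <- 2 * w
  lambda <- vapply(seq_len(k), function(j) drop(t(tap[, j]) %*% S %*% tap[, j]),
                   numeric(1))
  list(tapers = tap, eigenvalues = pmin(1, pmax(0, lambda)))
}

.dpss_cache <- new.env(parent = emptyenv())

cached_dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.dpss_cache[[key]])) .dpss_cache[[key]] <- dpss_tapers(n, nw, k)
  .dpss_cache[[key]]
}

#' Multitaper spectrogram of one EEG channel
#'
#' Power spectra on non-overlapping 2-s windows stepped every 2 s, DPSS
#' tapers with time-bandwidth NW = 2 (3 tapers), eigenvalue-weighted average,
#' one-sided power spectral density in uV^2/Hz on a 0 to Nyquist grid at
#' exactly 0.5 Hz spacing.
#'
#' @param eeg an [eeg_record()].
#' @param channel channel name.
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default 3, i.e. 2*NW - 1).
#' @return a `spectrogram`: list with `times` (window centers, seconds
#'   relative to lights-off), `freqs` (Hz), and `power` (windows x freqs).
#' @export
multitaper_spectrogram <- function(eeg, channel = names(eeg$channels)[1],
                                   nw = 2, k = 3) {
  stopifnot(inherits(eeg, "eeg_record"))
  x <- eeg$channels[[channel]]
  if (is.null(x)) stop("unknown channel: ", channel)
  fs <- eeg$sampling_rate
  wlen <- as.integer(2 * fs)
  n_win <- floor(length(x) / wlen)
  if (n_win < 1) stop("record shorter than one 2-s analysis window")
  dp <- cached_dpss(wlen, nw, k)
  n_freq <- wlen %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * fs / wlen          # 0.5 Hz spacing
  lam <- dp$eigenvalues / sum(dp$eigenvalues)

  xm <- matrix(x[seq_len(n_win * wlen)], nrow = wlen)
  xm[!is.finite(xm)] <- 0
  power <- matrix(0, n_win, n_freq)
  for (j in seq_len(k)) {
    tap <- dp$tapers[, j]
    ft <- stats::mvfft(xm * tap)
    p <- (Mod(ft[seq_len(n_freq), , drop = FALSE])^2) / fs
    # one-sided: double everything except DC (and Nyquist when wlen even)
    dbl <- rep(2, n_freq); dbl[1] <- 1
    if (wlen %% 2 == 0) dbl[n_freq] <- 1
    power <- power + lam[j] * t(p * dbl)
  }
  centers <- (seq_len(n_win) - 0.5) * 2 - eeg$lights_off
  structure(list(times = centers, freqs = freqs, power = power,
                 window_starts = (seq_len(n_win) - 1) * 2 - eeg$lights_off),
            class = "spectrogram")
}

#' Theta/alpha ratio per 15-s epoch
#'
#' Averages the surviving (unrejected) 2-s window spectra within each 15-s
#' epoch (windows assigned by start time relative to lights-off), sums power
#' over the theta band [4, 8) Hz and the alpha band [8, 12) Hz, and returns
#' their ratio. The half-open bands count the shared 8 Hz bin once. An epoch
#' is invalid when fewer than `min_windows` of its windows survive artifact
#' rejection or its alpha power is zero.
#'
#' @param spec a `spectrogram` from [multitaper_spectrogram()].
#' @param mask an `artifact_mask` from [detect_artifacts()] on the same
#'   window grid, or NULL to keep all windows.
#' @param epoch_len epoch length in seconds (default 15).
#' @param min_windows per-epoch quorum of surviving windows (default 4 of
#'   the ~7-8 windows per epoch).
#' @return an [epoch_series()] of theta/alpha ratios.
#' @export
band_ratio_epochs <- function(spec, mask = NULL, epoch_len = 15,
                              min_windows = 4) {
  stopifnot(inherits(spec, "spectrogram"))
  n_win <- nrow(spec$power)
  keep <- rep(TRUE, n_win)
  if (!is.null(mask)) {
    if (nrow(mask) != n_win)
      stop("artifact mask (", nrow(mask), ") and spectrogram (", n_win,
           ") must share the window grid")
    keep <- !mask$rejected
  }
  starts <- spec$window_starts
  ep <- floor(starts / epoch_len)
  valid_pos <- starts >= 0
  n_epoch <- if (any(valid_pos)) max(ep[valid_pos]) + 1L else 0L
  th_bins <- spec$freqs >= 4 & spec$freqs < 8
  al_bins <- spec$freqs >= 8 & spec$freqs < 12

  values <- rep(NA_real_, n_epoch)
  valid <- rep(FALSE, n_epoch)
  for (e in seq_len(n_epoch) - 1L) {
    idx <- which(ep == e & keep & valid_pos)
    if (length(idx) < min_windows) next
    avg <- colMeans(spec$power[idx, , drop = FALSE])
    th <- sum(avg[th_bins]); al <- sum(avg[al_bins])
    if (al <= 0) next
    values[e + 1L] <- th / al
    valid[e + 1L] <- TRUE
  }
  epoch_series(values, epoch_len, valid)
}

#' Full qEEG chain: raw EEG to theta/alpha epoch series
#'
#' Convenience wrapper: [preprocess_eeg()] then [detect_artifacts()] then
#' [multitaper_spectrogram()] then [band_ratio_epochs()] on one channel
#' (default O2, the occipital analysis channel).
#'
#' @param eeg an [eeg_record()].
#' @param channel channel name.
#' @param cfg a [filter_config()].
#' @param ... passed to [band_ratio_epochs()].
#' @return an [epoch_series()] of theta/alpha ratios on the 15-s grid.
#' @export
theta_alpha_epochs <- function(eeg, channel = "O2", cfg = filter_config(), ...) {
  filtered <- preprocess_eeg(eeg, cfg)
  mask <- detect_artifacts(filtered, channel)
  spec <- multitaper_spectrogram(filtered, channel)
  band_ratio_epochs(spec, mask, ...)
}
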