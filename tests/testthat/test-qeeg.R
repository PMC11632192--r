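test_that("band-pass filtering attenuates out-of-band tones, preserves in-band", {
  fs <- 256
  rms <- function(x) sqrt(mean(x^2))
  # 60 Hz tone vs 0.1-55 Hz passband: >= 20 dB down
  t60 <- tone_record(60, fs = fs)
  f60 <- preprocess_eeg(t60, filter_config())
  expect_gt(20 * log10(rms(t60$channels$O2) / rms(f60$channels$O2)), 20)
  # 10 Hz tone with no notch at 10: amplitude within 5%
  t10 <- tone_record(10, fs = fs)
  f10 <- preprocess_eeg(t10, filter_config(notches = 50))
  expect_lt(abs(rms(f10$channels$O2) / rms(t10$channels$O2) - 1), 0.05)
  # 50 Hz notch on a 50 Hz tone: >= 20 dB down
  t50 <- tone_record(50, fs = fs)
  f50 <- preprocess_eeg(t50, filter_config(notches = 50))
  expect_gt(20 * log10(rms(t50$channels$O2) / rms(f50$channels$O2)), 20)
  # config validation
  expect_error(filter_config(bandpass_lo = 10, bandpass_hi = 5), "bandpass")
  expect_error(filter_config(notches = 70), "passband")
})

test_that("artifact detector passes clean signal and flags injected faults", {
  fs <- 256
  clean <- tone_record(10, fs = fs, dur = 60, amp = 50, noise_sd = 3)
  mask0 <- detect_artifacts(clean)
  expect_equal(sum(mask0$rejected), 0L)

  x <- clean$channels$O2
  # 3-s NaN gap starting at 10 s
  x_na <- x; x_na[(10 * fs):(13 * fs)] <- NA
  m <- detect_artifacts(eeg_record(list(O2 = x_na), fs))
  hit <- m$window >= 4 & m$window <= 6
  expect_true(all(m$rejected[hit]))
  expect_true(all(m$reason[hit] == "missing"))

  # 1-s segment pinned at the rail maximum -> saturation
  x_sat <- x; x_sat[(20 * fs):(21 * fs)] <- max(x)
  m <- detect_artifacts(eeg_record(list(O2 = x_sat), fs))
  expect_true(any(m$rejected & m$reason == "saturation"))

  # single-sample jump above the slew threshold
  x_slew <- x; x_slew[30 * fs] <- x_slew[30 * fs] + 120
  m <- detect_artifacts(eeg_record(list(O2 = x_slew), fs))
  expect_identical(m$reason[m$window == 14], "slew")

  # smooth large-amplitude excursion -> artifact (peak-to-peak rule, with
  # sample-to-sample steps kept below the slew threshold)
  x_big <- x
  seg <- (40 * fs + 1):(42 * fs)
  x_big[seg] <- x_big[seg] + 600 * sin(2 * pi * 0.5 * (seq_along(seg) - 1) / fs)
  m <- detect_artifacts(eeg_record(list(O2 = x_big), fs))
  expect_identical(m$reason[m$window == 20], "artifact")
})

test_that("multitaper spectrogram localizes tones on the 0.5 Hz grid", {
  fs <- 256
  spec <- multitaper_spectrogram(tone_record(10, fs = fs, dur = 30))
  expect_equal(diff(spec$freqs)[1], 0.5)
  expect_equal(max(spec$freqs), fs / 2)
  peak <- spec$freqs[apply(spec$power, 1, which.max)]
  expect_true(all(peak == 10))
  # constant signal: power concentrated at DC, only taper-sidelobe dust in
  # the theta/alpha bands
  const <- eeg_record(list(O2 = rep(5, fs * 20)), fs)
  sp <- multitaper_spectrogram(const)
  band <- sp$freqs >= 4 & sp$freqs < 12
  expect_lte(sp$freqs[which.max(sp$power[1, ])], 1)  # within the taper bandwidth
  expect_lt(max(sp$power[, band]) / max(sp$power[, 1]), 1e-3)
  expect_error(multitaper_spectrogram(tone_record(10), channel = "C3"), "unknown channel")
})

test_that("multitaper power satisfies Parseval on white noise", {
  fs <- 256
  x <- mwtbio:::with_seed(11, rnorm(fs * 60, sd = 10))
  spec <- multitaper_spectrogram(eeg_record(list(O2 = x), fs))
  df <- 0.5
  total <- rowSums(spec$power) * df
  v <- var(x)
  expect_lt(abs(mean(total) - v) / v, 0.10)
})

test_that("theta/alpha ratio separates theta- from alpha-dominant signals", {
  fs <- 256
  mk <- function(freq) {
    x <- 40 * sin(2 * pi * freq * (seq_len(fs * 60) - 1) / fs) +
      mwtbio:::with_seed(5, rnorm(fs * 60, sd = 2))
    eeg_record(list(O2 = x), fs)
  }
  ta_theta <- band_ratio_epochs(multitaper_spectrogram(mk(6)))
  expect_true(all(ta_theta$values[ta_theta$valid] > 5))
  ta_alpha <- band_ratio_epochs(multitaper_spectrogram(mk(10)))
  expect_true(all(ta_alpha$values[ta_alpha$valid] < 0.2))
  # scale invariance: multiplying the signal leaves the ratio unchanged
  e1 <- mk(6); e2 <- e1; e2$channels$O2 <- 3.7 * e2$channels$O2
  r1 <- band_ratio_epochs(multitaper_spectrogram(e1))
  r2 <- band_ratio_epochs(multitaper_spectrogram(e2))
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
})

test_that("epochs lose validity when too few windows survive rejection", {
  fs <- 256
  rec <- tone_record(6, fs = fs, dur = 30, noise_sd = 1)
  spec <- multitaper_spectrogram(rec)
  mask <- detect_artifacts(rec)
  # reject enough windows of epoch 0 (8 windows) to break the quorum of 4
  mask$rejected[1:5] <- TRUE
  ta <- band_ratio_epochs(spec, mask)
  expect_false(ta$valid[1])
  expect_true(ta$valid[2])
  # all windows rejected -> all-invalid series, not an error
  mask$rejected[] <- TRUE
  ta_none <- band_ratio_epochs(spec, mask)
  expect_false(any(ta_none$valid))
  # mismatched grids are an error
  expect_error(band_ratio_epochs(spec, mask[-1, ]), "window grid")
})

test_that("raising the theta oscillator raises the epoch theta/alpha ratio", {
  cfg <- sim_session_config(seed = 8, max_duration = 3, microsleep_base_rate = 0)
  sess <- simulate_session(trajectory_params(log(0.4), 0, 0), cfg)
  med <- vapply(c(5, 15, 30, 60), function(amp) {
    ta <- theta_alpha_epochs(synthesize_eeg(sess, cfg, theta_amp = amp))
    median(ta$values[ta$valid])
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("log theta/alpha tracks the latent log sleepiness on synthetic EEG", {
  cfg <- sim_session_config(seed = 21, max_duration = 15, microsleep_base_rate = 0)
  sess <- simulate_session(trajectory_params(-2.5, 0.15, 0.1), cfg)
  ta <- theta_alpha_epochs(synthesize_eeg(sess, cfg))
  s <- sess$sleepiness$values[seq_along(ta$values)]
  ok <- ta$valid
  expect_gt(cor(log(ta$values[ok]), log(s[ok])), 0.7)
})

test_that("notch suggestion flags a strong line-interference peak", {
  fs <- 256
  x <- mwtbio:::with_seed(3, rnorm(fs * 60, sd = 5)) +
    40 * sin(2 * pi * 50 * (seq_len(fs * 60) - 1) / fs)
  cand <- suggest_notches(eeg_record(list(O2 = x), fs))
  expect_true(50 %in% cand)
})
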