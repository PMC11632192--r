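# Shared fixtures and independent oracles.

# Brute-force SOL scan, independent of score_sol: walk every epoch and test
# the two onset clauses directly.
oracle_sol <- function(stages, max_min = 40, epoch_len = 30) {
  n <- length(stages)
  for (e in seq_len(n)) {
    if (stages[e] %in% c("N2", "N3", "REM"))
      return(list(sol_min = (e - 1) * epoch_len / 60, censored = FALSE))
    if (e + 2 <= n && all(stages[e:(e + 2)] == "N1"))
      return(list(sol_min = (e - 1) * epoch_len / 60, censored = FALSE))
  }
  list(sol_min = max_min, censored = TRUE)
}

# Random hypnogram generator for oracle-equivalence tests.
random_hypnogram <- function(n, p_stage = c(W = 0.6, N1 = 0.25, N2 = 0.1,
                                            N3 = 0.03, REM = 0.02)) {
  sample(names(p_stage), n, replace = TRUE, prob = p_stage)
}

# FFT peak-frequency oracle: dominant frequency of a signal, Hz.
oracle_peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2)]
  (which.max(p) - 1) * fs / n
}

# Pure tone as a single-channel EEG record.
tone_record <- function(freq, fs = 256, dur = 60, amp = 50, noise_sd = 0,
                        seed = 42) {
  tt <- (seq_len(dur * fs) - 1) / fs
  x <- amp * sin(2 * pi * freq * tt)
  if (noise_sd > 0) x <- x + mwtbio:::with_seed(seed, rnorm(length(tt), 0, noise_sd))
  eeg_record(list(O2 = x), sampling_rate = fs)
}

# Brute-force repeated-measures correlation via explicit ANCOVA sums of
# squares (fits the null subject-only model and the subject+x model).
oracle_rmcorr <- function(df) {
  df$subject <- factor(df$subject)
  fit0 <- lm(y ~ subject, data = df)
  fit1 <- lm(y ~ subject + x, data = df)
  ss_err <- sum(residuals(fit1)^2)
  ss_x <- sum(residuals(fit0)^2) - ss_err
  slope <- coef(fit1)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df_err <- nrow(df) - nlevels(df$subject) - 1
  tval <- r * sqrt(df_err / (1 - r^2))
  list(r = r, df = df_err, p = 2 * pt(-abs(tval), df_err))
}

# Small deterministic endpoint table with participant offsets.
offset_table <- function(n_subj = 3, n_obs = 4) {
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    x <- seq_len(n_obs) + s
    data.frame(participant = paste0("s", s), x = x, y = x + 10 * s)
  }))
}
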