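test_that("sleepiness score is the summed non-wake probability", {
  h <- data.frame(p_W = c(0.7, 1, 0.4), p_N1 = c(0.2, 0, 0.3),
                  p_N2 = c(0.1, 0, 0.3), p_N3 = 0, p_REM = 0)
  s <- sleepiness_from_hypnodensity(h)
  expect_equal(s$values, c(0.3, 0, 0.6))
  expect_equal(s$epoch_len, 15)
  expect_true(all(s$values >= 0 & s$values <= 1))
  # a row summing to 0.9 is rejected, naming the row
  bad <- data.frame(p_W = 0.2, p_N1 = 0.2, p_N2 = 0.2, p_N3 = 0.2, p_REM = 0.1)
  expect_error(sleepiness_from_hypnodensity(bad), "row 1")
})

test_that("log-trajectory fit recovers exact linear data and clips zeros", {
  cfg_centers <- (seq_len(160) - 0.5) * 15 / 60
  series <- epoch_series(exp(-2 + 0.05 * cfg_centers), 15)
  censored <- score_sol(rep("W", 80))
  fit <- fit_log_trajectory(series, censored)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, -2, tolerance = 1e-12)
  # constant series
  fitc <- fit_log_trajectory(epoch_series(rep(0.5, 40), 15), censored)
  expect_equal(fitc$slope, 0, tolerance = 1e-12)
  expect_equal(fitc$intercept, log(0.5), tolerance = 1e-12)
  expect_equal(fitc$average, 0.5)
  # all-zero series: clipped to the 1e-3 floor
  fit0 <- fit_log_trajectory(epoch_series(rep(0, 40), 15), censored)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, log(1e-3), tolerance = 1e-12)
  # fewer than 4 usable epochs: invalid fit
  short <- fit_log_trajectory(epoch_series(c(0.2, 0.3, 0.4), 15), censored)
  expect_false(short$valid)
  expect_true(is.na(short$slope))
})

test_that("trajectory fit window ends at sleep onset", {
  centers <- (seq_len(160) - 0.5) * 15 / 60
  # log-linear until 10 min, junk afterwards; SOL at 10 min must shield the fit
  vals <- exp(-2 + 0.1 * centers)
  vals[centers >= 10] <- 1
  sol <- score_sol(c(rep("W", 20), rep("N2", 3)))   # onset epoch 20 -> 10 min
  fit <- fit_log_trajectory(epoch_series(vals, 15), sol)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$fit_window_end, 10)
  expect_equal(fit$n_epochs_used, 40L)
})

test_that("the session average can use the fit window or the whole series", {
  centers <- (seq_len(160) - 0.5) * 15 / 60
  vals <- exp(-2 + 0.1 * centers)
  sol <- score_sol(c(rep("W", 20), rep("N2", 3)))   # onset at 10 min
  s <- epoch_series(vals, 15)
  f_fit <- fit_log_trajectory(s, sol)
  f_all <- fit_log_trajectory(s, sol, average_window = "session")
  expect_equal(f_fit$average, mean(vals[centers < 10]), tolerance = 1e-12)
  expect_equal(f_all$average, mean(vals), tolerance = 1e-12)
  expect_equal(f_fit$slope, f_all$slope)
})

test_that("trajectory fit is scale-equivariant", {
  set.seed(42)
  centers <- (seq_len(80) - 0.5) * 15 / 60
  vals <- exp(-2 + 0.08 * centers + rnorm(80, 0, 0.1))
  s1 <- epoch_series(vals, 15)
  s2 <- epoch_series(0.37 * vals, 15)
  f1 <- fit_log_trajectory(s1)
  f2 <- fit_log_trajectory(s2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept + log(0.37), tolerance = 1e-10)
})

test_that("SOL scorer matches the worked examples and the brute-force oracle", {
  ex1 <- score_sol(c("W", "W", "N1", "N1", "N1", rep("W", 10)))
  expect_equal(ex1$sol_min, 1.0)
  expect_equal(ex1$onset_epoch, 2L)
  ex2 <- score_sol(c("W", "N1", "W", "N2", rep("W", 10)))
  expect_equal(ex2$sol_min, 1.5)
  ex3 <- score_sol(rep("W", 80))
  expect_true(ex3$censored)
  expect_equal(ex3$sol_min, 40)
  expect_error(score_sol(character(0)), "empty")
  expect_error(score_sol(c("W", "N4")), "invalid stage")

  set.seed(99)
  for (i in 1:300) {
    stages <- random_hypnogram(sample(1:80, 1))
    got <- score_sol(stages)
    want <- oracle_sol(stages)
    expect_equal(got$sol_min, want$sol_min)
    expect_equal(got$censored, want$censored)
  }
})

test_that("microsleep metrics follow the zero convention and exact arithmetic", {
  expect_equal(microsleep_metrics(NULL, 40), list(rate = 0, mean_duration_s = 0))
  ev <- data.frame(onset_s = c(10, 60, 120, 200, 300), duration_s = 3:7)
  m <- microsleep_metrics(ev, 10)
  expect_equal(m$rate, 0.25)
  expect_equal(m$mean_duration_s, 5)
  expect_error(microsleep_metrics(data.frame(onset_s = 1, duration_s = 15), 10),
               "\\[3, 15\\)")
  expect_error(microsleep_metrics(data.frame(onset_s = 1, duration_s = 2.9), 10),
               "\\[3, 15\\)")
  # partial epochs are not counted in the denominator
  m2 <- microsleep_metrics(data.frame(onset_s = 5, duration_s = 4), 10.4)
  expect_equal(m2$rate, 1 / 20)
})

test_that("KSS interpolation is linear in clock time without extrapolation", {
  kss <- data.frame(clock_time = c("09:50", "10:50"), score = c(7, 5))
  expect_equal(interpolate_kss(kss, "10:20"), 6.0)
  expect_equal(interpolate_kss(kss, "09:50"), 7)
  expect_true(is.na(interpolate_kss(kss, "09:00")))
  expect_true(is.na(interpolate_kss(kss, "11:00")))
  expect_error(interpolate_kss(data.frame(clock_time = c("10:00", "10:00"),
                                          score = c(5, 5)), "10:00"),
               "strictly increasing")
  expect_error(interpolate_kss(data.frame(clock_time = "10:00", score = 12),
                               "10:00"), "\\[1, 9\\]")
})

test_that("endpoint table carries all endpoints, flags and the siesta slot", {
  st <- simulate_study(default_study_design(n_per_cohort = 2, seed = 6))
  kss <- expand.grid(participant = unique(st$design_table$participant),
                     clock_time = c("09:00", "11:00", "13:00", "15:00", "17:00"))
  kss$score <- 6
  ep <- compile_endpoints(st, kss = kss)
  expect_equal(nrow(ep), 48)
  expect_setequal(
    c("sol_min", "sol_censored", "inverse_sol", "slope_analysis_eligible",
      "microsleep_rate", "microsleep_duration", "sleepiness_avg",
      "sleepiness_slope", "sleepiness_intercept", "theta_alpha_avg",
      "theta_alpha_slope", "theta_alpha_intercept", "kss"),
    setdiff(names(ep), names(st$design_table)))
  expect_equal(ep$isSiesta, as.integer(ep$session_time == "14:00"))
  expect_equal(ep$slope_analysis_eligible, ep$sol_min > 1)
  # censored sessions keep inverse SOL = 1/40 with the censored flag
  cen <- ep$sol_censored
  if (any(cen)) expect_equal(ep$inverse_sol[cen], rep(1 / 40, sum(cen)))
  expect_true(all(ep$kss == 6))
  # duplicate keys are rejected
  st2 <- st
  st2$design_table$day[2] <- st2$design_table$day[1]
  st2$design_table$session_time[2] <- st2$design_table$session_time[1]
  expect_error(compile_endpoints(st2), "duplicate")
})

test_that("inverse SOL is proportional to slope for noiseless shared-intercept sessions", {
  # ladder kept inside the regime where onset fires via the triple-N1 clause
  # (b <= ~0.3/min); beyond it the deeper-stage clause takes over with a
  # different proportionality constant
  slopes <- seq(0.04, 0.3, length.out = 12)
  inv_sol <- slope_hat <- numeric(length(slopes))
  for (i in seq_along(slopes)) {
    cfg <- sim_session_config(seed = i)
    s <- simulate_session(trajectory_params(-2, slopes[i], 0), cfg)
    inv_sol[i] <- 1 / s$sol$sol_min
    fit <- fit_log_trajectory(sleepiness_from_hypnodensity(s$hypnodensity), s$sol)
    slope_hat[i] <- fit$slope
  }
  expect_gt(cor(slope_hat, inv_sol), 0.99)
})
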