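test_that("simulated trajectory follows the closed-form log-linear model", {
  cfg <- sim_session_config(seed = 1)
  tr <- simulate_trajectory(trajectory_params(-2, 0.05, 0), cfg)
  tc <- epoch_centers(tr)
  expect_equal(tr$values, pmin(1, exp(-2 + 0.05 * tc)), tolerance = 1e-12)
  # constant case
  tr0 <- simulate_trajectory(trajectory_params(-2, 0, 0), cfg)
  expect_true(all(tr0$values == exp(-2)))
  # seed reproducibility
  trn1 <- simulate_trajectory(trajectory_params(-2, 0.05, 0.1), cfg)
  trn2 <- simulate_trajectory(trajectory_params(-2, 0.05, 0.1), cfg)
  expect_identical(trn1$values, trn2$values)
})

test_that("trajectory parameter validation rejects bad inputs", {
  expect_error(trajectory_params(-2, NA, 0), "non-finite")
  expect_error(trajectory_params(-2, 0.1, -1), "noise_sd")
  expect_error(trajectory_params(0.5, 0.1, 0), "<= 1")
  expect_error(sim_session_config(theta_n1 = 0.9, theta_n2 = 0.5), "thresholds")
  expect_error(sim_session_config(epoch_len_fine = 20, epoch_len_stage = 30),
               "multiple")
})

test_that("hypnodensity rows sum to one and encode the latent sleepiness", {
  cfg <- sim_session_config(seed = 3)
  s <- simulate_session(trajectory_params(-2, 0.08, 0.2), cfg)
  p <- as.matrix(s$hypnodensity[, c("p_W", "p_N1", "p_N2", "p_N3", "p_REM")])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(unname(1 - p[, "p_W"]), s$sleepiness$values)
})

test_that("flat low trajectory yields an all-wake censored session", {
  s <- simulate_session(trajectory_params(-4, 0, 0),
                        sim_session_config(seed = 2, microsleep_base_rate = 0))
  expect_true(all(s$hypnogram == "W"))
  expect_true(s$sol$censored)
  expect_equal(s$sol$sol_min, 40)
  expect_equal(nrow(s$microsleeps), 0L)
})

test_that("scored SOL tracks the analytic threshold crossing over a grid", {
  # noiseless sessions: scored SOL within one 30-s stage epoch of
  # (ln theta_n1 - a) / b
  for (a in c(-3, -2, -1.2)) {
    for (b in c(0.05, 0.1, 0.2)) {
      for (th in c(0.4, 0.5, 0.6)) {
        cfg <- sim_session_config(seed = 1, theta_n1 = th,
                                  theta_n2 = min(1, th + 0.3))
        s <- simulate_session(trajectory_params(a, b, 0), cfg)
        analytic <- (log(th) - a) / b
        if (analytic <= 40) {
          expect_false(s$sol$censored)
          expect_lt(abs(s$sol$sol_min - analytic), 0.5 + 1e-9)
        } else {
          expect_true(s$sol$censored)
        }
      }
    }
  }
})

test_that("session truncates one stage epoch after unambiguous sleep onset", {
  s <- simulate_session(trajectory_params(-2, 0.1, 0), sim_session_config(seed = 1))
  # onset via triple-N1 at epoch e: trial retains epochs through e+3
  e <- s$sol$onset_epoch
  expect_true(s$hypnogram[e + 1] == "N1")
  expect_lte(length(s$hypnogram), e + 4)
  expect_equal(s$duration_min, length(s$hypnogram) * 0.5)
})

test_that("microsleep events respect duration bounds and never overlap", {
  for (seed in c(1, 7, 23)) {
    cfg <- sim_session_config(seed = seed, microsleep_base_rate = 4)
    s <- simulate_session(trajectory_params(-1.2, 0.02, 0.15), cfg)
    ev <- s$microsleeps
    if (nrow(ev) < 2) next
    expect_true(all(ev$duration_s >= 3 & ev$duration_s < 15))
    ends <- ev$onset_s + ev$duration_s
    expect_true(all(ev$onset_s[-1] >= ends[-nrow(ev)]))
  }
  # zero base rate -> empty list
  s0 <- simulate_session(trajectory_params(-1.2, 0.02, 0.15),
                         sim_session_config(seed = 1, microsleep_base_rate = 0))
  expect_equal(nrow(s0$microsleeps), 0L)
})

test_that("study simulation emits the full design with a siesta slope bump", {
  des <- study_design(
    cohorts = list(
      list(label = "placebo", n_participants = 3,
           slope_by_day = c(baseline = 0.1, day1 = 0.1, day7 = 0.1)),
      list(label = "treated", n_participants = 3,
           slope_by_day = c(baseline = 0.1, day1 = 0.04, day7 = 0.04))),
    siesta_slope_bump = 0.05, seed = 9)
  st <- simulate_study(des)
  expect_equal(length(st$sessions), 2 * 3 * 3 * 4)
  expect_equal(nrow(st$design_table), 72)
  expect_equal(sum(st$design_table$isSiesta), 18)  # one slot in four
  gt <- st$ground_truth
  siesta <- st$design_table$isSiesta == 1
  expect_gt(mean(gt$true_slope_b[siesta]), mean(gt$true_slope_b[!siesta]))
  expect_error(study_design(cohorts = list()), "cohort")
})

test_that("a fixed study seed reproduces every artifact bit-exactly", {
  des <- default_study_design(n_per_cohort = 2, seed = 5)
  s1 <- simulate_study(des)
  s2 <- simulate_study(des)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(lapply(s1$sessions, `[[`, "hypnodensity"),
                   lapply(s2$sessions, `[[`, "hypnodensity"))
  expect_identical(lapply(s1$sessions, `[[`, "microsleeps"),
                   lapply(s2$sessions, `[[`, "microsleeps"))
})

test_that("synthesized EEG puts its spectral peak at the dominant oscillator", {
  cfg <- sim_session_config(seed = 4, max_duration = 2, microsleep_base_rate = 0)
  # fully awake: S ~ 0 -> alpha (10 Hz) dominates
  awake <- simulate_session(trajectory_params(log(1e-3), 0, 0), cfg)
  e_awake <- synthesize_eeg(awake, cfg)
  expect_equal(oracle_peak_freq(e_awake$channels$O2, 256), 10, tolerance = 0.05)
  # fully asleep: S = 1 -> theta (6 Hz) dominates
  asleep <- simulate_session(trajectory_params(0, 0, 0), cfg)
  e_asleep <- synthesize_eeg(asleep, cfg)
  expect_equal(oracle_peak_freq(e_asleep$channels$O2, 256), 6, tolerance = 0.05)
  # bit-identical under the seed
  expect_identical(e_awake$channels$O2, synthesize_eeg(awake, cfg)$channels$O2)
  # sampling rates below 128 Hz are refused
  cfg_low <- sim_session_config(seed = 4, max_duration = 2, sampling_rate = 100)
  expect_error(synthesize_eeg(awake, cfg_low), "128")
})
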