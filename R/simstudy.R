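# Synthetic MWT study generator.
#
# The latent model is exactly log-linear: sleepiness S(t) = exp(a + b t + eps)
# clipped to [LOG_FLOOR, 1], with t in minutes from lights-off. This makes the
# downstream linear fit to log sleepiness the correctly specified model, so
# parameter-recovery tests are sharp. Hypnodensities, hypnograms, microsleeps
# and surrogate EEG are all derived from S(t) with known ground truth.

#' Latent trajectory parameters for one MWT session
#'
#' @param intercept_a log-sleepiness at lights-off (natural log scale);
#'   `exp(intercept_a)` must be at most 1.
#' @param slope_b log-sleepiness growth rate, per minute.
#' @param noise_sd standard deviation of additive per-epoch noise on the log
#'   scale; must be non-negative.
#' @return a `trajectory_params` object.
#' @export
trajectory_params <- function(intercept_a, slope_b, noise_sd = 0) {
  stopifnot_finite(c(intercept_a, slope_b, noise_sd), "trajectory params")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (exp(intercept_a) > 1 + 1e-12) stop("exp(intercept_a) must be <= 1")
  structure(list(intercept_a = intercept_a, slope_b = slope_b, noise_sd = noise_sd),
            class = "trajectory_params")
}

#' Configuration of one simulated MWT session
#'
#' @param session_start clock time, "HH:MM" or minutes since midnight.
#' @param max_duration maximum trial length in minutes (standard MWT: 40).
#' @param epoch_len_fine hypnodensity epoch length, seconds (default 15).
#' @param epoch_len_stage hypnogram epoch length, seconds (default 30); must
#'   be a multiple of `epoch_len_fine`.
#' @param theta_n1,theta_n2 sleepiness thresholds mapping mean stage-epoch
#'   sleepiness to stages N1 and N2; require 0 < theta_n1 < theta_n2 <= 1.
#' @param microsleep_base_rate microsleep event rate (events/minute) at
#'   sleepiness = 1; the realized rate is `microsleep_base_rate * S(t)` on
#'   wake epochs.
#' @param sampling_rate EEG sampling rate in Hz for synthesized signals.
#' @param seed integer seed for the session's randomness.
#' @return a `sim_session_config` object.
#' @export
sim_session_config <- function(session_start = "10:00", max_duration = 40,
                               epoch_len_fine = 15, epoch_len_stage = 30,
                               theta_n1 = 0.5, theta_n2 = 0.8,
                               microsleep_base_rate = 1.0,
                               sampling_rate = 256, seed = 1L) {
  if (max_duration <= 0) stop("max_duration must be positive")
  if (epoch_len_stage %% epoch_len_fine != 0)
    stop("epoch_len_stage must be a multiple of epoch_len_fine")
  if (!(theta_n1 > 0 && theta_n1 < theta_n2 && theta_n2 <= 1))
    stop("stage thresholds must satisfy 0 < theta_n1 < theta_n2 <= 1")
  if (microsleep_base_rate < 0) stop("microsleep_base_rate must be >= 0")
  structure(list(session_start = session_start, max_duration = max_duration,
                 epoch_len_fine = epoch_len_fine, epoch_len_stage = epoch_len_stage,
                 theta_n1 = theta_n1, theta_n2 = theta_n2,
                 microsleep_base_rate = microsleep_base_rate,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "sim_session_config")
}

#' Simulate a latent sleepiness trajectory on the fine epoch grid
#'
#' Sleepiness at epoch-center time t (minutes from lights-off) is
#' `clip(exp(a + b t + eps_t), LOG_FLOOR, 1)` with iid Gaussian log-scale
#' noise, on a grid of `epoch_len_fine`-second epochs spanning the full
#' `max_duration`.
#'
#' @param params a [trajectory_params()] object.
#' @param cfg a [sim_session_config()] object.
#' @return an [epoch_series()] of sleepiness values in `[1e-3, 1]`.
#' @export
simulate_trajectory <- function(params, cfg) {
  stopifnot(inherits(params, "trajectory_params"), inherits(cfg, "sim_session_config"))
  n <- floor(cfg$max_duration * 60 / cfg$epoch_len_fine)
  t_min <- (seq_len(n) - 0.5) * cfg$epoch_len_fine / 60
  eps <- if (params$noise_sd > 0)
    with_seed(cfg$seed, stats::rnorm(n, 0, params$noise_sd)) else numeric(n)
  s <- exp(params$intercept_a + params$slope_b * t_min + eps)
  epoch_series(pmin(1, pmax(LOG_FLOOR, s)), cfg$epoch_len_fine)
}

# Fixed mixing rule allocating non-wake probability across stages: N1 takes
# fraction min(1, 2(1 - S)), the remainder goes to N2; N3/REM stay 0 (MWT
# naps rarely reach them). Keeps both clauses of the SOL rule exercisable.
hypnodensity_from_sleepiness <- function(s) {
  f_n1 <- pmin(1, 2 * (1 - s))
  p_n1 <- s * f_n1
  p_n2 <- s - p_n1
  data.frame(epoch_index = seq_along(s) - 1L,
             p_W = 1 - s, p_N1 = p_n1, p_N2 = p_n2,
             p_N3 = 0, p_REM = 0)
}

#' Simulate one complete MWT session
#'
#' Generates the latent trajectory, the per-15-s hypnodensity table, the
#' per-30-s hypnogram (N2 if mean sleepiness exceeds `theta_n2`, N1 if it
#' exceeds `theta_n1`, else wake), scores sleep onset with the standard rule
#' (three consecutive N1 epochs or one epoch of deeper sleep), truncates the
#' trial one stage-epoch after the rule fires (the trial ends at unambiguous
#' sleep onset) or at `max_duration`, and draws microsleep events from an
#' inhomogeneous Poisson process with rate `microsleep_base_rate * S(t)`
#' restricted to wake epochs, durations uniform on [3, 15) s, non-overlapping.
#'
#' @param params a [trajectory_params()] object.
#' @param cfg a [sim_session_config()] object.
#' @return a `session_record`: list with `sleepiness` (epoch_series),
#'   `hypnodensity` (data.frame), `hypnogram` (character vector),
#'   `microsleeps` (data.frame onset_s/duration_s), `sol` ([sol_result]),
#'   `duration_min`, `config`, and `ground_truth` (true parameters, analytic
#'   SOL, censoring).
#' @export
simulate_session <- function(params, cfg) {
  stopifnot(inherits(params, "trajectory_params"), inherits(cfg, "sim_session_config"))
  traj_full <- simulate_trajectory(params, cfg)
  s_fine <- traj_full$values
  per <- cfg$epoch_len_stage / cfg$epoch_len_fine
  n_stage_full <- floor(length(s_fine) / per)
  s_stage <- colMeans(matrix(s_fine[seq_len(n_stage_full * per)], nrow = per))
  stages <- ifelse(s_stage > cfg$theta_n2, "N2",
                   ifelse(s_stage > cfg$theta_n1, "N1", "W"))

  sol <- score_sol(stages, max_min = cfg$max_duration,
                   epoch_len = cfg$epoch_len_stage)

  # Truncate one stage-epoch after the rule completes.
  if (!sol$censored) {
    trigger <- sol$onset_epoch
    complete <- if (stages[trigger + 1L] %in% c("N2", "N3", "REM")) trigger else trigger + 2L
    last_epoch <- min(complete + 1L, n_stage_full - 1L)   # 0-based
    n_stage <- last_epoch + 1L
  } else {
    n_stage <- n_stage_full
  }
  duration_min <- n_stage * cfg$epoch_len_stage / 60
  n_fine <- n_stage * per
  s_fine <- s_fine[seq_len(n_fine)]
  stages <- stages[seq_len(n_stage)]

  hypno <- hypnodensity_from_sleepiness(s_fine)
  # the hypnodensity is the single source of truth for the stored series, so
  # that sleepiness reconstructed downstream (1 - p_W) is bitwise identical
  s_fine <- 1 - hypno$p_W
  events <- simulate_microsleeps(s_fine, stages, cfg)

  b <- params$slope_b
  sol_analytic <- if (b > 0) (log(cfg$theta_n1) - params$intercept_a) / b else Inf
  censored_analytic <- !(is.finite(sol_analytic) && sol_analytic <= cfg$max_duration &&
                           sol_analytic >= 0)
  structure(list(
    sleepiness = epoch_series(s_fine, cfg$epoch_len_fine),
    hypnodensity = hypno,
    hypnogram = stages,
    microsleeps = events,
    sol = sol,
    duration_min = duration_min,
    config = cfg,
    ground_truth = list(
      intercept_a = params$intercept_a, slope_b = b, noise_sd = params$noise_sd,
      sol_analytic_min = if (censored_analytic) cfg$max_duration else sol_analytic,
      sol_censored = censored_analytic,
      n_microsleeps = nrow(events))
  ), class = "session_record")
}

# Thinning sampler for the inhomogeneous Poisson microsleep process.
# Candidates at the max rate are accepted with probability S(t)/S_max and only
# when they start inside a wake stage-epoch; overlapping candidates are
# rejected and redrawn at most 100 times.
simulate_microsleeps <- function(s_fine, stages, cfg) {
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  rate0 <- cfg$microsleep_base_rate
  dur_min <- length(s_fine) * cfg$epoch_len_fine / 60
  if (rate0 <= 0 || dur_min <= 0) return(empty)
  s_max <- max(s_fine)
  if (s_max <= 0) return(empty)

  with_seed(cfg$seed + 1L, {
    lambda_max <- rate0 * s_max                      # events per minute
    n_cand <- stats::rpois(1, lambda_max * dur_min)
    if (n_cand == 0) return(empty)
    onsets <- sort(stats::runif(n_cand, 0, dur_min * 60))     # seconds
    fine_idx <- pmin(length(s_fine), floor(onsets / cfg$epoch_len_fine) + 1L)
    keep <- stats::runif(n_cand) < s_fine[fine_idx] / s_max
    stage_idx <- pmin(length(stages), floor(onsets / cfg$epoch_len_stage) + 1L)
    keep <- keep & stages[stage_idx] == "W"
    onsets <- onsets[keep]
    if (length(onsets) == 0) return(empty)

    accepted_on <- numeric(0); accepted_dur <- numeric(0)
    for (on in onsets) {
      dur <- stats::runif(1, 3, 15)
      tries <- 0L
      while (tries < 100L &&
             any(on < accepted_on + accepted_dur & on + dur > accepted_on)) {
        dur <- stats::runif(1, 3, 15)
        on <- stats::runif(1, 0, dur_min * 60)
        tries <- tries + 1L
      }
      if (tries >= 100L) next
      accepted_on <- c(accepted_on, on); accepted_dur <- c(accepted_dur, dur)
    }
    ord <- order(accepted_on)
    data.frame(onset_s = accepted_on[ord], duration_s = accepted_dur[ord])
  })
}

#' Define a simulated MWT study
#'
#' Mirrors the structure of a small narcolepsy trial: cohorts of participants,
#' MWT days (baseline plus treatment days), four sessions per day at fixed
#' clock times, a between-subject random intercept on log-sleepiness at
#' lights-off, and a siesta effect adding to the slope of the 14:00 session.
#'
#' @param cohorts list of cohort descriptors, each a list with `label`,
#'   `n_participants`, and `slope_by_day` — a named numeric vector giving the
#'   base log-sleepiness growth rate (1/min) for each day. Treatment effects
#'   are expressed as reduced slopes on post-baseline days.
#' @param days character vector of day labels; the first is the baseline.
#' @param session_times four session clock times, strictly increasing.
#' @param intercept_a shared log-sleepiness intercept at lights-off.
#' @param participant_intercept_sd between-subject SD of the intercept.
#' @param participant_slope_sd between-subject SD of a participant-level
#'   slope perturbation (constant across that participant's sessions).
#' @param siesta_slope_bump additive slope increment (1/min) for the 14:00
#'   session, the early-afternoon dip in wakefulness.
#' @param noise_sd per-epoch log-scale noise SD passed to each session.
#' @param session_config baseline [sim_session_config()] whose grid/threshold
#'   settings are shared by all sessions.
#' @param seed study-level seed; all session seeds derive from it.
#' @return a `study_design` object.
#' @export
study_design <- function(cohorts,
                         days = c("baseline", "day1", "day7"),
                         session_times = c("10:00", "12:00", "14:00", "16:00"),
                         intercept_a = -2,
                         participant_intercept_sd = 0.3,
                         participant_slope_sd = 0.01,
                         siesta_slope_bump = 0.03,
                         noise_sd = 0.2,
                         session_config = sim_session_config(),
                         seed = 1L) {
  if (length(cohorts) == 0) stop("at least one cohort is required")
  for (co in cohorts) {
    if (is.null(co$label) || is.null(co$n_participants) || is.null(co$slope_by_day))
      stop("each cohort needs label, n_participants, slope_by_day")
    if (co$n_participants < 1) stop("n_participants must be >= 1 in cohort ", co$label)
    if (!all(days %in% names(co$slope_by_day)))
      stop("slope_by_day must name every day in cohort ", co$label)
  }
  tm <- clock_to_min(session_times)
  if (any(diff(tm) <= 0)) stop("session clock times must be strictly increasing")
  structure(list(cohorts = cohorts, days = days, session_times = session_times,
                 intercept_a = intercept_a,
                 participant_intercept_sd = participant_intercept_sd,
                 participant_slope_sd = participant_slope_sd,
                 siesta_slope_bump = siesta_slope_bump,
                 noise_sd = noise_sd, session_config = session_config,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Default two-cohort study design
#'
#' A compact stand-in for a placebo-controlled narcolepsy trial: two cohorts,
#' three MWT days, four sessions per day. The "treated" cohort's slope drops
#' markedly on post-baseline days (treatment reduces the rate of sleepiness
#' growth); the "placebo" cohort's does not.
#'
#' @param n_per_cohort participants per cohort.
#' @param seed study seed.
#' @param ... passed on to [study_design()].
#' @export
default_study_design <- function(n_per_cohort = 4, seed = 1L, ...) {
  study_design(
    cohorts = list(
      list(label = "placebo", n_participants = n_per_cohort,
           slope_by_day = c(baseline = 0.10, day1 = 0.10, day7 = 0.10)),
      list(label = "treated", n_participants = n_per_cohort,
           slope_by_day = c(baseline = 0.10, day1 = 0.03, day7 = 0.04))
    ),
    seed = seed, ...
  )
}

#' Simulate a whole MWT study
#'
#' Draws one random intercept and one random slope perturbation per
#' participant, builds each session's true slope as cohort/day base slope +
#' siesta bump (14:00 only) + participant perturbation, simulates every
#' session, and returns the long-format design table plus ground truth.
#'
#' @param design a [study_design()] object.
#' @param with_eeg also synthesize a surrogate EEG record per session
#'   (slower; required for the qEEG chain).
#' @return a `study_dataset`: list with `sessions` (list of session_record),
#'   `design_table` (data.frame: participant, cohort, treatment, day,
#'   session_time, isSiesta), `ground_truth` (per-session true parameters),
#'   and `design`.
#' @export
simulate_study <- function(design, with_eeg = FALSE) {
  stopifnot(inherits(design, "study_design"))
  cfg0 <- design$session_config
  siesta_idx <- which(clock_to_min(design$session_times) == clock_to_min("14:00"))

  sessions <- list(); rows <- list(); truth <- list()
  p_global <- 0L
  for (ci in seq_along(design$cohorts)) {
    co <- design$cohorts[[ci]]
    for (pi in seq_len(co$n_participants)) {
      p_global <- p_global + 1L
      pid <- sprintf("%s_%02d", co$label, pi)
      re <- with_seed(derive_seed(design$seed, p_global, 0L, 0L), {
        c(stats::rnorm(1, 0, design$participant_intercept_sd),
          stats::rnorm(1, 0, design$participant_slope_sd))
      })
      a_i <- min(design$intercept_a + re[1], 0)   # keep exp(a) <= 1
      for (di in seq_along(design$days)) {
        day <- design$days[di]
        for (si in seq_along(design$session_times)) {
          is_siesta <- as.integer(si %in% siesta_idx)
          b_true <- unname(co$slope_by_day[day]) +
            design$siesta_slope_bump * is_siesta + re[2]
          sseed <- derive_seed(design$seed, p_global, di, si)
          cfg <- cfg0
          cfg$session_start <- design$session_times[si]
          cfg$seed <- sseed
          sess <- simulate_session(
            trajectory_params(a_i, b_true, design$noise_sd), cfg)
          if (with_eeg) sess$eeg <- synthesize_eeg(sess, cfg)
          key <- length(sessions) + 1L
          sessions[[key]] <- sess
          rows[[key]] <- data.frame(
            participant = pid, cohort = co$label,
            treatment = if (co$label == "placebo") "placebo" else "active",
            day = day, session_time = design$session_times[si],
            isSiesta = is_siesta)
          truth[[key]] <- data.frame(
            participant = pid, day = day,
            session_time = design$session_times[si],
            true_intercept_a = a_i, true_slope_b = b_true,
            sol_analytic_min = sess$ground_truth$sol_analytic_min,
            sol_censored = sess$ground_truth$sol_censored)
        }
      }
    }
  }
  structure(list(sessions = sessions,
                 design_table = do.call(rbind, rows),
                 ground_truth = do.call(rbind, truth),
                 design = design),
            class = "study_dataset")
}
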