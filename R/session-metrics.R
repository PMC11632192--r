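# Per-session MWT endpoints: sleepiness score, log-linear trajectory fits,
# sleep onset latency, microsleep metrics, interpolated KSS.

#' Sleepiness score from a hypnodensity table
#'
#' The sleepiness score per 15-s epoch is the summed probability of all
#' non-wake stages, i.e. `1 - p_W`.
#'
#' @param h data.frame with columns `p_W, p_N1, p_N2, p_N3, p_REM` (an
#'   `epoch_index` column is allowed and ignored).
#' @param tol maximum tolerated deviation of a row sum from 1 (default 1e-3).
#' @return an [epoch_series()] on the 15-s grid.
#' @export
sleepiness_from_hypnodensity <- function(h, tol = 1e-3) {
  cols <- c("p_W", "p_N1", "p_N2", "p_N3", "p_REM")
  if (!all(cols %in% names(h))) stop("hypnodensity must have columns ", paste(cols, collapse = ", "))
  p <- as.matrix(h[cols])
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) stop("stage probabilities must lie in [0, 1]")
  sums <- rowSums(p)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad))
    stop(sprintf("hypnodensity row %d sums to %.4f (must be 1 within %g)",
                 bad[1], sums[bad[1]], tol))
  epoch_series(1 - p[, "p_W"], epoch_len = 15)
}

#' Sleep onset latency result
#'
#' @param sol_min latency in minutes; `censored` is TRUE when no onset was
#'   found within the session. `onset_epoch` is the 0-based index of the
#'   first epoch of the triggering pattern (NA when censored).
#' @noRd
sol_result <- function(sol_min, censored, onset_epoch) {
  structure(list(sol_min = sol_min, censored = censored,
                 onset_epoch = onset_epoch), class = "sol_result")
}

#' Score sleep onset latency from a hypnogram
#'
#' Unambiguous sleep onset is the earliest epoch `e` (0-based) such that
#' epochs `e, e+1, e+2` are all N1, or epoch `e` is any deeper stage
#' (N2, N3 or REM). `sol_min = e * epoch_len / 60`. If the rule never fires
#' the latency is censored at `max_min`.
#'
#' @param stages character vector of stages in `{W, N1, N2, N3, REM}`,
#'   epoch 0 starting at lights-off.
#' @param max_min censoring value in minutes (MWT standard: 40).
#' @param epoch_len hypnogram epoch length in seconds (standard: 30).
#' @return a `sol_result`: `sol_min`, `censored`, `onset_epoch`.
#' @export
score_sol <- function(stages, max_min = 40, epoch_len = 30) {
  if (!length(stages)) stop("empty hypnogram")
  ok <- stages %in% c("W", "N1", "N2", "N3", "REM")
  if (!all(ok)) stop("invalid stage label at epoch ", which(!ok)[1] - 1L,
                     ": ", stages[!ok][1])
  deep <- stages %in% c("N2", "N3", "REM")
  n1 <- stages == "N1"
  n <- length(stages)
  triple <- if (n >= 3) n1[1:(n - 2)] & n1[2:(n - 1)] & n1[3:n] else logical(0)
  cand <- c(which(deep), which(triple))
  if (length(cand)) {
    e <- min(cand) - 1L                 # 0-based
    sol_result(e * epoch_len / 60, FALSE, e)
  } else {
    sol_result(max_min, TRUE, NA_integer_)
  }
}

#' Fit a log-linear trajectory to an epoch series
#'
#' Values are clipped below at 1e-3, natural-log transformed, and regressed
#' on epoch-center time (minutes from lights-off) by ordinary least squares
#' over epochs whose centers fall in `[0, sol_min)` — the growth of
#' sleepiness until sleep onset. For censored sessions the whole series is
#' used. The session average is the mean of the untransformed values over
#' the same window.
#'
#' @param series an [epoch_series()] anchored at lights-off.
#' @param sol a `sol_result` from [score_sol()]; NULL treats the session as
#'   censored (full window).
#' @param min_epochs minimum usable epochs for a valid fit (default 4,
#'   i.e. one minute of 15-s epochs).
#' @param average_window window for the untransformed average: `"fit"`
#'   (default, the same pre-onset window as the regression) or `"session"`
#'   (all valid epochs of the series).
#' @return a `trajectory_fit`: `slope` (1/min, log scale), `intercept`
#'   (log value at lights-off), `average` (untransformed), `n_epochs_used`,
#'   `fit_window_end` (minutes), `valid`.
#' @export
fit_log_trajectory <- function(series, sol = NULL, min_epochs = 4,
                               average_window = c("fit", "session")) {
  stopifnot(inherits(series, "epoch_series"))
  average_window <- match.arg(average_window)
  centers <- epoch_centers(series)
  window_end <- if (is.null(sol) || sol$censored)
    length(series) * series$epoch_len / 60 else sol$sol_min
  use <- series$valid & centers < window_end
  avg_use <- if (average_window == "fit") use else series$valid
  avg <- if (any(avg_use)) mean(series$values[avg_use]) else NA_real_
  n_used <- sum(use)
  if (n_used < min_epochs) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          average = avg,
                          n_epochs_used = n_used, fit_window_end = window_end,
                          valid = FALSE), class = "trajectory_fit"))
  }
  y <- log(pmax(series$values[use], LOG_FLOOR))
  t <- centers[use]
  fit <- stats::lm.fit(cbind(1, t), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 average = avg,
                 n_epochs_used = n_used, fit_window_end = window_end,
                 valid = TRUE), class = "trajectory_fit")
}

#' Microsleep rate and mean duration for one session
#'
#' Rate is the number of microsleeps per complete 30-s epoch between
#' lights-off and lights-on; duration is the arithmetic mean event length.
#' Sessions without microsleeps report 0 for both.
#'
#' @param events data.frame with columns `onset_s`, `duration_s`; durations
#'   must lie in `[3, 15)` seconds.
#' @param session_duration_min session length in minutes (> 0). The whole
#'   session (lights-off to lights-on) is the standard denominator; to rate
#'   events over the pre-onset window only, pass the SOL here instead.
#' @return list `rate` (events / 30-s epoch) and `mean_duration_s`.
#' @export
microsleep_metrics <- function(events, session_duration_min) {
  if (session_duration_min <= 0) stop("session_duration_min must be positive")
  n_epochs <- floor(session_duration_min * 2)
  if (n_epochs < 1) stop("session shorter than one 30-s epoch")
  if (is.null(events) || nrow(events) == 0)
    return(list(rate = 0, mean_duration_s = 0))
  d <- events$duration_s
  bad <- which(d < 3 | d >= 15)
  if (length(bad))
    stop(sprintf("microsleep duration %.2f s outside [3, 15) at event %d",
                 d[bad[1]], bad[1]))
  list(rate = nrow(events) / n_epochs, mean_duration_s = mean(d))
}

#' Interpolate a KSS measurement series to a session time
#'
#' Linear interpolation in clock time between the nearest bracketing
#' measurements; a session time coinciding with a measurement returns that
#' score; times outside the measurement span return NA (no extrapolation).
#'
#' @param kss data.frame with `clock_time` ("HH:MM" or minutes since
#'   midnight, strictly increasing) and `score` (1-9).
#' @param session_time clock time of the session.
#' @return interpolated score, or NA if out of span.
#' @export
interpolate_kss <- function(kss, session_time) {
  if (!all(c("clock_time", "score") %in% names(kss)))
    stop("kss needs columns clock_time, score")
  tm <- clock_to_min(kss$clock_time)
  if (any(diff(tm) <= 0)) stop("KSS measurement times must be strictly increasing")
  if (any(kss$score < 1 | kss$score > 9)) stop("KSS scores must lie in [1, 9]")
  at <- clock_to_min(session_time)
  if (at < min(tm) || at > max(tm)) return(NA_real_)
  stats::approx(tm, kss$score, xout = at)$y
}

#' Compile the per-session endpoint table for a simulated study
#'
#' One row per participant x day x session with the study's ten endpoints:
#' SOL, microsleep rate and duration, sleepiness average/slope/intercept,
#' theta/alpha average/slope/intercept, and interpolated KSS; plus
#' `inverse_sol = 1/sol_min` (kept for censored sessions, flagged),
#' `isSiesta` (the 14:00 session slot), and `slope_analysis_eligible`
#' (`sol_min > 1` minute, the reliability filter for slope correlations).
#'
#' Theta/alpha endpoints are computed through the qEEG chain when sessions
#' carry an EEG record (see [simulate_study()] `with_eeg`), otherwise NA.
#'
#' @param study a `study_dataset` from [simulate_study()].
#' @param kss optional data.frame (`participant`, `clock_time`, `score`)
#'   of KSS self-ratings; interpolated to each session's clock time.
#' @param filter_cfg [filter_config()] used for the qEEG chain.
#' @return data.frame, one row per session.
#' @export
compile_endpoints <- function(study, kss = NULL, filter_cfg = filter_config()) {
  stopifnot(inherits(study, "study_dataset"))
  dt <- study$design_table
  key <- paste(dt$participant, dt$day, dt$session_time)
  if (anyDuplicated(key)) stop("duplicate (participant, day, session) keys")
  rows <- vector("list", length(study$sessions))
  for (i in seq_along(study$sessions)) {
    sess <- study$sessions[[i]]
    sol <- sess$sol
    sleep_series <- sleepiness_from_hypnodensity(sess$hypnodensity)
    sfit <- fit_log_trajectory(sleep_series, sol)
    ms <- microsleep_metrics(sess$microsleeps, sess$duration_min)

    ta_avg <- ta_slope <- ta_int <- NA_real_
    if (!is.null(sess$eeg)) {
      ta <- theta_alpha_epochs(sess$eeg, cfg = filter_cfg)
      tfit <- fit_log_trajectory(ta, sol)
      ta_avg <- tfit$average; ta_slope <- tfit$slope; ta_int <- tfit$intercept
    }
    kss_val <- NA_real_
    if (!is.null(kss)) {
      sub <- kss[kss$participant == dt$participant[i], , drop = FALSE]
      if (nrow(sub))
        kss_val <- interpolate_kss(sub[order(clock_to_min(sub$clock_time)), ],
                                   dt$session_time[i])
    }
    rows[[i]] <- data.frame(
      sol_min = sol$sol_min, sol_censored = sol$censored,
      inverse_sol = 1 / sol$sol_min,
      slope_analysis_eligible = sol$sol_min > 1,
      microsleep_rate = ms$rate, microsleep_duration = ms$mean_duration_s,
      sleepiness_avg = sfit$average, sleepiness_slope = sfit$slope,
      sleepiness_intercept = sfit$intercept,
      theta_alpha_avg = ta_avg, theta_alpha_slope = ta_slope,
      theta_alpha_intercept = ta_int,
      kss = kss_val)
  }
  cbind(dt, do.call(rbind, rows))
}
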