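# mwtbio — EEG biomarkers for the Maintenance of Wakefulness Test

The Maintenance of Wakefulness Test (MWT) is the standard objective measure
of daytime sleepiness: four 40-minute trials a day in which a participant
tries to stay awake, scored by the latency to unambiguous sleep onset
(SOL — three consecutive 30-s epochs of N1, or one epoch of N2/N3/REM).
SOL alone says nothing about how drowsy a participant was *before* falling
asleep. This package implements, for sleep researchers and trial
statisticians, the biomarkers that fill that gap:

- **microsleep metrics** — rate (events per 30-s epoch) and mean duration
  of brief sleep intrusions (≥ 3 to < 15 s);
- **sleepiness score** — per 15-s epoch, `1 − P(wake)` summed from
  hypnodensity (automated sleep-staging probability) tables;
- **θ/α ratio** — EEG power in 4–8 Hz over 8–12 Hz, computed every 2 s by
  DPSS multitaper spectra at 0.5 Hz resolution after zero-phase 0.1–55 Hz
  band-pass filtering and rule-based artifact rejection, averaged to 15-s
  epochs;
- **trajectory endpoints** — per session, ordinary least squares of the
  log-transformed sleepiness score (or θ/α ratio) on time from lights-off,
  over the window up to sleep onset:

  $$\log S(t) = a + b\,t, \qquad t \in [0, \mathrm{SOL}),$$

  giving a slope *b* (1/min; the rate of sleepiness growth), an intercept
  *a* (sleepiness at lights-off), and the window average.

With a shared intercept, SOL is the time the latent sleepiness crosses the
sleep-onset threshold, so `1/SOL ∝ b` — steeper slopes mean faster sleep
onset. That threshold-crossing mechanism, and the calibration of the
statistics built on it, are what this package's tests establish.

Since no clinical recordings are distributable, the package includes a
synthetic MWT study generator with known ground truth (log-linear latent
trajectories, hypnodensities, hypnograms, microsleep point processes,
surrogate EEG with sleepiness-tracking α/θ oscillators), plus the study
statistics: linear mixed-effects models
(`endpoint ~ day * treatment + isSiesta + (1 | participant)`) with
change-from-baseline contrasts, a prior-stabilized Bayesian mixed model
(`N(0, t)` priors on non-intercept fixed effects, Gibbs sampling,
WAIC/PSIS-LOO hyperparameter sweep) for endpoints with degenerate cells
such as all-zero microsleep counts, and repeated-measures correlation.

## Worked example

Simulate one 14:00 MWT session whose log sleepiness starts at −2 and grows
at 0.1/min with log-scale noise 0.2, then score it end to end:

```r
library(mwtbio)

cfg  <- sim_session_config(session_start = "14:00", seed = 7)
sess <- simulate_session(trajectory_params(intercept_a = -2, slope_b = 0.1,
                                           noise_sd = 0.2), cfg)

sess$sol$sol_min                         # scored sleep onset latency
fit <- fit_log_trajectory(sleepiness_from_hypnodensity(sess$hypnodensity),
                          sess$sol)
ms  <- microsleep_metrics(sess$microsleeps, sess$duration_min)
ta  <- fit_log_trajectory(theta_alpha_epochs(synthesize_eeg(sess, cfg)),
                          sess$sol)
```

Output:

```
SOL: 13.0 min (censored: FALSE)
sleepiness slope: 0.0921 /min, intercept: -1.904, average: 0.292
microsleeps: 4 events, rate 0.133 /epoch, mean duration 10.4 s
theta/alpha slope: 0.2990 /min (52 valid epochs)
```

The scored SOL (13.0 min) sits within one stage epoch of the analytic
threshold crossing `(ln 0.5 + 2) / 0.1 = 13.07` min; the fitted slope
0.092/min recovers the generating 0.1/min from a noisy truncated session;
the θ/α slope rises with the same latent trajectory (on its own scale —
the θ/α ratio responds quadratically to the oscillator amplitude ratio).

## The analysis workflow

Numbered drivers under `analysis/` run the full study analysis and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # default 2-cohort study, with EEG
Rscript analysis/02_endpoints.R       # per-session endpoint table
Rscript analysis/03_mixed_models.R    # LMMs + change-from-baseline contrasts
Rscript analysis/04_bayes_sweep.R     # prior-scale sweep on microsleep rate
Rscript analysis/05_correlations.R    # rmcorr of slopes vs inverse SOL
```

Each step's computation lives in the package (`R/`); the scripts are thin
narrative drivers.

## Scope

Hypnodensities are consumed (or simulated), never produced: the
deep-learning staging network that generates them in practice is out of
scope, as are manual scoring itself, automated microsleep detection, count
likelihoods for microsleep endpoints (Hurdle models), and clinical effect
sizes — the latter were computed on trial data that are not publicly
available. See `vignettes/mwt-biomarkers.Rmd` for the models, design
choices, numerical conventions and known limitations.
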