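---
title: "MWT biomarkers: models, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MWT biomarkers: models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwtbio)
```

## The problem

The Maintenance of Wakefulness Test (MWT) asks a participant to stay awake
while sitting in a dark, quiet room, four 40-minute trials a day. Its
standard endpoint, sleep onset latency (SOL), says *when* a participant
falls asleep but nothing about how hard they fought sleep before that
moment. This package implements a family of EEG-derived biomarkers that
fill that gap — microsleep metrics, hypnodensity-derived sleepiness scores,
and quantitative-EEG theta/alpha ratios — together with the statistics used
to analyze them in a small repeated-measures treatment study (narcolepsy
type 1/2 scale: a dozen participants per cohort, three MWT days, four
sessions per day).

Because no clinical data ship with the package, a synthetic study generator
with fully known ground truth stands in for the clinic. Every downstream
stage — scoring, spectral estimation, endpoint compilation, mixed-effects
and Bayesian modeling — is exercised and tested against that generator.

## The latent model

The simulator's core assumption is that log sleepiness grows linearly
during a session. For session time $t$ (minutes from lights-off), latent
sleepiness is

$$ S(t) = \mathrm{clip}\!\left(\exp(a + b\,t + \varepsilon_t),\ 10^{-3},\ 1\right),
\qquad \varepsilon_t \sim N(0, \sigma^2), $$

on a 15-second epoch grid. The intercept $a$ is log sleepiness at
lights-off, the slope $b$ (1/min) is the rate of sleepiness growth, and
$\sigma$ is per-epoch log-scale noise (default 0.2). This makes the
package's trajectory fit — ordinary least squares of log values on
epoch-center time — the *correctly specified* model, so parameter-recovery
tests are sharp: any estimator bias is attributable to windowing and
scoring, not to model mismatch.

All derived artifacts flow from $S(t)$:

* **Hypnodensity** (per 15-s epoch): $P(\text{non-wake}) = S$, allocated
  across stages by a fixed mixing rule — N1 receives fraction
  $\min(1, 2(1-S))$ of the non-wake mass, the remainder goes to N2, and
  N3/REM stay at zero. MWT naps rarely reach N3 or REM; routing mass into
  N2 at high $S$ keeps both clauses of the sleep-onset rule exercised.
  The stored sleepiness series is defined as $1 - p_W$ from the
  hypnodensity table, so reconstruction downstream is bitwise exact.
* **Hypnogram** (per 30-s epoch): stage N2 where mean epoch sleepiness
  exceeds $\theta_{N2}$ (default 0.8), N1 above $\theta_{N1}$ (default
  0.5), wake otherwise.
* **SOL**: scored from the hypnogram with the standard rule — three
  consecutive N1 epochs or a single epoch of deeper sleep; latency is the
  start of the triggering pattern, censored at 40 minutes. For noiseless
  sessions this crosses at $t = (\ln\theta_{N1} - a)/b$, which is the
  analytic ground truth recorded per session. The trial is truncated one
  stage-epoch after the rule fires, mimicking a technician ending the
  trial at unambiguous sleep onset (trial-end handling is not standardized;
  this is the package's choice).
* **Microsleeps**: an inhomogeneous Poisson process with intensity
  `microsleep_base_rate` $\times\, S(t)$ restricted to wake epochs, drawn
  by thinning; durations uniform on $[3, 15)$ s (the defining bounds of a
  microsleep event); overlapping candidates are redrawn at most 100 times
  and then discarded.
* **Surrogate EEG** (optional): pink background noise plus a 10 Hz alpha
  oscillator with amplitude $\propto (1 - S)$ and a 6 Hz theta oscillator
  with amplitude $\propto S$; during microsleep events theta is boosted
  threefold and alpha suppressed to 20% — the alpha-to-theta shift that
  defines a microsleep. Default amplitudes: 30 µV per oscillator at full
  gain, 4 µV RMS pink noise, 256 Hz sampling.

All randomness flows from a single study seed through a documented
per-session derivation (participant, day, session indices hashed into a
32-bit seed), so a study is bit-reproducible.

### What the generator does and does not emulate

The generator reproduces the *mechanisms* the biomarkers rely on: log-linear
sleepiness growth, threshold-crossing sleep onset, sleepiness-modulated
microsleeps, and the spectral alpha-to-theta shift. It does not attempt
realistic EEG morphology (no spindles, K-complexes, EOG/EMG), realistic
hypnodensity confusion structure, or deep-network staging behavior.
Passing tests therefore demonstrate that the pipeline is *correct and
calibrated under its stated model*, not that it reproduces clinical effect
sizes — those were computed on data that are not publicly available.

## The qEEG chain

1. **Filtering** — zero-phase band-pass at 0.1–55 Hz plus configurable
   1-Hz-wide notches. The filter is applied in the frequency domain with
   raised-cosine transition bands (2 Hz), which is zero-phase by
   construction and reaches arbitrary stop-band attenuation; an IIR
   band-pass of practical order cannot attenuate 60 Hz line noise
   meaningfully with a 55 Hz edge (a Butterworth design would need order
   ≈ 27). Notch selection is deliberately manual: `suggest_notches()`
   flags spectral peaks more than 10 dB above the local median floor but
   never applies them.
2. **Artifact rejection** — 2-s windows are rejected by rule: saturation
   (≥ 10 consecutive samples within one least-significant quantum of the
   record's rails), missing (non-finite samples, or a flat run ≥ 0.5 s),
   slew (any sample-to-sample step above 50 µV at 256 Hz, scaled by
   256/fs), and amplitude (peak-to-peak > 500 µV). Saturation is checked
   before the flat-run clause because a rail-pinned run is also flat.
   These thresholds are documented conventions of this package, chosen to
   be conservative for clean wake EEG.
3. **Multitaper spectrogram** — non-overlapping 2-s windows (the minimal
   window giving the 0.5 Hz grid), DPSS tapers with time-bandwidth
   $NW = 2$ and $K = 3$ tapers, eigenvalue-weighted; one-sided PSD in
   µV²/Hz on a 0–Nyquist grid at exactly 0.5 Hz. The tapers are computed
   from the symmetric tridiagonal formulation with concentration
   eigenvalues from the Dirichlet-kernel quadratic form, and cached.
   $NW$ and $K$ are conventional choices; the literature the pipeline
   follows states the step (2 s) and grid (0.5 Hz) but not the window or
   taper parameters.
4. **Band ratio** — per 15-s epoch, surviving window spectra are averaged
   (windows assigned by start time), theta power summed over $[4, 8)$ Hz
   and alpha over $[8, 12)$ Hz — half-open bands so the shared 8 Hz bin is
   counted once — and the ratio taken. An epoch needs at least 4 surviving
   windows (of its ~8) and nonzero alpha power to be valid; the quorum is
   an invented convention.

The occipital channel (O2) is the default analysis channel, where the
alpha rhythm and its drowsiness-related collapse are most visible.

## Per-session endpoints

* `score_sol()` — the SOL rule above, on any hypnogram.
* `sleepiness_from_hypnodensity()` — $1 - p_W$ per epoch, with row sums
  validated to 1 within $10^{-3}$.
* `fit_log_trajectory()` — values clipped below at $10^{-3}$ (sleepiness
  and theta/alpha ratios can be ~0; the floor is shared with the
  simulator), log-transformed, OLS on epoch-center minutes over epochs in
  $[0, \mathrm{SOL})$ — the session's whole span when censored. Returns
  slope, intercept, and the mean of the untransformed values over the same
  window; at least 4 valid epochs (one minute) are required, echoing the
  SOL > 1 min eligibility filter used for slope analyses. Whether the
  session "average" should use the pre-SOL window or the full session is
  a genuinely open choice; the pre-SOL window is the default here so all
  three summary endpoints describe the same data, with a full-session
  switch available.
* `microsleep_metrics()` — events per complete 30-s epoch of the whole
  session, and mean duration; both 0 when no events occurred. The
  denominator uses the whole session (lights-off to lights-on), matching
  the "per epoch during a session" definition.
* `interpolate_kss()` — linear interpolation of Karolinska Sleepiness
  Scale ratings in clock time to the session start; no extrapolation
  (sessions outside the measurement span get NA). Clock time rather than
  session index is the interpolation axis; either is defensible, and clock
  time is the one that respects unequal measurement spacing.
* `compile_endpoints()` — the long-format study table, one row per
  participant × day × session, with `inverse_sol` = 1/SOL retained for
  censored sessions (1/40, flagged) rather than dropped, `isSiesta`
  marking the 14:00 slot by scheduled label, and `slope_analysis_eligible`
  = (SOL > 1 min).

## Statistics

**Mixed model.** Every endpoint is analyzed with
`endpoint ~ day * treatment + isSiesta + (1 | participant)` by REML
(lme4). The single `isSiesta` indicator in place of a full session factor
reflects how the 14:00 session behaves differently from the other three —
the early-afternoon siesta dip in wakefulness — while keeping the model
identical across endpoints. Change-from-baseline contrasts per treatment
arm are explicit linear combinations of fixed effects
($\beta_{\text{day}} + \beta_{\text{day:arm}}$), emitted with their
contrast vectors for audit; inference is Wald (normal approximation),
a documented choice in place of a finite-sample degrees-of-freedom
correction.

**Prior-stabilized Bayesian model.** The same Gaussian random-intercept
model with independent $N(0, t^2)$ priors on all non-intercept fixed
effects (flat on the intercept), fit by a Gibbs sampler with a *joint*
multivariate-normal update for (fixed effects, random intercepts) — block
updates mix poorly because intercept-level effects and the random-intercept
mean trade off — and inverse-gamma IG(0.001, 0.001) updates for the two
variances. The conventional notation $N(0,t)$ is ambiguous between
variance and standard deviation; $t$ is treated as a standard deviation here,
switchable via `prior_spec(t, t_is_sd = FALSE)`. The prior is what keeps
estimates finite in the motivating failure mode: a treatment cell in which
every participant has zero microsleeps, where unpenalized likelihoods send
estimates and standard errors to infinity. Microsleep endpoints are
modeled with a Gaussian response, as the mixed-model framework implies;
count likelihoods (Hurdle models) are explicitly out of scope.

Sampler defaults are 4 chains × 2000 iterations with the first half as
burn-in; split R-hat above 1.1 on any parameter flags the fit unreliable.
Simulation loops in tests and scripts use 2 chains × 600–1000 iterations,
problem sizes chosen so the whole calibration suite runs in minutes at
desk scale while keeping Monte-Carlo error well inside the asserted
margins.

**WAIC / PSIS-LOO.** WAIC is $-2(\mathrm{lppd} - p_{\mathrm{waic}})$ with
the variance-based penalty; LOO uses Pareto-smoothed importance sampling
(generalized-Pareto tail fit by the Zhang–Stephens profile-likelihood
method) with the shape diagnostic $k$ per observation and an exact-refit
fallback for $k > 0.7$. The prior scale is chosen by sweeping a grid of
$t$ values and selecting the inflection of the LOO curve — implemented as
the interior grid point with the largest discrete second difference of
elpd against $\log t$, flagged "weak" when that curvature is within the
Monte-Carlo error of the elpd differences. Clinical applications of this
prior-stabilization approach have reported clear inflections near
$t \approx 3$; any such value is data-specific, so the package reports
whatever its own sweep selects on the data at hand.

**Repeated-measures correlation.** The subject-adjusted ANCOVA
formulation: $y$ on subject indicators plus $x$ with a common slope;
$r = \mathrm{sign}(\hat\beta_x)\sqrt{SS_x / (SS_x + SS_{err})}$ with
$N - k - 1$ degrees of freedom. Implemented directly (not wrapped) and
tested against a brute-force two-model ANCOVA oracle to $10^{-10}$.

## The headline mechanism

With a shared intercept $a$, the analytic SOL is
$(\ln\theta_{N1} - a)/b$, so $1/\mathrm{SOL} \propto b$: sessions in which
log sleepiness grows faster cross the sleep-onset threshold sooner. The
package's end-to-end checks reproduce this coupling on synthetic studies —
repeated-measures correlation of the fitted sleepiness slope with inverse
SOL ≥ 0.9 among SOL > 1 min sessions, and of the sleepiness slope with the
theta/alpha slope ≥ 0.7 when both are computed from the same synthesized
EEG. These are the synthetic analogues of the strong correlations between
slope endpoints and inverse SOL reported in clinical MWT analyses;
agreement of the mechanism, not of the clinical coefficients, is what the
tests establish.

When building the slope ladder for the noiseless proportionality check,
slopes are kept below ~0.3/min: beyond that the deeper-stage clause of the
SOL rule (crossing $\theta_{N2}$) fires before three N1 epochs can
accumulate, and the proportionality constant changes — a scoring-rule
regime switch, not an estimator defect.

## Calibration results and known limitations

* Trajectory recovery: over 200 noisy sessions ($\sigma = 0.2$,
  $b \in [0.02, 0.2]$/min) the median relative slope error is well under
  10%; noiseless sessions recover slope and intercept to machine
  precision.
* The day × treatment Wald test holds its nominal 5% level (empirically
  within [0.02, 0.09] over 200 session-level null studies).
* **Heteroscedasticity caveat.** Per-session slope *estimates* carry
  measurement error whose variance grows as SOL shrinks (fewer epochs in
  the fit window). The homoscedastic LMM understates the sampling
  variability of cell contrasts that differ systematically in SOL — for
  the isSiesta coefficient on full session-level simulations, 95% Wald
  intervals covered ≈ 84% of the time despite an unbiased estimate. CI
  coverage is therefore verified under the model-true endpoint-level
  generator (`simulate_endpoint_table()`), where it sits inside
  [0.90, 0.98]; analysts applying the session-level pipeline to real data
  should expect the same optimism in contrast SEs whenever SOL differs
  strongly across cells.
* The generator's microsleep process is restricted to wake epochs, where
  latent sleepiness is capped near the N1 threshold by construction, so
  the per-epoch microsleep rate varies little between short- and long-SOL
  sessions; the (clinically expected) positive coupling between microsleep
  rate and inverse SOL is weak and unstable in sign on default synthetic
  studies. The microsleep *metrics* and their statistics are exact; it is
  this particular cross-endpoint correlation that the generator does not
  emulate.
* The artifact detector's thresholds are conventions; its operating
  characteristics (sensitivity ≥ 0.95, false-positive rate ≤ 0.05) are
  established on injected faults, not on real artifact morphology.
* Degenerate inputs: all-zero series fit with slope 0 at the clipping
  floor; all-rejected windows produce an all-invalid epoch series rather
  than an error; empty microsleep tables are valid and yield (0, 0).

## Problem sizes

Default study: 2 cohorts × 4 participants × 3 days × 4 sessions
(96 sessions). Simulation-based checks use 200 replicates for calibration
rates, 50 for model selection, and 2-chain/600–1000-iteration samplers;
the full default pipeline including EEG synthesis and the qEEG chain for
every session runs in well under five minutes on one CPU.
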