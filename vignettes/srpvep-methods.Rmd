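---
title: "Measuring short- and long-term visual cortical plasticity from chronic VEP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring short- and long-term visual cortical plasticity from chronic VEP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

A contrast-reversing grating shown to a head-fixed mouse evokes, at every
reversal, a stereotyped deflection of the layer-4 local field potential
(LFP): a visual evoked potential (VEP) with a fast negative trough followed
by a positive peak. Because the stimulus is passive and the animal merely
sits (or runs) on a wheel, the VEP amplitude can be tracked for weeks, and
it exposes two forms of intrinsic plasticity at once:

* **Stimulus-response potentiation (SRP)** — across days of repeated
  exposure, the VEP to the now-familiar grating grows and saturates, an
  LTP-like long-term effect. An orthogonal ("unfamiliar") grating shown
  only on the first and last day controls for stimulus specificity.
* **Adaptation** — within a stimulation block of continuous reversals,
  the amplitude decays over tens of reversals towards a steady state, a
  classic short-term suppression (except in the first block of a session,
  where responses instead build up).

Both effects ride on top of behavioural-state modulation: running
suppresses the visual response, and arousal (indexed by pupil size)
co-varies with locomotion. A pipeline that wants to attribute amplitude
changes to plasticity must therefore carry the wheel and pupil channels
through the analysis.

`srpvep` implements the full chain — session synthesis with known ground
truth, signal conditioning, VEP metrics, SRP and adaptation estimation,
behavioural-state conditioning, a regularisation-path regression for
attributing amplitude variance, and the group statistics — as composable
functions plus a one-call `run_pipeline()`.

## Protocol and conventions

The default protocol is 9 daily sessions of 10 blocks x 200 contrast
reversals at 1.95 Hz (reversal period 1/1.95 s ~ 0.513 s), blocks separated
by 30 s of grey screen, with familiar/unfamiliar blocks alternating on days
1 and 9. Two conventions are fixed throughout and stated here because the
literature usually leaves them implicit:

* **Epoch windows are half-open and 0-based in time**: epoch *i* holds the
  samples in `[t_i, t_i + period)`, with time 0 at the reversal event.
* **Average-then-metric**: wherever a waveform summarises several epochs
  (daily VEPs, 20-reversal bins), the epochs are averaged first and the
  trough/peak metric is taken from the mean waveform. The alternative —
  metric per epoch, then averaging — is systematically inflated on noisy
  data by the extreme-value bias of the per-epoch max/min search; the test
  suite demonstrates the difference. Per-epoch metrics are used only where
  the analysis genuinely needs a per-reversal target (the regression).

## Signal conditioning

Wide-band recordings are decimated to 1 kHz with an 8th-order Chebyshev
type I lowpass (0.01 dB passband ripple, corner at 0.4 x output Nyquist,
factors above 10 split into stages). For VEP extraction the 1 kHz trace is
band-passed 0.3–50 Hz with a 2nd-order Butterworth. Both filters are
applied forward–backward (zero phase): latency measures (time-to-trough,
time-to-peak) would otherwise be shifted by the filter group delay. The
0.01 dB ripple is chosen because forward–backward application squares the
transfer function; at 0.05 dB the squared ripple would already eat the 1%
passband-amplitude budget the tests enforce. The band-pass is applied to
the continuous trace, not per epoch, so block-onset transients are shared
by all epochs of a block rather than re-excited at every reversal.

VEP metrics follow the standard windows: trough = minimum within 150 ms of
the reversal, peak = maximum within 250 ms, amplitude = peak − trough.
Ties break to the earliest sample. FWHM is measured per deflection at half
the deflection's extremum relative to 0 uV (the band-passed signal is
zero-mean; a pre-reversal baseline would re-introduce the noise of a short
window), with linear interpolation at the crossings, and is reported
missing when a deflection never returns to half inside the epoch. The
decay slope is the least-squares slope from the peak to the first return
to half-peak, capped at the epoch end.

## Behavioural state

Wheel counts become speed via `circumference / resolution`, smoothed with
a 50 ms Gaussian window (kernel sd = window/4, truncated at +-2 sd). An
epoch is *running* when its mean speed exceeds 1 cm/s, *stationary*
otherwise; a mean speed of exactly 1 cm/s is classed stationary, since the
strict inequalities of the usual definition leave the boundary
unassigned. Blink samples are those whose eye position deviates from the
coordinate median by more than twice the coordinate sd — the median
resists the blink outliers themselves, the sd keeps the criterion in
pixels — and are replaced (position and area) by the nearest clean
sample. The criterion is applied per coordinate rather than radially; with
the default multiplier the two are nearly equivalent, and the multiplier
is exposed for sensitivity analysis. Pupil area is normalised either to
the 2 minutes of grey screen before stimulus onset (the default) or to the
stationary samples of the final 12 s before onset (the convention for
event-triggered pupil responses, where running-driven dilation must not
contaminate the baseline). Both are kept because both are defensible and
they answer different questions; the event-triggered variant is the one
`analyze_session()` uses for the stimulus-onset response.

## SRP across days

`daily_amplitudes()` averages each session's epochs per familiarity (and
optionally per state) and takes the amplitude of the mean waveform;
`srp_change()` subtracts each animal's day-1 amplitude *within animal*
before any group averaging, so between-animal baseline differences cancel
exactly. A convenient scalar summary of a group's day course is the
saturating growth fit `delta(d) = delta_max * (1 - exp(-(d-1)/tau_d))`
(`fit_srp_growth()`), profiling `delta_max` in closed form and searching
`tau_d` by golden section; `delta_max` estimates the plateau change and
`tau_d` the growth rate in days.

## Within-block adaptation

The within-block timecourse is built from non-overlapping 20-reversal
bins (average-then-metric), reported at bin centres `(k - 0.5) * 20` with
1-based bins. Each block's steady state — the mean over its final 100
reversals — is subtracted, curves are averaged over a block set (2–10,
2–5 or 6–10; block 1 is always excluded because its rising profile is not
adaptation) and over the familiar-only days, and the result is fitted with
`A * exp(-(n - 1)/tau)`.

Two numerical choices matter here:

* **Steady-state window.** With 200-reversal blocks, subtracting the mean
  of the *last 200* reversals would subtract the whole block mean —
  including the adaptation transient itself — which biases the fitted
  amplitude upward by roughly a third under the projection fit. The
  package therefore defaults to the last 100 reversals (for which the
  tail of an 8.4-reversal exponential is numerically zero) and leaves the
  window as an argument.
* **Bin-mean basis.** The curve consists of bin means, so the regression
  basis is the exact per-bin mean of `exp(-(n-1)/tau)` (closed form), not
  the exponential evaluated at the bin centre. At tau ~ 8.4 reversals the
  first bin's mean (0.40) is a third larger than its centre value (0.30);
  using the centre value would overestimate the amplitude by the same
  factor. With the bin-mean basis, noiseless recovery is exact.

* **Stationary conditioning.** By default the adaptation curves use only
  stationary epochs (`adaptation_analysis(state = "stationary")`; the
  all-epoch variant remains available). Locomotion multiplies the VEP
  amplitude by a gain below one, and running bouts last about as long as
  one 20-reversal bin, so all-epoch curves carry large, bin-correlated
  state noise. A curve-level Monte-Carlo at the default study scale shows
  the all-epoch pooled-tau estimate is unbiased but has a sampling sd of
  ~1.6 reversals — too noisy to be useful — while the stationary subset
  (the large majority of epochs) removes that error term entirely.
  Conditioning also means the fitted amplitude estimates the stationary
  adaptation amplitude directly, without the `1 - p(1-g)` mixture
  shrinkage of pooled epochs.

For fixed tau the least-squares amplitude is the closed-form projection
`A = sum(y*b) / sum(b^2)`. The shared tau is estimated once, from the
grand-mean curve over all animals, days 2–8 and blocks 2–10
(`fit_pooled_tau()`), and then reused as the fixed constant of every
per-session fit — per-session curves are too noisy to constrain a
two-parameter fit, and a common time constant makes the amplitudes
comparable. The pooled estimate from the analysed dataset itself is used
rather than any literature constant, because the time constant is a
property of the dataset; an externally fixed value can be supplied via
`tau_fixed`. Fits are performed per animal-day (one session), the finest
grain the data support; cumulative histograms over sessions are a
reporting view of the same fits.

## Regularisation-path regressor impact

To ask how much of the per-reversal amplitude variance is carried by time
(day, block) versus behaviour (speed, pupil), one model per animal
regresses the single-epoch amplitude on the four regressors, all min-max
normalised to [0, 1]. Rather than selecting one penalty by
cross-validation, the elastic-net is solved along the whole penalty path
and each regressor's impact is its contribution summed over the path:

    M(r_i) = [ sum_l sum_t w_{i,l} r_{i,t} ] / [ sum_l sum_t yhat_{l,t} ] * 100

Because both double sums factorise, the metric needs only the path
coefficients and the design's column sums; a naive double-loop oracle
verifies the identity in the tests to 1e-10.

Numerical choices:

* **Mixing.** The penalty is
  `lambda * (alpha * ||w||_1 + (1-alpha)/2 * ||w||_2^2)` with
  `alpha = 2/3`, i.e. an L1:L2 mixing ratio `alpha/(1-alpha)` of 2.
  The ratio statement is ambiguous between parameterisations, so `alpha`
  is an argument.
* **Grid.** `L = 10000` log-spaced penalties from `lambda_max` (the
  smallest penalty that zeroes all weights, computed from the KKT
  conditions) down to `1e-4 * lambda_max`.
* **Intercept.** The model includes an intercept (the normalised target
  has mean ~ 0.5; without one the weights would absorb it). The impact
  numerator contains only regressor terms; the denominator includes the
  intercept contribution by default, and the regressor-only denominator is
  reported alongside since either convention is defensible.
* **Solver.** Fitting is delegated to glmnet. glmnet standardises the
  response internally, which rescales the effective L2 penalty by
  `1/sd(y)`; `fit_enet_path()` adjusts `(lambda, alpha)` so the objective
  above holds exactly in the user's units — the ridge and OLS limit tests
  check this against closed forms.
* **Target.** The regression uses the familiar-stimulus reversals of all
  days; unfamiliar blocks follow a different day-course by design and
  would contaminate the day regressor.

## Group statistics and tau burden

`rm_anova()` is a univariate repeated-measures ANOVA
(`aov` with an `Error(subject/within)` stratum), with one within factor,
an optional between factor, subjects missing any within level excluded
with a warning, and no sphericity correction by default
(Greenhouse–Geisser is available behind a flag; the analyses this package
reproduces reported none). Post hoc contrasts use estimated marginal means
with Tukey adjustment; at two levels this reduces exactly to the
unadjusted paired test, and on balanced designs it matches the
studentised-range closed form. Degenerate conventions are explicit: a
zero-variance effect gives F = 0, p = 1; two identical zero-variance
samples give t = 0, p = 1.

Histological tau burden: per region of interest a normal distribution is
fitted to the grey levels (maximum likelihood, i.e. sample mean and sd; a
histogram least-squares fit would add binning choices without adding
information), ROI means are averaged per animal, z-scored across animals
within region (denominator n−1), and sign-inverted so that darker DAB
staining — lower grey level, more tau — maps to larger positive burden.
Z-scoring is per region: the two regions' staining batches are not
assumed comparable.

## The synthetic generator

`simulate_session()` builds a raw session from known parameters so every
downstream stage is testable by parameter recovery. The LFP is a sum of
per-reversal scaled copies of an analytic VEP template, pink (`1/f`) noise
and white noise. The template is a piecewise smoothstep curve through
(onset, 0) → (trough latency, trough amplitude) → (peak latency, peak
amplitude) → (offset, 0) with zero slope at the anchors, so its extrema
equal the configured amplitudes exactly and samplings at different rates
agree at shared times. Reversal times are quantised to the LFP sample
grid, as they are in a real rig where the photodiode is digitised on the
recording clock; this makes the noise-free amplitude identity exact.

The per-reversal amplitude is

    level(day, familiarity)
      * block-1 rising profile OR (1 + adaptation excess)
      * running gain if the state is running

with `level` following the saturating SRP growth above, adaptation excess
`A * exp(-(n-1)/tau)` added in blocks 2+, and block 1 rising as
`1 - 0.35 * exp(-(n-1)/25)` (the rising shape is not characterised in the
literature; a saturating exponential with its own constant is the simplest
form with the right signature). Behavioural state is a two-state Markov
chain at 1 s resolution (mean running-bout length 10 s, per-group
occupancy), running speeds are log-normal (median 8 cm/s), wheel counts
integrate the speed through the encoder resolution, and the pupil trace
carries baseline noise, running-linked dilation, Poisson blinks, and — on
day 1, in the group that shows visually evoked behaviour — a
stimulus-onset dilation transient.

Default group parameters are anchored to the published 5-month cohort
values: SRP plateau change 90 uV (tau 1.3 d) for the
doxycycline-suppressed group versus 60 uV (tau 3.0 d) for the
mutant-tau-expressing group (these produce day-3 changes of ~71 and
~26 uV); unfamiliar day-9 changes 53 and 29 uV; adaptation amplitudes 42
and 28 uV with tau = 8.4 reversals; running occupancies 0.17 and 0.10
with a running amplitude gain of 0.8; recording noise 25 uV white plus
30 uV pink. Between-animal variability (CV 0.2 on baseline, SRP gain and
adaptation amplitude; 5 uV day-level jitter) is the package's own choice:
large enough that group statistics face realistic heterogeneity, small
enough that a 12-animal group recovers its injected means to a few
percent. Ground truth is emitted alongside each session but written to a
separate file that the analysis loaders never read.

What the generator deliberately does *not* emulate: spiking activity,
laminar structure, artifacts other than blinks, eye movements and
saccades, slow electrode drift, and any coupling between plasticity and
behaviour (injected SRP is independent of the simulated running, which is
exactly what makes the regression's null behaviour testable). Passing
recovery tests therefore shows the estimators are correct under the
model's assumptions, not that real recordings satisfy those assumptions.

## Verification scale and limitations

The test suite verifies oracle equivalence (exhaustive-scan metrics, the
double-loop impact oracle, closed-form projections, ridge/OLS limits),
statistical calibration (type-I error of the repeated-measures ANOVA over
500 null replicates), and parameter recovery on a simulated study of 2
groups x 12 animals x 9 days at default noise, where the injected SRP
plateau, adaptation amplitude and time constant are each recovered within
15%. Unit tests run on scaled-down protocols (3 blocks of 60 reversals)
because every protocol dimension is an explicit configuration field.

Known limitations: the per-epoch amplitude estimator carries an
extreme-value bias under noise (it cancels in steady-state-subtracted
curves and is quantified against a Monte-Carlo oracle in the tests); the
fixed-tau amplitude inherits any error in the pooled tau, whose sampling
sd at the default study scale is roughly half a reversal (~6%) with
stationary conditioning and ~1.6 reversals if all epochs are pooled, so
occasional simulated cohorts land outside a 15% band around the injected
value; the band-pass attenuates the measured amplitude by up to ~1%
relative to the injected level; and the RM-ANOVA assumes sphericity
unless the Greenhouse–Geisser flag is set.
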