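---
title: "Measuring the dynamics of SSVEP suppression with ssvepdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the dynamics of SSVEP suppression with ssvepdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepdyn)
library(dplyr)
```

## The measurement problem

When two stimuli flicker at different frequencies (here 5 and 7 Hz), each
drives a steady-state visual evoked potential (SSVEP) at its own frequency,
so the neural response to each stimulus can be read out separately from the
Fourier spectrum of occipital EEG/MEG. Divisive normalization predicts that
adding a second ("mask") component reduces the tagged response to the
first: the ratio of the target-alone amplitude to the masked amplitude is a
direct, time-resolvable index of suppression. The question this package
addresses is *how that suppression evolves over the first seconds of
stimulation* — normalization reweighting predicts the suppressive weight
between co-occurring stimuli grows with continued joint presentation.

`ssvepdyn` implements the full measurement chain: a forward model that
simulates epoched recordings with known ground truth, container I/O,
exact-frequency sliding-window amplitude estimation, complex-domain trial
rejection, dB suppression metrics, and cluster-corrected permutation
inference. Because real recordings of this kind are large external
deposits, the package's validation rests on the synthetic generator, whose
programmed dynamics the pipeline must recover.

## The forward model

Each participant's virtual occipital channel is simulated as

$$ s(t) \;=\; \sum_i A_i \, g_i(t)\, e(t) \sin(2\pi f_i t + \phi_i) \;+\; \eta(t), $$

with components at the fundamentals (5, 7 Hz), their second harmonics
(10, 14 Hz, amplitude `harmonic_gain` times the fundamental), and — in
plaid conditions only — a sum intermodulation term at 12 Hz. The divisive
gain applied to each tagged component is

$$ g_i(t) = \frac{1}{1 + w(t)\, m_i}, \qquad
   w(t) = w_0 + (w_\infty - w_0)\,\bigl(1 - e^{-t/\tau}\bigr), $$

where $m_i$ is the competing component's drive (0 when the stimulus is
shown alone, `mask_drive` = 1 in plaids) and $w(t)$ is the exponentially
reweighted suppressive weight, with separate asymptotes for monocular and
dichoptic mask arrangements. The programmed suppression in dB is therefore
$20\log_{10}(1 + w(t)m)$, rising from onset with time constant $\tau$.
This divisive form is a modelling choice: the measurements it must support
are ratio-based, and $g = 1/(1+wm)$ maps the latent weight monotonically
onto dB suppression. A single-exponential $w(t)$ is the minimal dynamic
consistent with suppression that strengthens over the first few seconds;
nothing in the analysis chain assumes it.

Remaining ingredients, each with a configurable knob in `sim_config()`:

* **Onset transient** `e(t)`: a multiplicative damped burst
  $1 + a\,e^{-t/\tau_e}$ (default $a = 0.5$, $\tau_e = 0.5$ s) applied to
  every component. Because it multiplies numerator and denominator
  conditions alike, it cancels in suppression ratios.
* **Noise** $\eta(t)$: $1/f^\beta$ noise (default $\beta = 1$, SD 1 µV)
  whose SD is multiplied by `iti_noise_multiplier` (default 2) outside the
  stimulation period, emulating the elevated broadband activity seen
  between trials; the ratio analysis must be robust to it. The shape of
  the transient and of the inter-trial noise spectrum are stipulations,
  not claims about physiology.
* **Participant heterogeneity**: fundamental amplitudes drawn per
  participant and frequency from a normal distribution (mean 2 µV, SD
  0.5 µV, truncated at 10% of the mean); phases uniform.
* **Artifacts**: a fraction `artifact_rate` (default 2%) of trials is
  replaced by broadband noise at 10 times the noise SD — the QC stage's
  quarry.

Default trial structure: 6-s stimulation, 3-s inter-trial interval,
epochs from 1.5 s before onset to 1.5 s after offset, 48 trials per
condition, 1 kHz sampling, four conditions (`alone_f1`, `alone_f2`,
`plaid_mon`, `plaid_dich`).

What the generator does *not* emulate: volume conduction and realistic
electrode geometry (one virtual occipital channel, optionally replicated
with independent noise), eye movements and blinks as structured artifacts,
drifting alpha rhythms, or any history dependence *across* trials. Tests
passing on this generator therefore validate the estimator chain — not
the physiological claim — on data whose spectral structure, SNR and
artifact burden are in the right regime.

## The analysis chain

1. **Channel averaging** (`average_channels()`): arithmetic mean of the
   analysis channels (classically Oz, POz, O1, O2) per trial.
2. **Trial QC** (`reject_outliers()`): one complex Fourier coefficient per
   trial and tagged frequency over the full stimulation period; a trial is
   excluded when the Mahalanobis distance of its (Re, Im) pair from its
   condition's mean exceeds 3. Under a Gaussian null the squared distance
   is $\chi^2_2$, so the threshold removes $e^{-4.5} \approx 1.1\%$ of
   clean trials per frequency. The default excludes a trial flagged at
   *any* analysed frequency (more sensitive to single-frequency
   artifacts); a joint 4-D distance over both frequencies is available via
   `joint = TRUE`. Distances are condition-local, and the plain sample
   mean/covariance is used.
3. **Coherent averaging** (`coherent_average()`): pointwise mean of the
   surviving trials per condition, attenuating non-phase-locked noise by
   $1/\sqrt{K}$.
4. **Sliding-window amplitude** (`sliding_timecourse()`): at each centre
   on a 10-ms step grid, the modulus of
   $\tfrac{2}{N}\sum_n s_n e^{-2\pi i f n / f_s}$ over a 1-s rectangular
   window. One second makes every integer frequency an exact bin, so no
   taper is needed and an on-bin sinusoid's modulus equals its amplitude
   exactly. Windows are centred; edge windows extending past the epoch are
   dropped rather than padded. A fixed-phase variant
   (`fixed_phase_timecourse()`) projects each window onto a sine of fixed
   frequency and phase (estimated once from the whole trial) and agrees
   with the modulus course for phase-locked signals.
5. **Suppression ratios** (`suppression_timecourses()`):
   $20\log_{10}\bigl(\max(A_\text{alone}, \epsilon)/\max(A_\text{masked},
   \epsilon)\bigr)$ with an amplitude floor $\epsilon = 10^{-3}$ µV that
   keeps noise-free ratios finite; both the raw ratio and dB are emitted.
   dB (amplitude, not power, convention) is used for all averaging and
   statistics; pooling across frequencies/mask types is the arithmetic
   mean in dB (`pool_timecourses()`).
6. **Effect size** (`window_effect_size()`): paired Cohen's *d* across
   participants of the late-window minus early-window mean suppression
   (defaults 0–1 s vs 3–4 s); a pooled-SD flavour is exposed via
   `method = "pooled"`.
7. **Cluster statistics** (`cluster_test_increase()`,
   `cluster_test_groups()`): described below.
8. **Display smoothing** (`spline_smooth()`): cubic smoothing splines for
   plots only; smoothed tibbles carry a flag and every statistical routine
   rejects them.

### Cluster-corrected inference

The trend test asks whether suppression increases over time: at each
window centre $t_c$, a paired one-sample *t* over participants of
$y(t_c + \mathrm{lag}/2) - y(t_c - \mathrm{lag}/2)$ with lag 1 s. Maximal
runs of adjacent centres exceeding the one-sided $\alpha = 0.05$ *t*
quantile form clusters scored by their summed *t*. The null distribution
flips the sign of each participant's whole difference series at random
(the exchangeable null for a one-sample design with symmetric noise) 1,000
times, recording the maximum cluster sum; a cluster is significant when
its sum exceeds the null's 95th percentile. The group test replaces the
pointwise statistic with a two-sided pooled-variance two-sample *t* and
the null with random reassignment of participants to groups of the
original sizes, comparing |summed *t*| against the null maximum.

Choices worth making explicit, since the procedure leaves them open: the
cluster-forming $\alpha$ is 0.05 (the conventional default); the trend
test is one-sided (an *increase* is the hypothesis) while the group test
is two-sided; label shuffling cannot apply to a one-sample trend design,
so participant-level sign flipping is the permutation unit there;
zero-variance pointwise differences map to a $\pm\infty$ sentinel that
counts as supra-threshold; the critical value is the 95th percentile of
the permutation maximum (a one-sided max-statistic reading of "outside
the 95% confidence limits"). The median split used for trait-based group
comparisons sends ties to the low group (`split_groups()`).

## Numerical behaviour and degenerate inputs

* **Window blur and ratio cancellation.** A 1-s window blurs amplitude
  dynamics over a 1-s support. For any *constant* gain applied from
  onset, the blur is identical in numerator and denominator and cancels
  exactly in the ratio — `blur_cancellation_diagnostic()` verifies this to
  machine precision, including windows straddling the onset. For a
  *time-varying* gain the measured course equals the window-averaged gain
  trajectory; `true_suppression_db(..., window_s = 1)` supplies that
  blurred ground truth. An exponential $w(t)$ survives windowing with its
  time constant intact (the window average of $1 - e^{-t/\tau}$ is
  $1 - c\,e^{-t/\tau}$), so exponential fits to windowed courses recover
  $\tau$ without deblurring.
* **Cross-frequency envelope leakage.** While the gain is still changing,
  the competing component's time-varying envelope spreads a small amount
  of energy across tagging frequencies (about 0.1 dB at a 250-Hz sampling
  of the default dynamics); once the envelope settles the windowed
  estimate matches the blurred truth to better than 0.01 dB. This bounds
  the accuracy of point estimates *during* the rise but does not bias the
  fitted asymptote.
* **Amplitude floor.** $10^{-3}$ µV, configurable. Window centres where
  either course sits at the floor (no signal at all) are excluded from
  blur-diagnostic summaries.
* **Singular covariances** in QC (duplicated trials) fall back to a ridge
  $\Sigma + \varepsilon I$ with a warning; distances of trials at the mean
  are 0 and nothing is excluded.
* **Exponential fitting** (`fit_reweighting()`) uses
  Levenberg–Marquardt least squares on the across-participant mean course
  restricted to centres whose window lies inside the stimulation period
  (0.5–5.5 s by default), with data-driven starting values and
  $\tau > 10^{-3}$ s as the only bound.
* **Off-grid requests** — a lag that is not a multiple of the step, or an
  off-bin frequency for the window length — snap or warn rather than fail.

## Reference simulation studies

Two simulation studies back the package's statistical claims; both are run
by the test suite and `scripts/acceptance.R`, and their sizes are the
package's reference choices:

* **Null calibration**: 200 datasets of N = 20 participants with *zero*
  suppressive weight ($w_0 = w_\infty = 0$), 8 trials/condition at 250 Hz
  with a 20-ms analysis step, 500 permutations. Both the increase test and
  the (arbitrarily split) group test must show a family-wise positive rate
  near the nominal 5%. The weight must be exactly zero for the null to be
  true everywhere the trend test looks: any *static nonzero* weight still
  steps the ratio from 0 dB (inter-trial interval) to its suppressed value
  at stimulus onset, and that onset step is a genuine increase — the test
  detects it, by design, in about 14% of such datasets under these sizes.
* **Parameter recovery**: 20 datasets of N = 40 participants, 48
  trials/condition at the full 1 kHz rate (50-ms analysis step), with
  programmed reweighting $w_0 = 0 \to w_\infty m = 10^{1.5/20}-1$
  (asymptote 1.5 dB) and $\tau = 1.5$ s under default noise and artifact
  rates. The increase test must detect the rise, and an exponential fit to
  the group-mean pooled course must recover $\tau$ within ±30% and the
  asymptote within ±0.2 dB.

The reduced sampling rate and trial count in the null study only make the
courses noisier; they do not change the null. The recovery study keeps the
full design size because bias in $\tau$ and the asymptote is the quantity
under test.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 10, n_trials_per_condition = 24,
                  sample_rate = 500, seed = 1)
res <- simulate_and_analyze(cfg, step_s = 0.02, freqs = c(5, 7))
pooled <- pool_timecourses(res$suppression)

glance(window_effect_size(pooled))
ct <- cluster_test_increase(pooled, n_permutations = 1000, seed = 1)
tidy(ct)
significant_until(ct)
glance(fit_reweighting(pooled))

plot_suppression(res$suppression)
autoplot(ct)
```

## Known limitations

* The generator's single virtual channel cannot exercise channel-level QC
  or topography; `average_channels()` is validated algebraically instead.
* The analysis assumes the two tagging frequencies are integers (exact
  1-s bins); off-bin tagging would need tapering, which is deliberately
  out of scope.
* Estimates of suppression *during* the first second after onset are blur-
  and leakage-limited as described above; conclusions about the rise are
  therefore drawn from cluster tests and exponential fits, not from single
  window centres.
* The intermodulation index inherits the noise of its alone-condition
  baseline (where no 12 Hz signal exists); it is reported relative to a
  floored baseline and is the least stable of the derived measures, which
  is consistent with its exploratory role.
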