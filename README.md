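# ssvepdyn

Time-resolved analysis of suppression between frequency-tagged steady-state
visual evoked potentials (SSVEPs).

## What problem this solves

When two stimuli flicker at different rates (say 5 and 7 Hz), each drives an
oscillatory cortical response at its own frequency, so the two responses can
be separated in the Fourier domain of occipital EEG/MEG. Divisive
normalization makes the response to a target stimulus shrink when a mask
stimulus is added: the ratio

```
suppression(t) [dB] = 20 log10( A_alone(t) / A_masked(t) )
```

of the target-alone to the target-plus-mask amplitude is a direct index of
suppression, and computing it in a sliding 1-s window resolves how it evolves
within a trial. Normalization *reweighting* predicts this suppression grows
over the first seconds of joint stimulation. `ssvepdyn` is for researchers
who want to measure that growth: it implements the estimator chain
(occipital-channel averaging, trial rejection on complex Fourier
coefficients, coherent averaging, exact-frequency sliding-window amplitudes,
dB ratios, windowed Cohen's *d*, intermodulation indices) together with
nonparametric cluster-corrected permutation tests — a one-sided trend test
for *increasing* suppression built on paired t statistics between time
points 1 s apart with participant-level sign-flip nulls, and a two-sided
two-group comparison with label-shuffle nulls.

Because the recordings such studies rest on live in large external deposits,
the package ships a forward model (`sim_config()`, `generate_dataset()`)
that simulates epoched recordings from a dynamic normalization model — each
tagged component's amplitude is scaled by `g(t) = 1/(1 + w(t) m)` with an
exponentially reweighted suppressive weight
`w(t) = w0 + (w_inf - w0)(1 - exp(-t/tau))` — plus harmonics, a 12 Hz sum
intermodulation term, onset transients, 1/f noise with elevated inter-trial
activity, participant heterogeneity and artifact trials. Every stage of the
pipeline is validated against this generator's known ground truth; the
methods vignette (`vignettes/ssvep-suppression-dynamics.Rmd`) gives the full
model and the reasoning behind the defaults.

## A worked example

Simulate a ten-participant study under the default reweighting dynamics and
run the full analysis:

```r
library(ssvepdyn)

cfg <- sim_config(n_participants = 10, n_trials_per_condition = 24,
                  sample_rate = 500, seed = 1)
res <- simulate_and_analyze(cfg, step_s = 0.02, freqs = c(5, 7))
pooled <- pool_timecourses(res$suppression)   # mean dB over frequency x mask

glance(window_effect_size(pooled))            # early (0-1 s) vs late (3-4 s)
#>   cohen_d n_participants mean_early_db mean_late_db mean_diff_db sd_diff_db
#> 1    1.76             10         0.856         1.74        0.883      0.503

cluster_test_increase(pooled, n_permutations = 1000, seed = 1)
#> <ssvep_cluster_test: increase> 8 cluster(s), critical summed t = 80.03 (1000 permutations)
#>   significant: 0.90-2.62 s (sum t = 491.9)

glance(fit_reweighting(pooled))
#>   tau_s asymptote_db d0_db   rss n_timepoints
#> 1  1.07         1.81 0.224 0.257          251
```

Reading the numbers: suppression averaged 0.86 dB in the first second and
1.74 dB three seconds later, a paired effect size of *d* = 1.76 across the
ten simulated participants. The cluster-corrected trend test finds
significantly increasing suppression from 0.9 s until 2.62 s after onset
(summed *t* = 491.9 against a permutation critical value of 80.0), and a
least-squares exponential fit to the group-mean course estimates a rise to
1.8 dB with a ~1.1-s time constant — consistent with the generator's
programmed monocular/dichoptic asymptotes (1.5 / 2.3 dB, pooled) and 1.5-s
time constant, given the 1-s analysis window. About 2.9% of trials were
removed by the Mahalanobis outlier rule, in line with the 2% artifact rate
plus the ~1% per-frequency false-positive rate of the threshold.

`plot_suppression(res$suppression)`, `plot_timecourse(res$amplitude)` and
`autoplot()` on a cluster test give the standard figures. Recordings can be
written to and read from a portable container (float32 array + JSON sidecar)
with `write_epochs()` / `read_epochs()`; `run_pipeline()` drives the whole
chain from a config and writes tidy CSV/JSON outputs with a checksummed run
manifest, and `inst/cli/ssvepdyn.R` wraps simulate/analyze/diagnose-blur as
shell subcommands.

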