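# serialdep

Serial dependence — the pull of the current percept or decision toward what
was seen or reported on recent trials — is usually quantified behaviorally,
but its neural account requires tracing *where past-trial information
reappears in the brain* and *how it is geometrically related to the current
representation*. `serialdep` implements that full analysis circle for
continuous 2-D spatial tasks with epoched EEG/MEG-style recordings, together
with a synthetic-data generator that plants known effect sizes and known
representational geometry, so every stage can be validated by parameter
recovery.

## What it computes

**Behavioral serial bias.** For a spatial reproduction task, a trial-wise
multiple regression per coordinate axis,

    report = b1 * stimulus + b2 * start + b3 * previous_report + e,

fitted separately on X and Y and averaged (`fit_serial_regression()`); a
positive `b3` is an attractive serial bias. For a two-probe comparison task,
the binary choice is graded into a *weighted choice* in [-1, 1] by
reaction time, `sign(choice) * (1 - RT_rescaled)`, and modelled by linear
mixed models on demeaned distance differences ΔL_demean (distance to probe 1
minus probe 2, corrected by a 10,000-sample Monte-Carlo estimate of the
probe-geometry bias). Candidate factor sets are compared by AIC via forward
stepwise selection (`compare_choice_models()`).

**Trial-wise RSA decoding.** For every trial pair, a location RDM
`|loc_i - loc_j|` per axis and a neural RDM `1 - cos(V_i, V_j)` from
spatiotemporal patterns pooled over a 50 ms window; the OLS slope of neural
on location RDM is the representation strength at each time point
(`decode_timecourse()`), with optional PCA reduction to 99% variance
(`pca_reduce()`) and residualization of current-trial locations for lagged
decoding (`residualize_current()`).

**Past–present interaction.** Per time point, every channel is regressed on
the predictor coordinates; the per-channel coefficient vector of a predictor
is its *representational axis*, and the cosine between the past and present
axes (averaged over X/Y, 50 ms boxcar-smoothed) measures their interaction:
+1 aligned (attractive), -1 flipped (repulsive), 0 orthogonal
(`interaction_timecourse()`). A leave-one-out variant yields trial-level
interaction values (`trial_level_interaction()`).

**Group inference.** Sign-flip permutation tests with cluster-based
correction over time (`sign_permutation_test()`, `cluster_correction()`)
and cross-region spatial correction (`spatial_correction()`).

**Neuro-behavioral coupling.** Across-subject Pearson correlation of the
behavioral bias with cluster-averaged interaction
(`across_subject_correlation()`), and within-subject regression of
reciprocal reaction time on the trial-level neural effect
(`within_subject_neurobehav()`).

## Worked example

```r
library(serialdep)

gt <- ground_truth(
  exp1_coefs = c(current_stimulus = 0.92, current_start = 0.008,
                 previous_report = 0.05),
  exp1_noise_sd = 0.5, axis_angle = 180, neural_noise_sd = 0.3)

tr <- simulate_behavior_exp1(n_subjects = 5, n_trials_per_block = 50,
                             n_blocks = 8, truth = gt, seed = 1)
fit <- fit_serial_regression(tr)
print(fit)
#> <serial_fit> 5 subjects, 1960 trials; response: current_report
#>         predictor     mean       t df         p cohens_d
#>  current_stimulus 0.917911 363.257  4 3.446e-10 162.4536
#>     current_start 0.002791   1.581  4 1.891e-01   0.7069
#>   previous_report 0.045735  22.058  4 2.500e-05   9.8644
```

The planted coefficients (0.92, 0.008, 0.05) are recovered, and the group
t-test detects the attractive serial bias (`previous_report` coefficient
positive, p = 2.5e-5). Now decode the planted *flipped* (180°) past axis
from one subject's simulated epochs:

```r
tr1 <- tr[tr$subject == 1, ]
ep <- simulate_neural(tr1, gt, n_channels = 16, sfreq = 100,
                      epoch_window = c(-100, 500), seed = 2)
itc <- interaction_timecourse(
  ep, tr1,
  predictors = c("current_stimulus", "current_start", "previous_report"),
  past = "previous_report", present = "current_stimulus")
mean(itc$cosine[itc$time_ms >= 150 & itc$time_ms <= 350])
#> [1] -0.938
```

The estimated past–present interaction in the overlap window is near -1:
the past-report axis is flipped relative to the current-stimulus axis, the
signature of a repulsive interaction.

A runnable end-to-end pipeline (simulate → fit → decode → interaction →
cluster statistics → neuro-behavioral correlation, with a manifest that
makes reruns byte-identical) is available as `run_pipeline()` or from the
shell:

```sh
Rscript inst/cli/serialdep.R run --seed 7 --out out/
```

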