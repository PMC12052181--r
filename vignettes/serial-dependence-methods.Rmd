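---
title: "Models and methods behind serialdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serialdep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`serialdep` estimates serial dependence — the influence of the previous
trial's report or choice on the current one — at three levels: behavior,
time-resolved neural decoding, and the geometry of neural representations.
This vignette describes the models, the tunable parameters, the synthetic
generator used for validation, and the numerical choices that are not
visible from function signatures.

## Behavioral models

### Spatial reproduction (single-item task)

Stimulus, response-start and report locations live in a round 2-D area
(default 15 degrees of visual angle in diameter, Cartesian coordinates in
degrees with the origin at the disk centre, X rightward, Y upward). The
serial-bias model is a trial-wise multiple regression per coordinate axis

    report = b0 + b1 stimulus + b2 start + b3 previous_report + e,

fitted by OLS per subject, separately on X and Y, with the two per-axis
coefficients averaged. A positive `b3` is an attractive bias toward the
previous report. We include an intercept by default although the model can
be written without one: the intercept absorbs any constant response offset
(e.g., a systematic pull toward the centre) and leaves the slope estimates
unchanged when no such offset exists; `intercept = FALSE` restores the
strict form. Group-level inference is a two-sided one-sample t-test of the
per-subject averaged coefficients with Cohen's d.

Serial structure is strictly lag-1 *within a recording block*: the first
trial of each block has no previous trial, its lagged fields are missing,
and it is excluded from every serial analysis. Cross-block pairs are never
treated as consecutive.

### Probe comparison (two-item task)

Each trial presents two memory items (one retro-cued as target) and two
response probes; the subject picks the probe closer to the cued item.
Because accuracy saturates near 0.9, the binary choice is graded by
reaction time into the *weighted choice*

    w = code(choice) * (1 - RT_rescaled),   code in {-1, +1},

which lies in [-1, 1]; fast confident choices sit near the bounds. RT
rescaling is min–max per subject by default (per-experiment rescaling is
available; the choice matters little because the mixed models carry
per-subject random effects). Out-of-range RTs are clipped when bounds are
supplied externally; equal bounds are a degenerate-scale error.

The decision variable for a candidate location is the signed distance
difference ΔL = d(probe1) − d(probe2). Probe geometry alone biases ΔL (a
probe near the centre is on average closer to anything), so each trial's
offset is estimated by Monte Carlo — the mean ΔL of 10,000 uniformly
sampled disk locations — and subtracted, giving ΔL_demean. The bulk path
shares the Monte-Carlo point sample across trials within chunks of 256;
this changes nothing in expectation and cuts the cost by two orders of
magnitude.

Candidate models regress the weighted choice on the ΔL_demean of factor
sets drawn from six locations (current target/non-target, previous
target/non-target, previous chosen/unchosen probe). Fitting uses
`lme4::lmer` by maximum likelihood — not REML, because AIC comparisons
across different fixed-effects structures are meaningless under REML — with
per-subject random effects on every coefficient. The random effects are
*uncorrelated* (`||`): with up to six slopes and tens of thousands of
trials, a full covariance is slow and routinely singular, while the
diagonal structure leaves model ranking unchanged in recovery simulations.
Selection is forward stepwise from the base model (current target only),
adding the factor with the largest AIC drop until no factor lowers AIC;
ties break by factor list order. If a fit fails, the model is refitted with
random intercepts only, flagged, and reported with a warning.

## The synthetic generator

The generator's role is to produce data whose ground truth is known exactly
so that every estimator in the package can be checked by recovery.

* **Disk sampling** is area-uniform: radius `R * sqrt(u)`, angle uniform.
  (Rejection sampling would be an acceptable alternative; the closed form
  is used because it is deterministic in the number of draws.)
* **Reproduction behavior** applies the regression model above per
  coordinate with i.i.d. Gaussian report noise. The report noise SD is a
  generator parameter with default 0.5 degrees — a plausible magnitude for
  mouse reproduction in a 15-degree area, stated here as a configuration
  choice, not an empirical value.
* **Choice behavior** forms a latent value from *raw* ΔL (not ΔL_demean)
  plus Gaussian noise (default SD 0.15), takes its sign as the choice, and
  draws RT from a shifted lognormal whose log-mean decreases with the
  absolute latent evidence (shift 0.3 s, scale 1.7 s, sensitivity 0.4,
  sdlog 0.3). Two consequences are intended: with no noise and only a
  current-target drive, the chosen probe is always the closer one
  (accuracy 1); and hard trials — probes nearly equidistant from the
  target — are slower, giving a negative RT slope on |ΔL|. The demeaning
  correction remains an analysis-side transform, applied by
  `compare_choice_models()`, mirroring the asymmetry between how observers
  behave (actual distances) and how analysts correct for probe geometry.
  With these defaults the simulated task yields accuracy ≈ 0.90 and
  RT ≈ 1.8 ± 0.5 s, the regime the analyses are designed for.
* **Neural epochs** place the present-trial and past-trial 2-D locations on
  unit-norm channel axes inside boxcar time-gain windows, with i.i.d.
  Gaussian channel noise (AR(1) noise is available for stress tests,
  default off). Four orthonormal channel directions `e1..e4` are drawn per
  dataset; the present X/Y axes are `e1, e2` and the past axes are rotated
  by the configured angle into `e3, e4`. The planted past–present cosine is
  therefore exactly `cos(angle)`, and `n_channels >= 4` is required. A
  per-trial gain and a per-trial axis angle allow planting trial-level
  modulation of the past signal.

What the generator deliberately does **not** emulate: realistic sensor
forward models, 1/f spectra, eye movements, trial-to-trial amplitude
nonstationarity, or spatially correlated noise. Passing recovery tests on
these data shows the estimators are correct and calibrated, not that real
recordings satisfy their assumptions.

All randomness flows from one integer seed through a Lehmer-style
splittable sub-seed scheme (`derive_seed`), so adding a pipeline stage
never perturbs the streams of earlier stages, and fixed seeds give
byte-identical outputs.

## Trial-wise RSA decoding

Location dissimilarity is `|loc_i - loc_j|` per coordinate axis; neural
dissimilarity is one minus the cosine of spatiotemporal pattern vectors
(channels x samples within a 50 ms window centred at each time point).
Condensed RDMs store one value per unordered pair in fixed lexicographic
order (i < j), which is asserted by pack/unpack round-trip tests. Edge
windows are truncated, never zero-padded — padding would bias cosines
toward the pattern mean. The representation strength is the OLS slope (with
intercept) of the neural on the location RDM, averaged over the X and Y
fits. Cosine dissimilarity makes decoding invariant to global channel
rescaling, and the intercept absorbs constant RDM shifts.

PCA reduction fits per subject and stage on the concatenated
(trials x time) x channels matrix, mean-centred per channel, and keeps the
smallest leading set of components reaching the variance target (default
0.99).

For lagged predictors, the dominant current-trial response is first
regressed out of every channel and time point (OLS on the X and Y
coordinates of all listed current locations, with intercept), and decoding
runs on the residuals. One subtlety is documented because it shapes the
negative control: within-sample OLS residuals of trials i and j have
covariance `-H_ij * sigma^2` (H the hat matrix), which couples weakly to
the *removed* predictor's own RDM and gives its residual decoding a small
negative bias of order 1/n. Decoding of *other* variables (past trial, next
trial) is unaffected because their locations are independent of the hat
matrix. Consequently the package's negative control for the removed
predictor compares its decoding against an artifact-matched null built from
random rotations of the decoded location frame, while the next-trial
control uses the ordinary cluster test.

## Representational axes and past-present interaction

At each time point and coordinate axis, all channels are regressed jointly
on the predictor coordinates (with intercept); the per-channel coefficient
vector of one predictor is its representational axis. The past-present
interaction is the cosine between the past and present axes, computed
separately for the X and Y fits and *then* averaged (averaging the cosines,
not the weight vectors), followed by a centred 50 ms boxcar smoother with
truncated edges. Signs follow the aligned/flipped convention: positive
cosine means the past reactivation is aligned with the present
representation (attractive), negative means flipped (repulsive).

The trial-level variant computes, for every trial, the full-sample
interaction minus the leave-one-out interaction. The default path refits
every leave-one-out regression from scratch; a rank-one Sherman–Morrison
downdate of the normal equations is available (`method = "downdate"`) and
agrees with the naive path to better than 1e-10, which is asserted in the
tests. Per-trial series are smoothed and then averaged within externally
supplied cluster windows — windows are an explicit input, never re-derived
inside the coupling module, to keep the selective-inference step visible.

A design note on validation: the leave-one-out value responds strongly and
specifically to the *aligned component* of a trial's past signal (planting
per-trial axis angles of 0 versus 90 degrees yields trial-level
correlations around 0.7 at moderate SNR), whereas modulating the total past
gain moves the value only weakly (around 0.1–0.2) because the
design-conditional expectation is dominated by location-leverage terms.
The recovery tests therefore plant aligned-component modulation as the
primary check and assert the direction of total-gain modulation on trials
pooled across seeds.

## Group statistics

The group null flips the sign of each subject's entire effect series with
probability 1/2 per permutation — whole-series flips preserve temporal
autocorrelation, the standard reading for time-resolved effects. Two-sided
pointwise p-values use add-one smoothing `(1 + count)/(1 + n_perm)`, which
prevents p = 0 and differs from the raw-percentage variant by at most
`1/n_perm`. A one-ulp tolerance is applied when counting null means at
least as extreme as the observed mean so that the identity flip pattern
always counts; without it the p-value can fall below its combinatorial
floor through floating-point rounding.

Clusters are maximal contiguous runs of pointwise p below the
cluster-forming threshold (default 0.05), split by the sign of the group
mean; the cluster statistic is the signed sum of group means (mass). The
corrected p of a cluster is the fraction of permutations whose maximal
absolute mass — clusters formed identically on the permuted data — meets or
exceeds the observed one. A t-mass variant was considered and not adopted;
the mean-mass choice keeps the statistic in the units of the plotted
effect. The desk-scale default is 1000 permutations; 1e5 is available via
`n_perm` where publication-grade tails are needed. The spatial correction
pools each permutation's maximal cluster mass across regions (requiring a
shared flip schedule) and is exactly the temporal correction when only one
region is supplied.

Calibration is tested empirically: pooled pointwise p-values under a pure
null pass a KS test for uniformity, and the family-wise error of the
cluster correction lies inside the binomial 99% interval around 5% over
200 simulated datasets (15 subjects x 200 time points, 1000 permutations).

## Neuro-behavioral coupling

Across subjects: Pearson correlation between the behavioral bias
coefficient and the interaction averaged within significant cluster
windows. Within subject: OLS of the reciprocal reaction time 1/RT
(strictly 1/RT, not −RT: the reciprocal has the interpretation of speed)
on the trial-level neural effect, with the per-subject slopes tested
against zero. Subjects with fewer than 10 valid trials are excluded with a
warning. No RT trimming is applied by default.

## Degenerate inputs and tie rules

Coincident probes are resampled at generation and rejected in the
demeaning transform. Zero-norm patterns and zero axes are errors naming
the offending trial. Sensors exactly at y = 0 go to the posterior group.
Collinear designs raise errors listing the offending predictors rather
than silently dropping columns. Group tests guard zero-variance inputs
(all-zero values give t = 0, p = 1; identical nonzero values give an
infinite t with p = 0).

## Problem sizes

The shipped tests validate at the generator's study-scale conditions:
20 subjects x 1600 trials for reproduction-task recovery (50 seeds);
26 subjects x 500 trials for choice-model selection (20 seeds); grids of
five axis angles at 20 seeds; 200 null datasets for calibration; and
8–10 synthetic subjects for the decoding, residualization and coupling
checks. These sizes were chosen so that each property is tested at the
power its effect size requires.

## Known limitations

* The file format for epochs is a package-native JSON + raw-binary layout;
  importers from standard M/EEG epoch formats are documented hooks, not
  shipped readers.
* The mixed-model engine fits uncorrelated random slopes; strongly
  correlated subject effects would be approximated.
* Cross-validated decoders, inverted encoding models, time-frequency
  decompositions and cross-temporal generalization are out of scope.
* The residualization artifact discussed above is a property of
  within-sample OLS residuals; analyses that decode a removed predictor
  from its own residuals should always use an artifact-matched null.
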