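---
title: "Models and methods behind the sceptic package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sceptic package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sceptic)
```

## The task and its contingencies

The clock task asks a participant to stop a dot revolving around a clock face
within a 4-s interval; the stopping time (response time, RT) determines a
probabilistic reward. Reward probability and magnitude both vary monotonically
with RT, in opposite directions, under four contingencies: expected value
increasing with RT (IEV), decreasing (DEV), constant (CEV), and constant with
the probability/magnitude tradeoff reversed (CEVR). IEV and DEV are learnable
(there is a best end of the interval); CEV and CEVR are not.

The exact curve shapes are not part of any analysis downstream — only their
monotonicity and expected-value structure matter — so `make_contingency()`
parameterizes them transparently: the probability is linear between two
endpoints, the expected value (EV) is linear between two endpoints, and the
magnitude is EV/probability, which is automatically monotone in the opposite
direction of probability whenever EV is flat or moves against it. Defaults
span probabilities roughly 0.3–0.9 and EVs 40–100 points, with IEV paying
rarely-but-big late in the interval and DEV the mirror image. All endpoints
are arguments.

Missed trials (RT at or beyond 4000 ms) pay 0 points. Time is in
milliseconds throughout and the decision interval is the half-open
[0, 4000).

## The value model

Value over the interval is represented by 24 unnormalized Gaussian elements
with evenly spaced centers $\mu_b$ (spanning the closed interval ends) and a
shared width $s_b^2$:
$$\phi_b(t) = \exp\!\left[-\frac{(t-\mu_b)^2}{2 s_b^2}\right], \qquad
V(t) = \sum_b w_b\, \phi_b(t).$$

The width is solved numerically so that the overlap coefficient of adjacent
normalized densities — the integral of their pointwise minimum, which for
equal widths is $2\Phi(-d/2s)$ at center distance $d$ — equals 0.5. Choice
operates on a 40-bin discretization (100 ms bins, values evaluated at bin
centers) through a softmax with temperature $\beta$.

Feedback at RT $t$ generalizes to neighboring times through a normalized
Gaussian kernel of variance $s_g^2$ ($= s_b^2$ by default) centered on $t$.
Each element's *eligibility* is the integral over the interval of that kernel
times the element's receptive field, divided by the perfect-overlap value so
that an RT exactly at a center yields eligibility 1. The integral has a
closed form (Gaussian product identity times a normal-CDF difference for the
interval truncation); the test suite verifies agreement with numerical
quadrature to far below 1e-8. A `truncate` switch selects whole-line
integration instead, and `edge_renormalize` optionally rescales edge elements
to equal within-interval area; defaults are truncated integrals and plain
Gaussians, the simplest reading of the model.

Learning is a delta rule gated by eligibility. Under *selective maintenance*
the unchosen elements additionally decay toward a reversion point $h = 0$:
$$w_b \leftarrow w_b + e_b\,\alpha\,(r - w_b) - \gamma (1-e_b)(w_b - h),$$
and the *full maintenance* variant omits the decay term. With nonnegative
rewards, $h=0$, $\alpha \le 1$ and $e_b \in [0,1]$, weights remain
nonnegative (the update is a convex-combination contraction), which the
property tests exercise.

Two summary signals drive the analyses. The entropy of the normalized
weights, $H = -\sum p_b \log p_b$ with $p_b = w_b/\sum w_b$ (nats), is a log
measure of the number of good actions; when the total weight is numerically
zero we return $\log 24$, the uniform value, since all actions are then
equally plausible. The location of the global value maximum, RT\_Vmax, is the
grid argmax with ties broken toward the earliest time (a documented, testable
convention that only matters for exactly flat functions). Entropy is computed
over the 24 element weights rather than the 40-bin value function — the
weights are the model's memory store, and compression of that store is the
mechanism of interest.

## Uncertainty tracking

The Kalman-filter variant ("fixed U+V") keeps per-element means (updated with
a fixed learning rate, like the full-maintenance rule) and standard
deviations. Gains are $k_b = \sigma_b^2/(\sigma_b^2 + \sigma_{rew}^2)$ and
uncertainties contract by $\sigma_b \leftarrow (1 - e_b k_b)\sigma_b$.
Initializing $\sigma_{b0}^2 = \sigma_{rew}^2$ makes the first-trial gain
exactly 0.5. The measurement noise $\sigma_{rew}$ defaults to the empirical
SD of rewards in the data being fit (or of a simulated reference run for a
generative agent); whether that reference pools contingencies is a
configuration choice (`reference_reward_sd()`), not a hidden constant.
Choice uses $Q = V + \tau U$, with $\tau > 0$ seeking uncertain RTs and
$\tau < 0$ avoiding them.

The trial-wise *uncertainty percentile* ranks the chosen RT's $U$ among all
40 bins of the same trial, removing the global exponential decay of
uncertainty over learning. Ranks use a midrank convention with a 0.1%
relative tie tolerance: the basis envelope has a tiny interior ripple
(~2e-5) that would otherwise break exact ties arbitrarily. One consequence
worth knowing: because fewer elements overlap the interval edges, the
evaluated $U$ genuinely dips there, so an unsampled agent ranks interior
bins above edge bins (interior percentile ≈ 57, not 50). We report this as a
property of the basis representation rather than flattening it away.

## Fitting

Parameters are estimated in transformed space (logit for $\alpha, \gamma$;
log for $\beta$; identity for $\tau$). The per-trial likelihood is the
softmax probability of the observed response bin under the value (or $Q$)
function *before* that trial's update; learning state resets at run starts.
A one-trial hand computation in the tests pins down the no-look-ahead
convention.

Subject fits are penalized maximum likelihood (MAP) with a Gaussian prior in
transformed space, five optimizer starts at prior quantiles, and
curvature-based (inverse-Hessian) posterior SDs; non-positive-definite
curvature flags the fit and reports wide SDs. The population loop alternates
subject fits with the standard EM update of the population mean (mean of
modes) and SD (mode dispersion pooled with mean posterior variance, floored
at 0.05), iterating to a 1e-3 absolute parameter tolerance with warm starts
after the first pass. This hierarchical-MAP scheme reproduces the contract
of variational empirical-Bayes estimation — shrinkage of individuals toward
an inferred population — with deterministic, dependency-light machinery. A
precision-weighted (random-effects meta-analytic) population update was
evaluated and retired: it was not consistently better in recovery
simulations than the canonical EM update.

`refit_group_means()` replays every subject's choices at the group-mean
parameters so that latent signals share a common scale across subjects —
the preferred input for between-subject regression coefficients.

**Known limitation.** At 20 subjects × 400 trials, recovery simulations show
a modest upward finite-sample bias in the population mean of transformed
$\alpha$ (about +0.2, i.e. 0.10 → ~0.12 on the natural scale, roughly 2.5
standard errors of the population-mean estimate), while $\beta$'s mean and
the subject-level truth–estimate correlations recover well
(cor ≈ 0.6–0.9). Single-subject maximum-likelihood estimates are unbiased
but heavy-tailed along the $\alpha$–$\beta$ ridge (faster learning can be
traded against a hotter softmax); shrinkage removes the downward outliers
asymmetrically. Alternative population updates did not remove the bias, so
it is documented rather than hidden, and the acceptance suite reports it
honestly.

## fMRI-style regressors

`extract_trial_signals()` aligns the reward prediction error with feedback
and entropy/uncertainty/value signals with the decision (clock) phase.
`build_dm_regressor()` convolves a unit-height boxcar of the phase duration
with a canonical double-gamma HRF (positive lobe shape 6, undershoot shape
16, ratio 1:6, scale 1 s — all exposed), renormalizes each trial's response
peak to 1, multiplies by the per-run mean-centered signal, sums trials, and
resamples from the 0.1 s internal grid to the 1 s repetition time. Peak
renormalization decouples response amplitude from decision time, so the
per-trial extremum equals |signal| — asserted exactly at the internal
resolution (on the decimated 1 s grid the sampled maximum can sit a fraction
of a percent below the true peak). Mean-centering precedes convolution;
clock- and feedback-aligned regressors share one per-run grid so they can be
correlated directly.

The high-pass filter is a Gaussian-weighted running-line detrend. Its weight
SD is derived from the cutoff as the half-amplitude frequency of the
underlying smoother, $\sigma = \sqrt{\ln 2}/(\sqrt{2}\,\pi f_c)$ (≈23 s at
the 0.008 Hz default, a 125 s period): a 0.05 Hz probe passes within 10%
and a 0.002 Hz drift is attenuated below 20%, which the tests measure from
the filter's empirical frequency response.

Run-level regressor correlations are pooled on the Fisher-z scale with a
t-interval over subject means — a deliberately simple hierarchical summary.
On synthetic behavior the pooled RPE–entropy correlation is small
(|r| < 0.2), supporting joint estimation of both signals in one design.

## Behavioral indices

`lagged_trial_table()` constructs one-trial lags that never cross run
boundaries, plus the late-learning weight $-1/\text{trial}$.
`exploration_index()` regresses current RT on previous RT × previous
outcome × a subject-level moderator with random intercepts for subject and
run-within-subject (lme4); the RT autocorrelation is the exploration
measure — near 1 for perseveration, near 0 for large swings — chosen over
|ΔRT|, whose distribution is zero-inflated and scale-confounded.
`convergence_index()` does the same with the lagged RT\_Vmax and its
$-1/\text{trial}$ interaction; positive coefficients indicate exploitation
of the learned maximum, strengthening late. RTs enter the models in
seconds purely for design-matrix conditioning; the autocorrelation
coefficients are dimensionless.

`build_survival_table()` expands responded trials into 100 ms
counting-process rows over the modeled 1000–3500 ms window: the row
containing the response carries the event, later responses are censored at
3500 ms, and responses at or before 1000 ms contribute nothing. Momentary
value comes from the selective-maintenance replay and momentary uncertainty
from the Kalman replay of the same choices, each sampled per bin from the
pre-trial state; both can be standardized within subject
(`rescale_within_subject()`), removing the parameter-dependent scaling of
model quantities. Optional "no-go" censoring drops a configurable margin
(default one bin) at each window edge, since precise no-go boundaries are an
analysis choice. `fit_hazard_model()` wraps `survival::coxph` on this table
with a subject cluster term; the bespoke scientific content is the table
construction, and the proportional-hazards machinery is deliberately
off-the-shelf.

## Long-axis geometry

`long_axis_rotation()` finds the ten most anteroinferior and posterosuperior
voxels per hemisphere (scored along a direction in the sagittal y–z plane,
anterior-and-inferior by default), connects the centroids of the extreme
sets, averages the per-hemisphere slopes and reports the clockwise angle
from the AC–PC axis. Scoring along the fixed anatomical direction biases the
extreme sets toward corners when the key is misaligned with the true axis,
so by default the scoring direction is refined against the estimated axis
for three passes; with `refine = 0` the single-pass anatomical procedure is
used. The default key is anterior-plus-inferior (y − z in RAS mm), which
stays monotone along any axis rotated clockwise by less than 135°; the
obvious alternative y + z degenerates exactly in the 40–45° regime typical
of the hippocampus.

`quantile_bins()` projects voxels onto the rotated axis and cuts them into
12 bins of even size per hemisphere (counts differ by at most one; remainders
go to the most posterior bins), `binwise_stat()` averages voxelwise
statistics per bin, and `timelock_trials()` interpolates a 1 s-sampled
activity series onto event-aligned grids, marking samples beyond the series
or at/after the next trial's onset as missing — never imputed.
`timecourse_regression()` provides the per-timepoint regression companion
with Benjamini–Yekutieli control at rate 0.05 across models. NIfTI masks are
read through `read_voxel_mask()` (RNifti) when volumetric inputs are
available; all tests build masks in code.

## The synthetic-data module

The generator mirrors the study design: 70 subjects by default (tests use
4–20 for speed), 8 runs of 50 trials on the 4-s interval, the four
contingencies counterbalanced two runs each in per-subject shuffled order,
and exponential inter-trial intervals (mean 2.5 s, truncated to [1, 10] s —
the mean chosen so that a 50-trial run lasts about 4.5 minutes; the
study-specific optimizer-chosen ITI sequences are not reproducible, only
their distributional family). Subject parameters are normal in transformed
space around a moderate learner: $\alpha$ around 0.1 (SD 0.5),
$\gamma$ around 0.2 (SD 0.5), $\beta$ around 20 points (SD 0.4 on the log
scale), $\tau$ around −0.5 (mild uncertainty aversion, as observed in
humans). These defaults were fixed once as the package's study conditions.

`gen_betas()` plants subject-level "brain beta" covariates as linear
functions of transformed parameters plus noise, standardized — a ground
truth for moderator-recovery tests. `gen_mask()` produces elongated voxel
clouds at a requested sagittal angle with an elliptical thickness taper
(without the taper, extreme-voxel centroids are corner-biased and rotation
recovery degrades). Rotation-recovery tests use 1 mm fixture voxels: at
2.3 mm the ten-voxel tip centroids carry ~0.7 mm quantization noise, which
over a 40 mm lever arm costs up to ~2° — a property of coarse anatomy, not
of the estimator, whose error at fine resolution is below 0.3°.
`gen_timecourses()` plants ramp/on–off/delayed-sustained event-locked
shapes in 1 s-sampled series.

What passing tests on these data do and do not show: the generators share
the model family with the fitted models, so recovery tests validate the
estimation machinery, not the model's adequacy for human behavior; the
synthetic "BOLD" series contain planted shapes with white noise, not
physiological confounds, so time-locking tests validate alignment and
censoring logic, not denoising.

## Problem sizes and numerical conventions

Test and acceptance runs use 20-subject cohorts for recovery and entropy
comparisons, 4–8 subjects elsewhere, 1000 trials for the survival oracle,
and 20 masks of ~300 voxels for geometry — sizes at which every stochastic
assertion has comfortable margin while the whole suite stays quick.
Optimizer tolerances: 1e-6 relative (inner BFGS), 1e-3 absolute parameter
change (outer loop), at most 50 outer iterations. Ties: earliest-time
argmax; midrank percentiles with 0.1% relative tolerance. Degenerate
inputs: all-zero weights yield maximal entropy; constant covariates rescale
to zeros with a warning; flat likelihoods yield wide-SD flagged fits.
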