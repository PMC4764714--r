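---
title: "Decoding time-lagged eye-position signals from population spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding time-lagged eye-position signals from population spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedecode)
```

## The question and the method

During active vision the brain must combine retinal input with an estimate
of where the eyes are pointing. Neurons in the dorsal visual stream carry
tonic eye-position signals (gain fields) plus a rich variety of transient
modulations around saccades. `gazedecode` implements a population
read-out that asks how much continuous eye-position information — at the
current moment, but also at past and future moments — can be extracted
from such activity by a single linear operation.

The read-out is a pair of hypothetical downstream units ("uber-neurons"),
one per eye coordinate, whose outputs are fixed weighted sums of the
instantaneous population firing rates:

$$\hat X(t) = R(t)\,\beta_X + c_X, \qquad \hat Y(t) = R(t)\,\beta_Y + c_Y,$$

where $R(t)$ is the row of a time $\times$ neuron design matrix of
trial-averaged firing rates. The critical constraint is that the weights
are *fixed over time and across saccade directions*: the two directions'
design matrices and regression targets are concatenated in time and fitted
jointly, so the read-out cannot re-tune itself per condition. Whatever
structure appears in $\hat X, \hat Y$ across conditions must come from the
population activity itself.

The regression target is a synthetic eye-position signal: a scaled
cumulative Gaussian matched to the average 10° saccade (transition mean
$\mu_0 = 25$ ms relative to saccade onset, SD $\sigma = 10$ ms), rising
from 0 to +10° on the horizontal channel for rightward saccades and
falling 0 to −10° on the vertical channel for downward saccades (downward
is stored with its physical, negative-y sign; any sign flip is left to
plotting). Shifting the transition time by a *target lag* between −400 and
+400 ms asks the same population for predictive (negative lag) or delayed
(positive lag) representations. Only the target is shifted, never the
neural data.

### Estimation

Weights are estimated by ridge regression, the standard remedy for the
strong collinearity among neurons:

* predictors (neuron columns of the concatenated design) are z-scored;
* the penalty $\gamma \sum_i \beta_i^2$ is applied on that standardized
  scale with $\gamma = 30$; the intercept is unpenalized (realized by
  centering rather than a literal ones-column, which would be degenerate
  after standardization);
* the closed-form solution $(Z^\top Z + \gamma I)^{-1} Z^\top y$ is
  computed per channel by a Cholesky solve and the coefficients are
  rescaled to the original spikes/s units.

This mirrors the default behaviour of the classic `ridge` routines in
numerical environments, which standardize internally, and makes $\gamma$
comparable across populations of different size and rate scale. At
$\gamma = 0$ the solve requires a full-column-rank design; zero-variance
neuron columns are dropped with a warning at any $\gamma$.

Generalization is enforced by cross-validation: each of `n_sets` random
half/half splits of the trials within each of the 10 task conditions
(5 initial fixation positions $\times$ 2 directions; the odd trial of an
odd count goes to the training side) yields training condition-averages
for weight estimation and test averages for prediction. Reported decodes
are the pointwise mean and SD across sets. All splits derive from one
master seed with per-set substreams, so every result in the package is
bit-reproducible.

### Quantification

Decoded time courses are parameterized by a cumulative Gaussian
$\text{offset} + A\,\Phi((t-\mu)/\sigma)$ fitted by Levenberg–Marquardt
jointly to the two saccade channels ($\hat X$ for rightward, $\hat Y$ for
downward, the latter entering with negated amplitude), accumulating
squared residuals across both. The fitted $\mu$ minus the true transition
time (25 ms) is the *achieved lag*; the 1st–99th percentile width
$4.6527\,\sigma$ is the *represented saccade duration*, reported as a
ratio to the true duration ($\sigma/10$). Initialization uses the
half-range crossing for $\mu$, $\sigma_0 = 10$ ms, and plateau medians for
amplitude and offset, with five deterministic restarts ($\mu_0$ shifted by
0, ±100, ±200 ms); the best SSE wins. Confidence intervals come from the
Jacobian at the optimum (asymptotic normal theory). Per-set variability is
quantified by refitting each cross-validation set with amplitude and
offset frozen at the mean-fit values, estimating only $(\mu, \sigma)$;
non-converged sets are flagged and excluded from the variance summary.

Goodness of fit is $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ with both sums
pooled over both channels and both directions before the ratio, either
over the full −800..+800 ms course or over a peri-saccadic window defined
as ±100 ms around the *target's* transition time (for lagged targets the
window follows the target, not the animal's saccade). A window with zero
target variance raises an error rather than returning a silent `NaN`.

Because the decoder may satisfy an extreme predictive target by drifting
obliquely before the saccade direction is knowable, the package also
parameterizes the *direction-specific difference* (rightward minus
downward within each channel, stored unflipped). For an ideal decoder both
difference series rise 0 → +10°; direction-unspecific drifts cancel.

## The synthetic population

No recordings are distributed with the paper this analysis style comes
from, so the package includes a generative stand-in whose purpose is to
carry, in known quantities, the statistical structure the decoding
analysis assumes. Each neuron's intensity is a rectified linear sum

$$\lambda(t) = \big[\,b + g_x x(t-\Delta) + g_y y(t-\Delta)
  + \textstyle\sum_c a_{c,d}\,\varphi_c(t) + a_\psi \psi(t)\,\big]_+$$

with a tonic gain field read at a per-neuron delay $\Delta$, a bank of
direction-specific transient components $\varphi_c$, and a
direction-nonspecific saccadic bump $\psi$. Spikes are drawn by thinning a
piecewise-linear interpolation of $\lambda$ on a 1 ms lattice, with one
seeded random stream per trial so any subset of trials regenerates
identically.

The transient basis contains three canonical motifs — a plateau rising
near −100 ms and decaying by +150 ms, a biphasic (derivative-of-Gaussian)
modulation, and a sustained pre→post step — plus two slowly decaying
post-saccadic components (time constants 200 and 400 ms) and eight brief
bumps (SD 20 ms) at 50 ms intervals from −100 to +250 ms. The brief bumps
model the empirical observation that the *timing* of peri-saccadic
modulation varies widely across neurons over the epoch in which the
population reorganizes; the slow components model the gradually fading
memory of the movement. Without this temporal heterogeneity a ridge
read-out at $\gamma = 30$ cannot synthesize sharp transitions at arbitrary
lags — the decoded saccade smears to several times its true duration — so
the bank is an assumption about the recorded populations that the decoding
results themselves imply.

Default parameter ranges (all uniform, drawn once per neuron) are chosen
for recordings in near darkness: baseline 5–25 spikes/s; gain-field slopes
±2 spikes/s per degree; tonic delay $\Delta$ on [−100, +200] ms, matching
the band of lags the analysis probes; canonical transient amplitudes ±8,
slow-decay amplitudes ±20, timed-bump amplitudes ±35, and saccadic-bump
amplitudes 0–10 spikes/s. The task geometry defaults reproduce the study
design: five initial fixations arranged like the five-spot on a die at
±10°, 10° rightward or downward steps, and at least 6 (by default 20)
trials per condition.

### What the generator does and does not emulate

It emulates: tonic, delayed gain-field coding; direction-specific
transient diversity of realistic magnitude; Poisson spiking variability;
the exact task and trial structure; and ground-truth availability (every
session carries its generating parameters, so recovery can be scored).

It does not emulate: visual responses to the fixation target (sessions
are emitted already saccade-aligned; the ~200 ms saccadic latency matters
only as the reason pre-saccadic information is bounded), eye-tracking
noise or saccade detection, non-Poisson count statistics, or correlated
noise across neurons. One consequence worth stating plainly: in the
synthetic population each neuron occupies a fairly specific temporal
niche, so decoders for different target lags select noticeably different
neurons — the cross-lag weight correlation comes out low (~0.3) and the
per-neuron modulation high (~100%), whereas recorded populations show the
opposite (correlations near 0.9, modulations of 20–40%). Real neurons
multiplex many broad signals, letting small weight adjustments retune the
read-out; passing tests on the synthetic study therefore validates the
*pipeline*, not that particular empirical claim.

## Conventions and edge cases

* Rate binning: spike counts in half-open windows $[t-25, t+25)$ ms, 50 ms
  wide, stepped 25 ms; grid times are window centres from −800 to +800 ms
  (65 points). Sessions are simulated to ±900 ms so edge windows are
  complete.
* Condition averaging: trials within each of the 10 conditions first, then
  an unweighted mean of the 5 positions per direction.
* PCA of the direction-differential time courses removes each neuron's
  mean over time (isolating dynamics from tonic offsets), then
  eigendecomposes the time $\times$ time covariance across neurons.
  Neurons are not z-scored by default (strongly modulated neurons should
  dominate, as they do in the decoder), but a `standardize` flag exposes
  the alternative. Component signs follow a largest-element-positive
  convention; bootstrap replicates (resampling neurons with replacement)
  are aligned to the full-sample components by greedy matching on absolute
  correlation with sign flip before pointwise SDs are taken.
* The fixation-only decoder removes training rows strictly within the
  exclusion half-width (default 100 ms) of saccade onset ($t = 0$) or
  offset (the 99th percentile of the true trajectory, ≈48 ms), plus the
  interval between them; an exclusion of 0 removes nothing. Predictions
  are always emitted for the full grid.
* The inter-target similarity statistic concatenates, per lag, the two
  active saccade channels sign-aligned (the rightward horizontal channel
  and the vertically flipped downward channel) on the full −800..+800 ms
  grid; the time span is an assumption recorded here because the summary
  is sensitive to how much fixation plateau the window includes.

## Problem sizes

The packaged study runs at 100 neurons, 20 trials per condition, 50
cross-validation sets, and 200 bootstrap replicates; the lag sweep covers
−400..+400 ms in 100 ms steps. These sizes give stable estimates (the
across-set SD of the fitted transition time at zero lag is ≈1 ms) while
keeping a full pipeline run around a minute. The recorded samples this
emulates were of comparable size (74–107 neurons per area, ≥6 trials per
condition, 1000 cross-validation sets).

## Known limitations

The generator's amplitude ranges were fixed by design judgement, not fit
to data; absolute $R^2$ values on synthetic sessions are higher than on
real recordings (there is no extraneous signal multiplexed into the
rates). The ridge dialect (z-scored predictors, unpenalized intercept)
matches the common default but other dialects shift the meaning of
$\gamma$. The sigmoid parameterization assumes a single monotonic
transition; for far-out-of-band targets the decoded course can be
non-sigmoidal and the fit then reports the best compromise, which is
exactly how the duration-ratio diagnostic flags those lags.
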