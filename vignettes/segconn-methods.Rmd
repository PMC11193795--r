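---
title: "Models and methods behind segconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind segconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segconn)
```

segconn implements the analysis chain of a naturalistic event-segmentation
experiment: observers watch a film and press a key whenever they feel one
meaningful event ends and another begins, while multichannel EEG is
recorded. The package covers the behavioral statistics, the sensor-level
spectral statistics, source reconstruction, and — at its core — nCREANN, a
nonlinear multivariate autoregressive (MVAR) estimator of directed linear
and nonlinear connectivity. A synthetic-data module generates every input
with known ground truth, so each stage can be validated end to end.

## Behavioral model

The recording is split into consecutive 2-s intervals (half-open
`[start, start + 2)`; a press exactly on a boundary belongs to the later
interval). An interval is a *boundary interval* (BI, response 1) iff it
contains at least one keypress. Situational changes in the film — nine
coded types — are counted per interval.

Two mixed-effects logistic regressions link responses to changes, both
with a subject random intercept and fit by maximum likelihood with the
Laplace approximation (`lme4::glmer`):

1. `response ~ count + group + count:group + (1 | subject)`, with group
   coded adolescent = 0, adult = 1. A per-group variant
   (`response ~ count + (1 | subject)` per group) is the default surface
   for comparing slopes, since the published per-group coefficients are
   parameterized that way; the interaction model is also exposed.
2. `response ~ group * (type_1 + ... + type_9) + (1 | subject)` for the
   nine change types.

Odds ratios use Wald 95% intervals, `exp(estimate ± 1.96 · se)`; the
geometric mean of the bounds is therefore exactly the OR, a property the
tests exploit against the published tables. The multiplier 1.96 is a
design choice — the publication reports CIs without naming a method, and
the printed bounds are symmetric on the log scale, which is what the Wald
form produces. Slopes of the two groups are compared with the standard
two-coefficient Wald contrast `z = (b1 − b2)/sqrt(se1² + se2²)`. The
segment-length comparison uses the pooled-variance Student t
(`df = n1 + n2 − 2`), matching the published degrees of freedom (77 for
groups of 40 and 39); Welch's form would not reproduce that df.
Collinearity among predictors is checked with variance inflation factors
computed directly as `1/(1 − R²_k)`; exact collinearity is reported as an
infinite VIF rather than an error in the numerator.

Internally `fit_count_model` collapses Bernoulli rows to binomial counts
per (subject, count) cell before calling `glmer` — the likelihood depends
on the data only through those totals, so the estimates and standard
errors are identical while fits are roughly an order of magnitude faster.

### Synthetic behavior

`simulate_segmentation_behavior` draws, per subject and interval, a
change count from the empirical frequency of 0–5 changes in the film
(518/278/106/52/29/4, normalized), computes the response log-odds from
the configured fixed effects plus a Gaussian subject intercept, and draws
the response. Defaults use the published per-group coefficients
(adolescent intercept −3.342, slope 0.306; adult −2.399, 0.438),
expressed against the adolescent reference, at the published design size
(39 + 40 subjects × 982 intervals). The published combined-model
coefficients are numerically consistent only with an adult reference
group, contradicting the stated coding; the per-group values are
unambiguous, so the generator is parameterized from them. The subject
random-intercept SD defaults to 0.5 logit units — a moderate
between-subject spread typical of keypress criteria in segmentation
tasks; it is a free parameter, not an estimate. The nine type indicators
are drawn independently Bernoulli, because the film's joint type
distribution is not published; tests that need correlated types inject
them explicitly. Note the published interval frequencies sum to 987
although 982 intervals are stated in the methods; the generator keeps
the interval count free (default 982) and only uses the frequencies as a
distribution.

## Spectral statistics

Epochs are cut as 4-s windows centered on each marker; wavelet transforms
run on the full window and only the central −1..+1 s enters analysis, so
filter edges never touch the analysis axis. Morlet wavelets cover 3–30 Hz
in 1-Hz steps (the publication states the range and the cycle rule but
not the step; 1 Hz resolves the band masks), with cycles growing linearly
from 3 at 3 Hz to 12 at 30 Hz and the Gaussian envelope truncated at
three standard deviations. Power is the squared magnitude of the complex
coefficients in relative units — all downstream statistics compare power
across channels, times or groups, so the absolute scale cancels.

The group comparison of band power uses a spatiotemporal cluster-based
permutation test. Per (channel, time) cell an independent-samples pooled
t is computed; despite the original description of a "paired-sample"
test, adults versus adolescents is a between-subjects design, so the
independent form is the coherent choice. Cells with two-sided
`p < 0.05` form clusters under the channel adjacency graph (a required
input; no cap geometry is shipped) plus consecutive time points, with a
two-cell minimum; positive and negative clusters are formed separately
from the signed t map. The null distribution of the maximum cluster mass
comes from subject-level relabelings, with the observed labeling included
in the count (the standard Monte-Carlo correction, so the smallest
attainable p is `1/(n_perm + 1)`); clusters with `p < 0.0025` are
flagged.

## Source reconstruction

`band_csd` averages Hann-tapered FFT cross-spectra over all bins in a
band and over trials. `dics` builds, per voxel, the unit-gain spatial
filter `w = (lᵀC_r⁻¹l)⁻¹ lᵀC_r⁻¹` on the regularized CSD
`C_r = C + λ (trace(C)/S) I`; λ defaults to 5% of mean sensor power, the
common beamformer default, and is exposed. The Neural Activity Index
divides filter-output power by the noise projected through the same
filter, compensating the depth bias; the noise CSD defaults to white
noise at the smallest eigenvalue of the band CSD — a standard white-floor
estimate, chosen because the original "local noise per voxel" estimate is
not specified. `10·log10(NAI)` gives the dB map.

Top activity is extracted by thresholding the NAI map at the
`100 − top_pct` percentile (default top 3%; voxels exactly at the
threshold are included, which matters when the map has ties) and running
DBSCAN over the suprathreshold voxel coordinates with `eps` of one grid
spacing and a two-voxel minimum — so isolated voxels are noise, and on a
regular grid the clusters coincide with flood-fill connected components,
which is how the tests verify the implementation. DBSCAN is implemented
in the package because no clustering package shipping it is available in
the dependency set; it follows the textbook algorithm.

`lcmv_timeseries` band-passes the epochs with a zero-phase FIR filter
(window-method design, order of one second's worth of taps, halved
passband ripple by forward-backward application), estimates the sensor
covariance over the −500..+500 ms window of every trial, and applies the
unit-gain LCMV filter of the cluster's peak-NAI voxel to each trial,
concatenating the trials. The peak voxel, rather than a voxel average,
avoids sign cancellation across voxels; beamformer outputs carry an
arbitrary sign, so comparisons use absolute correlations.

## nCREANN

The signals are modeled as a nonlinear MVAR process
`x(n) = f(x_p) + σ(n)`, with `x_p` the stacked `p` previous samples of
all `M` channels. `f` is realized by a single-hidden-layer perceptron
(10 tanh hidden units, linear outputs), trained on standardized channels
by incremental (per-sample) backpropagation with momentum, weights
initialized uniformly in [−0.5, 0.5]. Ten permuted cross-validation folds
each split the samples 80/10/10 (train/validation/test); training stops
early when validation MSE stalls, and the best-validation fold supplies
the model. Per-fold MSE and R² on train and test data are retained.

A first-order Taylor expansion of each hidden unit about its bias point
splits the mapping exactly: `f_lin` is affine with gain matrix
`W2 · diag(tanh′(b1)) · W1`, and `f_nonlin = f − f_lin` holds every
higher-order term, so the decomposition reproduces `f` to machine
precision by construction. Linear connectivity from channel i to j
averages the absolute weight-path gain `|Σ_h W2[j,h] tanh′(b1[h])
W1[h,(i,k)]|` over lags k — the literal product of the connecting weights
and the hidden units' scaling parameters. Nonlinear connectivity is the
log ratio of restricted to full mean squared prediction error,
`NC_{i→j} = ln(⟨ε²_restricted⟩/⟨ε²_full⟩)`, where the restricted
prediction lets channel i act on j only linearly: i's lags are replaced
by their standardized mean (zero) inside the nonlinear pathway while the
linear part is untouched. Residuals are taken on each fold's held-out
test samples and averaged over folds, so NC is not inflated by in-sample
overfitting.

Significance uses time-shifted surrogates: each channel is circularly
shifted by an independent uniform offset in [0.1 T, 0.9 T], which
preserves each channel's marginal distribution and circular
autocovariance exactly while destroying cross-channel alignment. The
identical training procedure (same hyperparameters, fresh random
initializations) runs on each surrogate, and a connection is significant
when its real value strictly exceeds the 90th percentile
(linear-interpolation definition) of its surrogate distribution. Note the
strictness bites only inside the interpolation gap between the 90th and
91st order statistics. Group matrices average the significant subjects'
values per connection and apply a ×100 presentation scale.

### Training schedule

The trainer's default schedule is a small constant learning rate
(0.002, momentum 0.5) with *tail averaging*: the returned weights are
the mean of the last 15 epoch-end snapshots, which bracket the
early-stopping optimum. The classic performance-reactive rule — raise
the rate 5% after an improving epoch, discard the epoch and cut the rate
30% after a >4% deterioration — is implemented and available through
`ncreann_config`, but it is not the default for a calibration reason
discovered during development: a reactive rate depends on how learnable
the data are. On time-shifted surrogates there is nothing to learn, the
rule collapses the rate, and surrogate networks end with a much smaller
stochastic-gradient weight-noise floor than real-data networks; the
surrogate-derived significance threshold then sits below the real fits'
own noise, flagging spurious edges. A data-independent schedule applied
identically to real and surrogate fits keeps the two noise floors
comparable, and tail averaging shrinks both: null-edge NC biases are
quadratic in the weight noise, so averaging is particularly effective
there. With a strict 90th-percentile rule, a perfectly calibrated null
connection still exceeds its threshold about 10% of the time — that
nominal level is inherent to the test, not an implementation artifact.

Model order is selected by Akaike and Schwarz criteria over linear VAR
fits on a common sample window (`select_order`); the full pipeline
default is order 10, consistent with the published choice, and
over-ordering is benign because surplus-lag gains shrink toward zero. On
the three-channel benchmark systems both criteria select the generating
order, and the structure-recovery suites run at that order.

### Benchmarks and what they show

`make_benchmark_system` provides fixtures with known edges; `mixed3` is
canonical: channel 1 is white noise, channel 2 receives `0.5·x1(n−1)`
(a purely linear edge), channel 3 receives `0.4·x2(n−1)²` (a purely
nonlinear edge). The recovery suite simulates 2000 samples, trains at
the generating order, and tests 20 surrogates per fit across 20 seeds,
asking for at least 80% detection of each true edge and at most 20%
false-edge rate. Two honest caveats: first, the ~10% nominal exceedance
of the percentile rule consumes half of that false-edge budget by
itself; second, the square of a symmetric variable has a *genuine*
finite-sample linear association with its argument (the sample third
moment of `x2` is of order `sqrt(15/T)`), so the linear-connectivity
matrix legitimately sees a small 2→3 effect in some realizations — a
property of the generating system at T = 2000, not an estimator error.

The synthetic benchmark omits features of real source-space EEG: channels
are nearly white rather than oscillatory, there is no volume-conduction
mixing residual, and surrogate channels are therefore easier to model
than real surrogate EEG would be. Passing the recovery suite shows the
estimator separates linear from nonlinear directed structure under
clean conditions; it does not certify performance on mixed, oscillatory
field data.

## Problem sizes

Test and acceptance runs use the study's stated conditions where they
are stated: 39 + 40 subjects × 982 intervals and 50 replicates for GLMM
recovery; T = 2000, 20 seeds, 20 surrogates for structure recovery; 200
null datasets × 200 permutations on an 8-channel × 50-point grid for
cluster-test calibration. The acceptance script reruns the same
computations at 10 replicates/seeds and 100 null datasets to keep a
single sequential run short; its outputs are rates and estimates whose
expected values do not depend on those counts.

## Known limitations

* Fixed-orientation toy leadfields only; free-orientation gains and real
  head models are out of scope (leadfields are accepted as input).
* The partial-correlation linkage takes control variables explicitly and
  defaults to none, with a warning — the published control set is not
  stated, and guessing one would be worse than exposing the choice.
* GLMM non-convergence is flagged, not raised, so simulation batches
  complete; callers should check `converged`.
* The nCREANN surrogate test calibrates each connection against its own
  null distribution; it does not correct across the M·(M−1) connections
  of a network.
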