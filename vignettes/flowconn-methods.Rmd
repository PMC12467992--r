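---
title: "Information-flow connectivity and recurrent-network classification: methods"
author: "flowconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-flow connectivity and recurrent-network classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`flowconn` implements two complementary analyses of resting-state EEG
cohorts:

1. a **causal (effective) connectivity** track that estimates the
   normalized Liang–Kleeman information flow rate between every ordered
   pair of ten region-of-interest (ROI) source time series, thresholds
   active connections, builds permutation significance nulls, compares
   pooled group distributions and summarizes network topology by
   weighted directed degree assortativity; and
2. a **classification** track that trains a bidirectional-LSTM network
   on minimally preprocessed 64-channel recordings segmented into 10 s
   epochs, under strictly subject-wise ensemble cross-validation.

Because clinical EEG recordings of this kind are typically restricted,
both tracks are driven by a seeded synthetic-cohort generator with
known ground truth, which is first-class, tested code: every
methodological claim the package makes is validated against analytic
oracles on these synthetic cohorts.

# The information flow rate

## Model

For a transmitter series $v_i$ and receiver $v_j$ sampled at interval
$dt$, all moments are population ($1/N$) cross-covariances
$\hat C_{i,j} = \overline{v_i v_j} - \bar v_i \bar v_j$, with
$\hat\sigma_i = \hat C_{i,i}^{1/2}$, correlations
$\hat r_{i,j} = \hat C_{i,j} / (\hat\sigma_i \hat\sigma_j)$, and
derivative cross-correlations
$\hat r_{i,dj} = \hat C_{i,dj} / (\hat\sigma_i \hat\sigma_j)$ where
$\dot v_j$ is the forward difference $(v_{j,n+k} - v_{j,n})/(k\,dt)$,
$k = 1$ by default. The flow rate in nats per unit time is

$$T_{i \to j} = \frac{\hat r_{i,j}}{1 - \hat r_{i,j}^2}
  \left(\hat r_{i,dj} - \hat r_{i,j}\, \hat r_{j,dj}\right),$$

with $\hat r_{j,dj} = \hat C_{j,dj}/\hat\sigma_j^2$ (the $i = j$ case
of the derivative correlation). In this form $T_{i \to j}$ is
algebraically identical to the covariance form of the maximum-likelihood
flow estimator for linear stochastic systems,
$(\hat C_{jj} \hat C_{ij} \hat C_{i,dj} - \hat C_{ij}^2 \hat C_{j,dj})
/(\hat C_{jj}^2 \hat C_{ii} - \hat C_{jj} \hat C_{ij}^2)$.

## Numerical conventions

* **Alignment.** Every moment is computed on the first $N - k$ samples
  of both series, paired with the derivative at the same index, so all
  statistics share one index set.
* **Derivative normalization.** The printed correlation convention
  normalizes $\hat C_{i,dj}$ by $\hat\sigma_i\hat\sigma_j$ rather than
  by the derivative's own standard deviation. `pairStats(deriv_sd =
  TRUE)` selects the alternative; it rescales $r_{i,dj}$ and $r_{j,dj}$
  by a common factor and leaves zero crossings unchanged, but alters
  the normalizer components, so the default follows the printed form.
* **Degenerate pairs** (zero variance, $|\hat r_{i,j}| \ge 1 -
  10^{-10}$) are masked as `NA` in the flow matrix with one warning per
  participant rather than aborting; one flat ROI should not cost the
  participant.

## Normalization

The dimensionless flow $\tau_{i \to j} = T_{i \to j} / Z_{i \to j}$
divides by the magnitude of the receiver's entropy-rate budget. The
receiver's derivative is fitted by least squares on (receiver,
transmitter) using the same covariances:
$a_{jj} = (\hat C_{ii}\hat C_{j,dj} - \hat C_{ij}\hat C_{i,dj})/\det$,
$a_{ij} = (\hat C_{jj}\hat C_{i,dj} - \hat C_{ij}\hat C_{j,dj})/\det$,
$\det = \hat C_{ii}\hat C_{jj} - \hat C_{ij}^2$. The self term is
$a_{jj}$; the noise intensity is $g_j = dt \cdot \mathrm{MSE}$ of that
fit and the noise term $g_j/(2\hat C_{jj})$; then

$$Z = |T| + |a_{jj}| + \left|\frac{g_j}{2\hat C_{jj}}\right|, \qquad
  |\tau| \le 1 \text{ by construction}, \qquad
  \mathrm{sign}(\tau) = \mathrm{sign}(T).$$

A tiny negative MSE from round-off is clamped to zero. When $Z = 0$
(possible only for degenerate inputs) $\tau$ is reported as 0 with a
flag.

## Known estimator bias

On *independent but autocorrelated* null series
(Ornstein–Uhlenbeck paths), the plug-in estimator of $T$ carries a
positive $O(1/n)$ bias: about 0.011, 0.004 and 0.0017 at
$n = 10^4, 2\times10^4, 5\times10^4$ samples against a planted-flow
scale of 0.111. The bias vanishes with sample length but is larger
than the Monte-Carlo standard error at a few hundred replicates, so
"null flows are centered on zero" should be read as "an order of
magnitude below real flows and shrinking with $n$", which is what the
test suite asserts. For white-noise inputs the bias is negligible.

# Synthetic cohorts

## Coupled ROI dynamics

`genVarCohort()` discretizes the linear stochastic system
$dX = A X\,dt + \mathrm{diag}(\sigma)\,dW$ by Euler–Maruyama — the
same forward-difference convention the estimator uses — with a
2000-step burn-in. The default drift has self-feedback $-1$ on all ten
ROIs and three planted couplings of 0.5 (RC→LC, LO→LC, RP→LP),
echoing the central/occipital hub patterns seen in resting-state
source networks and making top-$k$ edge recovery checkable. Defaults
emulate the study conditions: $dt = 1/250$ s and 75,000 samples (five
minutes at 250 Hz); tests and the acceptance script run shorter series
(1,500–15,000 samples), stated per run. The concussed-like group's
off-diagonal drift entries are scaled by `group_gain` (default 1.5),
planting a group-level magnitude effect; stability of the scaled drift
is verified by eigenvalue check and violations are rejected with the
offending eigenvalue named.

The ground-truth flow for a planted two-node coupling is the closed
form $T_{2\to1} = a_{12}\sigma_{12}/\sigma_{11}$ at the stationary
covariance $\Sigma$ solving $A\Sigma + \Sigma A^\top + Q = 0$
(`lyapunovCov()`), giving an analytic oracle independent of the
estimator.

## Raw EEG-like recordings

`genRawEEGCohort()` mixes one 8–12 Hz band-limited oscillation and
seven $1/f$-shaped noise sources through a fixed random orthonormal
64-channel mixing matrix (drawn once per cohort seed), plus white
sensor noise at one tenth the source scale. The concussed class scales
the oscillation amplitude by $1 +$ `class_effect_size`; at 0 the labels
carry no signal. What this emulates is the *spectral* class signature
of resting EEG at the study's montage and rates (64 channels, 250/500
Hz); it deliberately does not model volume conduction, artifacts
(blinks, EMG) or nonstationary drifts, so classifier results on it
bound what architecture and protocol can do, not performance on real
clinical data.

# Group-level connectivity analysis

Participant matrices are averaged elementwise on $|\tau|$ (pairwise
exclusion of masked cells); connections with mean $|\tau| > 0.05$ are
called active. Rankings break ties deterministically by (transmitter,
receiver) position in the fixed ROI order LF, RF, LC, RC, LP, RP, LT,
RT, LO, RO.

**Permutation null.** For each participant, connection and permutation
the transmitter's samples are shuffled uniformly (destroying all
temporal structure; the receiver is untouched) and $|\tau|$ recomputed.
Permuted values are pooled across participants *and* connections into
one group-level null, whose 95th percentile is the significance
threshold for mean connections; the 5th percentile is reported for
completeness, though absolute values make it uninformative. Only the
transmitter-dependent moments are recomputed per shuffle, with the
permutations of one pair batched through a single cross-product, which
keeps 100 permutations x 90 connections tractable on full-length
series.

**Distribution comparison.** Each group's per-participant off-diagonal
$|\tau|$ values (90 per participant) are pooled; mean, median, SD,
COV = SD/mean, moment skewness and kurtosis (raw Pearson by default,
excess by flag — the raw convention makes a normal distribution read
3) are reported, and groups are compared by the two-sample
Kolmogorov–Smirnov test, the Kruskal–Wallis test and pooled-SD
Cohen's d. One caveat the package documents rather than hides: pooled
values are clustered within participants, so the iid-assuming K-S test
is anticonservative at the cohort sizes involved (type-I error near
0.2 rather than 0.05 in simulation). The calibration test therefore
checks nominal behavior on iid draws, and the power property — K-S
rejection frequency rising monotonically with the planted gain — is
what the cohort-level suite asserts.

**Subsampled shape features.** For each of 100,000 repetitions, six
participants are drawn without replacement, their values pooled and
(COV, skewness, kurtosis) recorded. Pooled moments are reconstructed
exactly from per-participant raw-moment sums ($n, \sum x, \dots, \sum
x^4$), reducing each repetition to one row of a matrix product; the
degenerate subsample ($k$ = group size) reproduces the full-group
statistics to machine precision, which the tests exploit.

# Degree assortativity

Weighted in/out degrees are column/row sums of $|\tau|$ (masked cells
contribute zero, so total in equals total out exactly). The
assortativity coefficient $r_w$ is the edge-weight-weighted Pearson
correlation between the source node's degree and the target node's
degree over all directed edges. The degree pairing at the two ends is
selectable (`out-in` default, plus `in-out`, `out-out`, `in-in`),
since weighted-directed adaptations of the classic coefficient differ
on this point; results for all four variants are one argument away.
$r_w$ is undefined (flagged, `NA`) when either endpoint degree list
has zero weighted variance — which includes the one-way star, where
every edge pairs the hub's constant out-degree with a constant leaf
in-degree; a bidirectional star yields $r_w = -1$ as intuition
expects. Undefined participants are excluded from the group comparison
with a logged count. Groups are compared by Welch's unequal-variance
t-test with Welch–Satterthwaite degrees of freedom, mean difference
with SE and 95% CI, and Cohen's d with a normal-approximation CI.

# The classifier track

## Preprocessing and epochs

Recordings are trimmed by 4 s at each end, resampled to 250 Hz
(anti-aliased IIR decimation for 500 Hz input) and low-pass filtered
at 100 Hz with a 5th-order digital Butterworth filter applied causally
(a zero-phase flag exists). Note the digital filter's response at
frequencies near Nyquist is much steeper than the analog prototype:
at 120 Hz and $f_s = 250$ Hz, bilinear warping gives ~71 dB rather
than the analog formula's ~8.6 dB; the tests assert the warped closed
form. Preprocessed recordings are cut into contiguous non-overlapping
10 s epochs (64 x 2500), the trailing partial window discarded.

## Architecture and training

The network is two stacked bidirectional LSTM layers of 24 units per
direction — the first sequence-to-sequence, the second emitting its
concatenated final hidden states (48 features) — followed by dropout
0.32 after each recurrent layer, a dense ReLU layer of 8 units with
dropout, and a 2-unit softmax trained with cross-entropy, Adam at
learning rate 0.03, batches of 12, 5 epochs. With 64 input channels
this is 31,514 trainable parameters, which the tests verify against
the closed-form count. "Bidirectional" is the reading adopted for the
recurrent layers; bilinear recurrent layers are not a standard
construct.

The forward pass, backpropagation-through-time and Adam update are
implemented in compiled code, batched over sequences so each time step
is one matrix product. Gradients are verified against central finite
differences in the test suite. Dropout masks, weight initialization
(Glorot uniform; forget-gate biases start at 1) and shuffling all draw
from R's RNG, so a single seed reproduces training bit for bit.
Epochs are z-scored per channel before input by default (disable with
`standardize = FALSE` for strictly raw amplitudes); bounded inputs are
needed for stable training at the high configured learning rate. The
validation pair is monitored only; training always runs the fixed
number of epochs.

## Cross-validation protocol

Splits are strictly participant-wise. Each repeat shuffles each class
and partitions it into `folds` cyclic test cores of size
$\lceil n/\mathrm{folds} \rceil$ (when cores overrun the class, early
participants are tested twice in that repeat); each fold then takes
one validation participant per class, a class-balanced training set of
the largest equal size, and every remaining participant joins the test
set. For 15 + 11 participants and 6 folds this yields train 8+8,
validation 1+1, test 6+2 in every fold, 30 realizations over 5
repeats, every participant tested at least once per repeat, and a hard
assertion that no participant ever sits on both sides of a divide.

Participants are classified by the median of their epoch probabilities
with a strict `> 0.5` rule. Metrics (accuracy, recall, specificity,
precision, F1, threshold-sweep ROC with trapezoidal AUC) are averaged
over realizations with normal-approximation 95% CIs; a per-participant
table counts how often each participant was tested and misclassified.

## Problem sizes in the shipped checks

The test suite and acceptance script size the cohorts so the whole
battery runs on one CPU in minutes, as the package's own choice of
study scale: connectivity cohorts of 8–15 participants per group at
1,500–15,000 samples; classifier cohorts of 30 s recordings (2 epochs
per participant) with one repeat of 6 folds, a null cohort of 8+8 at
`class_effect_size = 0` and a "strongly separable" cohort of 13+13 at
`class_effect_size = 4` (alpha amplitude x5, needed for ceiling
performance with such small training sets). At these sizes the null
cohort scores ~50% accuracy and the separable cohort AUC ~1.0. The
power-curve check uses a 5-node motif with gains (1, 2.5, 4), where
the K-S rejection frequency climbs from ~0.25 through ~0.6 to ~1.0.

# Pipeline and provenance

`runPipeline()` executes synth → flow estimation → group/assortativity
(→ classifier) from a single `runConfig()` document, writes CSV/JSON
outputs plus a provenance manifest (config snapshot, per-stage child
seeds derived deterministically from the master seed, package version,
timestamp), and reproduces every stochastic output when rerun with the
same config. On-disk formats are deliberately plain: comma-separated
numeric matrices with sidecar JSON metadata; ROI files are reordered
to the canonical label order on read.

# Limitations

* The synthetic dynamics are linear and Gaussian; the estimator's
  behavior on nonlinear or nonstationary coupling is not characterized
  here.
* Pairwise flows are unconditional; multivariate (conditional) flow,
  frequency-resolved connectivity and other graph metrics are out of
  scope.
* The EEG generator omits volume conduction and artifacts; classifier
  results on it do not transfer to clinical performance claims.
* The pooled-distribution K-S/K-W tests inherit the clustering caveat
  above; between-participant hierarchical models would be the
  statistically stricter alternative.
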