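---
title: "Subject-independent EEG affect recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-independent EEG affect recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emotion recognition from EEG is usually evaluated subject-dependently, with
the same person contributing to both training and test data. The harder and
more useful setting is *subject-independent*: a classifier trained on a pool
of subjects must generalise to a person it has never seen. Inter-subject
variability in EEG is large, so the pipeline implemented here reduces both
the temporal feature space and the spatial (electrode channel) space in an
*unsupervised, per-subject* manner before any labels are used, and only then
applies a small supervised refinement and a support vector machine, evaluated
with leave-one-subject-out (LOSO) nested cross-validation on binary valence
and arousal targets derived from 1-9 self-assessment ratings (split at the
midpoint, > 5 = high).

The pipeline stages, in fixed order:

1. **Preprocessing** — 50 Hz notch, 0.5-40 Hz band-pass (both zero-phase),
   ICA-based ocular artifact removal referenced to the bipolar EOG (or the
   prefrontal channels when no EOG exists), polyphase down-sampling to
   128 Hz, and epoching into non-overlapping windows of `w` seconds
   (`w` in {2, 5, 10}; trailing partial windows are discarded).
2. **Feature extraction** — 54 features per epoch and channel: 17
   time-domain, 17 frequency-domain, 20 time-frequency (wavelet) features.
3. **Laplacian-score feature ranking** (unsupervised, per subject).
4. **Affinity-propagation channel selection** (unsupervised, per subject) —
   the package's core algorithm.
5. **Mutual-information best-k refinement** (supervised, training folds
   only).
6. **LOSO nested cross-validation** with an SVM grid search.

## Models and estimators

### Laplacian score

All epoch-by-channel feature vectors of one subject are pooled as samples.
A k-nearest-neighbour graph (k = 5, edges symmetrised by union) over the
z-scored vectors carries heat-kernel weights `S_ij = exp(-||x_i - x_j||^2 / t)`,
with `t` set to the mean squared distance over connected pairs — a
self-tuning choice that keeps the kernel neither saturated nor empty. Each
feature r is scored

    L_r = sum_ij (f_ri - f_rj)^2 S_ij / Var(f_r),

and *lower* scores rank higher: a good feature varies smoothly along the
sample-similarity graph relative to its overall variance. The score is
implemented exactly in this printed form — with a plain variance in the
denominator rather than the degree-weighted variance of the original
Laplacian-score literature — and the graph Laplacian `L = D - S` is exposed
for inspection. Zero-variance features receive an infinite sentinel and rank
last; ties break lexicographically so rankings are reproducible. One third
of the features survive this stage by default (`top_fraction = 1/3`).

### Channel selection by affinity propagation

Within each epoch, channels are compared by the Pearson correlation of their
feature vectors, after z-scoring each feature across channels so that
large-magnitude features (band energies) do not dominate. Affinity
propagation (AP) then clusters channels by responsibility/availability
message passing (damping 0.9, preference = median off-diagonal similarity,
at most 500 iterations, convergence declared after 25 iterations with a
stable exemplar set). AP needs no preset cluster count and no random
initialisation — both properties matter for an online, per-subject method.
Exemplars are channels with `availability + responsibility > 0` on the
diagonal; the co-membership matrix `L` (zero diagonal) marks channel pairs
sharing a cluster.

Spatially adjacent electrodes record overlapping neural sources through
volume conduction, so co-activation between close channels is less
informative than co-activation at a distance. A topological distance matrix
`delta` holds shortest-path hop counts on the montage adjacency graph,
capped at `kappa_max = 2` (entries beyond the cap are 0, meaning "far").
The per-epoch co-activation graph weights are

    w_ij = L_ij * max(S_ij, 0) * f(delta_ij),   f(d) = d / (kappa_max + 1)
                                                 for 0 < d <= kappa_max, else 1,

so a 1-hop pair keeps 1/3 of its weight, a 2-hop pair 2/3, and distant pairs
full weight. Negative correlations are clamped to zero in the graph
(anticorrelation is not co-activation) but are passed to AP unchanged, which
handles them naturally. AP runs on the raw similarity; the spatial discount
applies only to the graph — discounting before clustering would distort the
cluster structure itself.

Epochs are then screened for consistency: the consensus co-membership matrix
M is the mean of the per-epoch L matrices, each epoch scores the Pearson
correlation between its vectorised L and M (diagonal excluded), and epochs
below the median are discarded. On the retained epochs each channel scores

    score = alpha * exemplar_frequency + (1 - alpha) * functional_strength

with `alpha = 0.5`; functional strength is the mean spatially-discounted
weighted degree, normalised by each channel's *maximum attainable*
discounted degree and then min-max rescaled to [0, 1]. The normalisation
matters: channels with many close montage neighbours have more of their
edges discounted, so a raw weighted degree would systematically favour
peripheral electrodes even on structureless data. Dividing by the
per-channel ceiling makes the expected strength uniform under the null.
Ties break by exemplar frequency, then channel name. Per-trial rankings aggregate to subject level
by mean rank, and the top `ceiling(fraction * C)` channels are selected at
each fraction of the 10%-100% sweep.

The consistency rule, the discount formula and the 0.5 blend are design
choices of this package: each lives in a single small function so that
alternatives can be swapped and compared.

### Mutual information refinement

Once ratings are available, each surviving feature column is scored by the
plug-in estimate of `MI(x, y) = H(x) + H(y) - H(x, y)` in bits, with the
feature discretised into 8 equal-frequency bins (features with at most 8
distinct values are used as-is, which keeps MI symmetric for discrete
inputs). Zero-MI features are dropped; the top `k` (default 24 columns)
are kept, ties resolved by the upstream unsupervised rank. The estimate is
clipped at zero since the plug-in estimator can go marginally negative
through finite-sample noise.

### Classification and evaluation

The outer loop holds out one subject per stimulus; all selection
(aggregation of the training subjects' unsupervised rankings, MI
refinement, grid search) sees training subjects only, which the report's
audit table records fold by fold. The inner loop is a stratified 3-fold
split over training subjects; the grid is cost `C` in {.025, .5, 1, 10, 100}
for linear and RBF kernels with RBF scale in {0.001, 2, 10, 50, 100}
(interpreted as the RBF gamma). Class weights are inverse-frequency.

Two scoring details deserve a note, both consequences of folds that hold a
single subject with a single true label:

* the positive-class F1 of one fold is degenerate (a perfect all-"low"
  prediction scores 0), so the headline number is the *pooled* epoch-level
  F1 over all LOSO predictions, alongside the majority-vote subject-level
  F1; per-fold rows remain in the report for inspection;
* inner-loop model selection uses *macro*-averaged F1 on validation
  predictions pooled across the inner folds — with the positive-class F1 a
  degenerate always-"high" predictor would win ties on noisy small
  validation sets. Exact ties resolve to the earliest grid row, and linear
  rows precede RBF rows, encoding a preference for the more stable linear
  kernel.

Monotonicity of F1 over channel fractions is deliberately not asserted
anywhere: performance typically plateaus once the informative channels are
included.

## The synthetic data generator

Real affect benchmarks are access-restricted, so the package ships a
generator that emulates their structure — S subjects x T trials x C channels
at a configurable rate — with a known ground truth. Each channel carries:

* a 1/f^alpha background (default alpha = 1, sd 1), synthesised in the
  frequency domain;
* one amplitude-modulated oscillation per canonical band, amplitudes
  delta 1.5, theta 1.0, alpha 1.0, beta 0.8, gamma 0.4 — a roughly
  1/f-consistent profile of the rhythms a scalp recording shows;
* a common-phase 50 Hz mains component (amplitude 0.5);
* blink transients: 300 ms biphasic raised-cosine pulses at 4 events/min,
  peak amplitude 60 with an `exp(-d/0.3)` decay from the front of the
  montage. The amplitude is chosen so frontal blink peaks sit ~6x the
  background sd, matching the physiological ratio of blinks (100-200 uV)
  to background EEG (20-50 uV). Blinks are mirrored into two synthetic EOG
  channels of opposite polarity, providing the bipolar reference;
* neighbour leakage (coefficient 0.2) emulating volume conduction — this is
  precisely the nuisance the spatial discount is designed to suppress.

Each trial has a hidden binary state, balanced within subject; valence and
arousal ratings are drawn from Uniform(6, 9) under the high state and
Uniform(1, 4) under the low state, so both targets reflect the planted
effect. In the high state the informative channels' oscillations in the
informative bands are scaled by `sqrt(effect_size)` (power ratio
`effect_size`). Crucially, the informative channels *share* one oscillation
draw (frequency, phase, slow envelope) per band and trial while all other
channels draw independently: the planted set genuinely co-activates, which
is the structure the channel-selection algorithm is built to detect — a
generator that only shifted marginal band power would not exercise it.
`effect_size = 1` disables the planted structure entirely — both the class
power shift and the co-activation sharing — so it is a true null under
which no channel should be selected above chance.

What the generator does **not** emulate: dipole forward modelling and
realistic scalp topographies, non-stationary artifact mixtures (EMG,
electrode pops), subject-specific spectral idiosyncrasies, or rating noise
(labels are perfectly consistent with the planted state). Passing the
recovery tests therefore demonstrates that the algorithms detect planted
co-activation and band-power structure under realistic noise, line
interference and blinks — not that they reach any particular accuracy on
real recordings.

## Numerical choices and degenerate inputs

* **Welch PSD**: Hamming window, segment length `min(n, 256)` samples
  (2 s at 128 Hz), 50% overlap, per-segment mean removal, one-sided density.
* **Entropies**: ApEn and SampEn with m = 2, r = 0.2 sd (field defaults),
  vectorised over template distance matrices. Spectral entropy uses log2 of
  the sum-normalised PSD without bin-count normalisation (a monotone choice
  that affects no ranking).
* **Wavelets**: 6-level db4 pyramid with symmetric extension; each level
  summarised as log10 mean squared detail coefficients (floor -30 for
  silent sub-bands); each of the 7 sub-bands contributes the mean and sd of
  its Teager-Kaiser energy sequence, giving the (levels+1)*2 = 14 TK
  features.
* **Hurst**: rescaled-range over dyadic windows >= 8 samples; DFA was
  rejected to keep the estimator simple and dependency-free.
* **Fractal dimensions**: Higuchi with k_max = 10; Katz in its standard
  log10 form.
* **Zero crossings** are counted on the mean-centred signal with exact
  zeros collapsed (a zero-touching crossing counts once).
* **Spectral slope** features are the intercept, slope, mean squared
  residual and R^2 of the least-squares line through log10 PSD vs log10
  frequency over 1-40 Hz; the residual statistics are computed on the
  log-power scale, matching the scale on which the line is fit.
* Constant (zero-variance) epochs yield zeros (never NaN) for
  variance-normalised features, and are flagged in the tensor's
  `zero_variance` attribute.
* The gamma band runs from 30 Hz to Nyquist as defined, even though the
  default band-pass ends at 40 Hz; its content then reflects filter
  roll-off. Keeping the printed definition preserves the five-band feature
  layout regardless of preprocessing choices.
* **FastICA** uses deflation (one-unit) updates with the logcosh contrast
  and deterministic unit-vector initialisation. Symmetric updates were
  tried first and oscillate indefinitely on 32-channel data whose sources
  are mostly near-Gaussian; deflation isolates the strongly non-Gaussian
  blink component within a few iterations. Removal is skipped (with a
  warning and a provenance flag) only if a majority of components fail to
  converge or a component slated for removal did; at most 30% of components
  may be removed, strongest EOG correlates first, threshold |r| >= 0.7.
* **Filters**: Butterworth order 4 band-pass and a quality-30 biquad notch,
  both applied forward-backward (zero phase). Channel means are removed
  before filtering and restored afterwards, which keeps DC exactly intact
  through the notch and avoids edge transients from offsets.
* **Montage geometry** is schematic: a checkerboard grid for the
  32-channel set and an equiangular ring for the 14-channel set, designed
  so that the adjacency rule (distance <= 1.1x the minimal spacing) yields
  a connected graph whose hop counts behave like electrode neighbourhood
  order. Only hop counts enter the algorithm, so the schematic geometry is
  sufficient; physical coordinates would change nothing qualitative.

## Problem sizes used in tests and the acceptance script

The packaged experiments run the full pipeline at reduced scale so the
whole suite completes on a single CPU: recovery experiments use 20-second
single-subject trials (10 epochs at w = 2 s) over 10-20 seeds, and the LOSO
experiment uses 12 subjects x 8 trials of 12-second recordings sampled at
128 Hz with the 25% channel fraction. These sizes were chosen as the
smallest at which subject-level variability and inner-fold model selection
remain meaningful; the algorithms scale unchanged to full-length benchmark
recordings.

## Known limitations

* The plug-in MI estimator is biased upward at small n (about
  `(bins-1)/(2 n ln 2)` bits); selection only ranks features, so the bias
  cancels, but reported MI values should not be read as unbiased estimates.
* AP on near-degenerate similarity matrices (exact ties) can oscillate;
  damping 0.9 makes this rare, and non-convergence is reported in the
  clustering object rather than hidden.
* With very few subjects the inner CV has little signal; model selection
  then behaves close to the linear-first tie-break. This is a property of
  the regime, not of the implementation.
* The EDF writer targets interoperability checks (16-bit quantisation, one
  record per second), not archival fidelity.
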