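---
title: "Quantifying dynamical non-stationarity in multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamical non-stationarity in multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstates)
```

## The model

Resting EEG is treated as a piecewise process: stretches of
quasi-stationary dynamics interrupted by switches between states. Rather
than tracking changes in stochastic moments (mean, variance, spectrum),
the package looks for changes in the parameters of a dynamical model of
the signal. Each channel of each epoch is divided into half-overlapping
windows, and every window is summarised by the least-squares fit of a
polynomial one-step map: the next sample is predicted from all monomials
of total degree at most `p` in the `m` most recent samples,

x[t+1] = a_1 + a_2 x[t] + ... (all monomials of degree <= p in
x[t], ..., x[t-m+1]),

giving a coefficient vector of length `choose(m + p, p)` per window. Two
windows are compared by the Euclidean distance between their coefficient
vectors, so windows governed by the same dynamics lie close together
regardless of where in the epoch they occur.

Windows are then clustered in coefficient space with a two-stage
affinity-propagation scheme (below). Temporally adjacent windows with the
same cluster label are glued into quasi-stationary segments, and the epoch
is summarised per channel by two complementary numbers:

* `n_states` - the number of distinct states (clusters) visited;
* `mean_seg_len_s` - the mean duration of the glued segments, in seconds.

A signal can become more non-stationary by visiting more states at
unchanged dwell times, or by alternating faster among the same states;
the two measures separate these mechanisms.

## Choices in the window model

The defaults are `window_len = 128` samples, half overlap, `m = 3`,
`p = 1`, and a numerically invisible ridge (`1e-8`) on the normal
equations. The embedding dimension and polynomial order deserve comment.
A cubic default (`p = 3`) looks attractive because the map family is
explicitly non-linear, but the variance of the higher-order coefficient
estimates at a 128-sample window is large: on oscillatory test signals it
dominates the Euclidean distance and buries the separation between
regimes that differ in their linear dynamics (narrowband alpha-like vs
broadband rhythms). With `m = 3, p = 1` the fitted map is an AR(3)
predictor - four coefficients, each estimated precisely - and regime
recovery on synthetic piecewise signals improves from roughly 84% to
above 95% window agreement under identical conditions. Both parameters
are plain arguments; fitting chaotic map regimes in the test-suite uses
`p = 2` or `3` explicitly, where the window content makes those
coefficients identifiable (the fits are exact on noise-free maps). The
precondition `window length >= 2 * coefficient count` guards
identifiability throughout.

Per-segment amplitude normalisation is off by default: only the epoch
mean is removed. A z-scored variant would discard amplitude information
that, through the interplay of observation noise and coefficient
attenuation, often carries real discriminative signal.

## Two-stage clustering

Affinity propagation treats every window as a potential cluster centre
(exemplar) and exchanges responsibility/availability messages until an
exemplar set stabilises. Similarity is negative squared Euclidean
distance; the per-point preference (self-similarity) controls how many
exemplars survive. The implementation is deterministic: damping 0.9, a
tiny seeded jitter that only breaks exact message symmetries, ties broken
toward the lowest index, and a greedy add/drop refinement of the exemplar
set afterwards, which repairs the occasional poor fixed point of message
passing (a distant two-point cluster can fail to accumulate
self-evidence at very negative preferences).

The first pass runs on all windows with the uniform median-similarity
preference. This routinely over-partitions: windows of one regime split
into sub-clusters, and windows straddling a regime switch form small
bridge fragments. The second pass therefore re-clusters the stage-1
exemplars only:

* exemplars of clearly undersized clusters (below a quarter of the median
  cluster size) are absorbed by their nearest surviving exemplar first -
  but only when that host is closer than the typical between-exemplar
  distance, so a small but genuinely distant state is never swallowed;
* the remaining exemplars are re-clustered with preferences anchored
  midway between the within-state similarity scale (median similarity of
  windows to their exemplar) and the between-state scale (median
  off-diagonal exemplar similarity), scaled by `sqrt(max size / size)` so
  that exemplars that unified many windows stay attractive;
* each window inherits its stage-1 exemplar's final label, exemplars are
  relocated to cluster medoids, and windows are re-assigned once.

On well-separated instances small enough for exhaustive search (up to 8
points) the result attains the global optimum of the net-similarity
objective in every tested instance; on piecewise-oscillator signals the
scheme recovers 2, 3 and 4 planted regimes with monotone fidelity. Both
behaviours are enforced by the test suite.

## The synthetic cohorts

No public recording accompanies the analyses the package implements, so
validation rests on a regime-switching generator with exact ground truth.
A regime is either a damped stochastic oscillator - an AR(2) process
parameterised by peak frequency and pole radius, with the pole angle
corrected so the spectral peak lands on the requested frequency - or a
deterministic polynomial map (logistic, Henon, Ulam and friends appear in
the tests). Signals alternate regimes cyclically with fixed or
exponential dwells; oscillators continue across switches from the last
two samples, so there are no amplitude jumps at boundaries.

The default oscillator library pairs well-spaced centre frequencies with
alternating narrowband/broadband pole radii (6 Hz at 0.97, 11 Hz at
0.75, 27 Hz at 0.97, 30 Hz at 0.72, 2.5 Hz at 0.85). The pairing is
deliberate: AR(2) coefficients depend on frequency only through
`cos(2*pi*f/fs)`, so nearby frequencies alone separate poorly in
coefficient space, while bandwidth differences - narrowband alpha versus
broadband beta being the natural EEG analogy - separate cleanly. The
library maximises the minimum pairwise coefficient distance over the
reachable AR(2) region.

Cohorts mirror a longitudinal design: every subject is seen at three
visits, in two conditions, with ages 10, 11.5 and 13 years plus a
per-subject jitter (SD 0.4 y) that is constant across visits. Two effect
topographies with known ground truth are available:

* a localized effect - the regime count K rises with visit on designated
  focal channels only;
* a global effect - the mean dwell time falls with visit on every
  channel.

The canonical study conditions are frozen in `demo_cohort_spec()`:
12 subjects, 8 channels (3 focal), 24-second epochs at 256 Hz, K rising
2, 3, 4 on focal channels, dwell falling 2.0, 1.5, 1.0 s globally, and
additive observation noise at 10% of each channel's SD. At these sizes
the per-channel state-count estimate rises monotonically with planted K
(roughly 2.0, 2.8, 3.1 on average) and the segment-length estimate
tracks the dwell gradient, which is what the cohort-level analyses need.

The `spectral_coupling` scenario adds two couplings for the spectral
analysis: a 2.5 Hz narrowband component whose amplitude is proportional
to the channel's switch rate (shorter dwells carry more low-frequency
power), and, on focal channels, a stationary 10 Hz component whose
amplitude grows with the channel's regime count. The second coupling is
imposed rather than emergent, for a structural reason worth recording: a
"pure" amplitude ladder of 10 Hz regimes is invisible to this method,
because the map coefficients of a linear oscillator do not depend on its
amplitude (only the noise-attenuation bias does, weakly). Subject-level
regime-count jitter and lognormal dwell jitter (sigma 0.3) decouple the
two couplings from each other and from the visit gradient.

What the generator does not emulate: volume conduction (an optional
mixing matrix exists but is off), eye-blink or movement artifacts,
1/f background spectra, and any realistic 128-channel geometry. Passing
tests therefore certify the estimation machinery against the piecewise
model class, not physiological realism of the signals.

## PLS and its resampling

Group/condition effects on each measure are assessed with task PLS. The
data matrix has one row per participant within condition within group and
one column per electrode. Mean-centered PLS decomposes the
group-by-condition cell means centered by their grand column mean;
contrast PLS decomposes the covariance between a-priori orthogonal,
zero-sum contrasts and the cell means. Each latent variable carries a
singular value, condition loadings and electrode loadings.

Significance uses permutation: cell assignments are reshuffled within
subjects (both factors are within-subject in the longitudinal design),
the PLS is refit, and the p-value is the plain exceedance proportion of
permuted singular values above the observed one - no add-one correction,
so a p of exactly 0 is possible and means "no permutation exceeded".
Stability uses bootstrap resampling of participants within cells;
resampled electrode loadings are sign-aligned to the original by inner
product per LV, and the bootstrap ratio is the original loading over the
bootstrap SE, with `|BSR| >= 2` read as stable. A collapsed bootstrap
distribution (zero SE) is reported as an infinite sentinel with a flag
rather than silently dropped.

Calibration of the permutation test is checked on measure-level null
cohorts (subject and channel random effects, no group or condition
effect): across 200 null cohorts of the study shape, the first-LV
rejection rate at 0.05 must fall in [0.02, 0.09]. The null is generated
at the measures level because only the exchangeability of cell labels
within subjects is at stake and the signal pipeline, run identically on
every cell, preserves it; this keeps the check inside a desk-scale
compute budget (the vignette-scale problem sizes throughout - 24 s
epochs, 8 channels, 12 subjects, 500 permutations/bootstraps - were
chosen on the same grounds).

## Spectral correlates

Relative power uses an averaged modified periodogram (Hann taper, 2 s
windows, half overlap) normalised per channel over the 1-30 Hz band, so
it is invariant to amplitude scaling. Each measure is correlated with
relative power per channel and frequency bin across pooled
subject-by-condition rows, controlling the other measure by first-order
partial correlation. Pooling merges visits and conditions; a
per-condition option exists. The focal-versus-nonfocal contrast of the
alpha coupling is evaluated on channel aggregates (mean partial
correlation over focal channels and the 8-12 Hz bins) because individual
channel-bin coefficients at ~70 pooled observations have standard errors
near 0.12 and their signs flip by sampling noise alone.

## Numerical and edge-case behaviour

* Zero-variance windows are flagged degenerate, receive the
  constant-only fit, and are recorded in the distance-matrix report.
* An all-zero distance matrix short-circuits to a single state.
* A stage-1 pass yielding a single exemplar skips stage 2.
* Epochs shorter than one window, mismatched coefficient lengths,
  non-orthogonal contrasts, and empty manifest rows raise errors naming
  the offending object; degeneracies are never silently repaired.
* Window starts and sample indices are 0-based and half-open in all file
  formats; in-memory R indices are 1-based only where they index R
  vectors.
* All randomness flows from explicit integer seeds; identical inputs and
  seeds give byte-identical outputs, including across the two-stage
  clustering and both resampling procedures.

## Known limitations

Estimated state counts are not absolute: they depend on the window
length, model order and preference rules, and the package reports them
for contrasts between groups or conditions, not as physiological
constants. Regimes closer in coefficient space than roughly the
coefficient-estimation noise at the chosen window length merge; amplitude
differences alone are invisible by construction of the distance. The EDF
adapter implements the minimal single-record, 16-bit layout for
interchange and round-trip testing, not the full EDF+ annotation
standard.
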