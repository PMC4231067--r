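---
title: "Classifying heart sounds with LPC features and a cuckoo-search-tuned SVM ensemble"
author: "pcgclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heart sounds with LPC features and a cuckoo-search-tuned SVM ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgclassify)
```

## The problem

A phonocardiogram (PCG) records the mechanical sounds of the heart at the
chest wall. Automatic classification of individual heart tones — the normal
sounds S1–S4, split variants, ejection clicks, opening snaps, and the
noise-like murmurs and rumbles of turbulent flow — is the core of any
"smart stethoscope". Two properties make this hard: PCG signals are
strongly non-stationary (each tone lasts tens of milliseconds and its
spectrum evolves), and the number of clinically distinguishable sound
morphologies is large (twelve classes here).

`pcgclassify` implements a complete pipeline:

1. **Segmentation** isolates each heart tone in a *variable-size* time
   window (fixed frames, as used in speech coding, straddle tone
   boundaries).
2. **Feature extraction** fits a 24th-order all-pole (Linear Predictive
   Coding) model to each windowed tone; the 24 denominator coefficients
   summarize the spectral envelope.
3. **Classification** uses a one-against-others ensemble of soft-margin
   SVMs, one binary classifier per class.
4. **Model selection** is done by a Modified Cuckoo Search (MCS) that
   jointly picks which LPC coefficients to use (a 24-bit mask) and, for
   every ensemble member, the kernel family, its parameter and the penalty
   `C`, scored by leave-one-out balanced accuracy.

## Segmentation: variable windows from a Shannon-energy envelope

The detector computes a per-frame normalized Shannon energy,
`-mean(x^2 log x^2)` (frames of 20 ms, hop 10 ms), which emphasizes
medium-amplitude activity over both background noise and isolated spikes.
Contiguous regions above a fraction (default 0.2) of the per-recording
envelope maximum become candidate windows; regions closer than 50 ms merge
(so the two lobes of a split tone form one window), regions shorter than
30 ms are dropped, and boundaries get 10 ms of padding. The threshold is
relative to the envelope maximum, so segmentation is invariant to the
overall gain of a recording. All constants live in
`segmentation_config()`. Degenerate cases are defined exactly: silence
yields an empty segment list, `0 log 0` is taken as 0, and a constant
recording has a constant envelope.

No pre-filter is applied before segmentation; with band-limited clinical
front-ends this is where a high-pass filter would slot in.

## LPC features and the spectrum-match fitness factor

Each segment is Hamming-windowed; its biased autocorrelation `r[0..24]`
feeds the Levinson–Durbin recursion, which solves the Toeplitz
Yule–Walker equations in O(p²) and guarantees a stable all-pole filter
`G / A(z)`, `A(z) = 1 + a_1 z^{-1} + ... + a_p z^{-p}`. The feature vector
is `(a_1, ..., a_24)`; the gain `G` is excluded because it carries
loudness, not morphology. Features are therefore invariant to amplitude
scaling of the input.

Why order 24? Pathological tones can show on the order of nine spectral
peaks; each peak needs a conjugate pole pair, so order 18 is the minimum,
and order 24 removes the residual low-frequency mismatch an order-18 fit
leaves. The package exposes the order as a parameter, and the test suite
asserts the monotonicity that justifies it: over a seeded synthetic tone
set, the mean spectrum match does not decrease from order 5 to 18 to 24.

Agreement between a model spectrum `Hf` and a reference spectrum `Hs` on a
shared `N = 512`-point linear grid over `[0, fs/2]` is measured by the
fitness factor

```
FF = 100 * (1 - sum (Hf - Hs)^2 / sum Hs^2)   (clamped below at 0),
```

with both spectra normalized to unit energy first (the LPC gain scaling
relative to a signal spectrum is arbitrary). Two design choices deserve a
note. *Energy* normalization is used rather than peak normalization:
dividing by the single maximum bin makes the whole score hostage to the
noisiest point of the spectrum. And the *squared* (energy) difference is
used rather than an absolute one: under the absolute form, the sampling
noise floor of an order-24 fit from 8192 samples already costs several
percent per bin, capping any achievable match in the low 90s — no
estimator could reach the high-90s agreement that order-24 fits are
reported to attain, whereas the energy form scores such fits at 99%+ and
degrades smoothly as the model order drops.

## The classifier: one-against-others SVMs

Binary members solve the standard soft-margin dual (via libsvm through
e1071) with one of four kernels: linear `x·y`, quadratic `(x·y+1)²`,
polynomial `(x·y+1)^u`, and RBF `exp(-||x-y||²/(2σ²))`. Quadratic is kept
as a named kind (not just `u = 2`) to mirror the fixed-kernel comparison
systems. For `m` classes, member `i` is trained on class `i` versus the
rest; prediction is the argmax of the members' real-valued decision
functions, with exact ties resolved to the earliest class in sorted class
order. Argmax aggregation (rather than sign voting) is the standard
resolution when zero or several members fire.

Every trained member stores its support vectors, dual coefficients and
bias, so decision values can be recomputed without the solver — this is
the serialization contract: a model written with `save_model()` and read
back with `load_model()` reproduces predictions exactly.

LPC coefficients are already scale-free, so no feature standardization is
applied by default.

**Numerical choice — solver tolerance.** The SMO termination tolerance
defaults to 0.01 rather than libsvm's 0.001. Model selection sweeps `C`
across twenty octaves; at extreme penalties on overlapping classes the
dual is ill-conditioned and a tight tolerance costs orders of magnitude in
iterations while leaving the fitness ranking of genomes unchanged.
Analytic unit tests pass a tighter tolerance explicitly.

## Evaluation: balanced accuracy under leave-one-out

A one-vs-rest reduction gives per-class confusion counts; sensitivity
`TP/(TP+FN)` and specificity `TN/(TN+FP)` combine into balanced accuracy
`(Se + Sp)/2`, which is insensitive to the 1-vs-11 imbalance inherent in
one-against-others evaluation. Undefined metrics (zero denominators) raise
an error instead of silently returning 0 — a silent zero would corrupt
fitness rankings. Leave-one-out retrains the full ensemble `n` times; the
report's "Average" is the unweighted mean of per-class balanced accuracies
and "Average var." their sample variance.

## Model selection: Modified Cuckoo Search

A candidate ("egg") is a point in `[0,1]^d` with `d = 24 + 3m`: 24 relaxed
mask genes (thresholded at 0.5 — MCS is a continuous-space method, and
relaxation plus thresholding is the minimal faithful extension to a mixed
space) plus per-member kernel-kind, kernel-parameter and penalty genes.
`σ` decodes log-uniformly into `[2^-10, 2^3]`, `C` into `[2^-5, 2^15]`,
and the polynomial degree into 1..6 — these parameters act
multiplicatively, so linear decoding would waste most of the range.

Each generation:

* the worst quarter of nests is abandoned; each replacement egg is a Lévy
  flight (Mantegna's algorithm, stability index 1.5) seeded at a randomly
  chosen top nest, with step scale `A0/sqrt(G)` — heavy-tailed global
  exploration that decays as the search matures;
* each top-quarter nest is recombined with a random top nest: the
  candidate sits at the golden-ratio point of the connecting line, nearer
  the fitter endpoint, and replaces a random nest if fitter; drawing the
  same nest triggers a fine local walk at scale `A0/G²`;
* the best nest takes two greedy hill steps with a 1/5-success-rule
  adapted Lévy scale, accepting improving *and* neutral candidates — this
  is the package's reading of MCS's "greedy promotion of the best
  solutions". Adaptive scaling turns the tail of the search from algebraic
  into geometric convergence (verified on a 10-dimensional sphere
  benchmark, which the optimizer solves to below 1e-6 within 5000
  evaluations), and neutral acceptance lets the climber drift across the
  plateaus that the thresholded mask genes create instead of collapsing
  its step on them;
* elitism: the best nest always survives, so the best-fitness trace is
  monotone.

Fitness is either leave-one-out average balanced accuracy (maximized) or
the total support-vector count of the full-data ensemble (minimized), a
complexity surrogate. Invalid genomes (empty mask) receive the worst
fitness instead of raising, so the search continues past them. Fitness
values are cached by decoded genome — thresholding makes many positions
decode identically — and a cached value equals a fresh evaluation exactly.
Runs are a pure function of the seed: identical seeds give identical best
genomes, fitness values and traces.

The original MCS description leaves population size, generation budget,
discard fraction and parameter ranges open; the defaults here
(25 nests, discard 0.25, top 0.25, `A0 = 1`) follow common practice for
the method and are all exposed in `mcs_config()`.

## The synthetic data generator

No public, redistributable PCG corpus covers these twelve tone classes, so
the package ships a seeded generator that emulates the *unit the
classifier operates on*: one segmented heart tone (or merged tone pair,
for splits) per short recording — not a full cardiac cycle with
respiration and ambient noise.

Each class is a set of components: damped sinusoids
(`a e^{-t/τ} sin(2π f t)`, `τ = duration/4`) for valve tones, and
Hann-enveloped Butterworth-bandpass noise bursts for murmurs. The default
table renders, at 4 kHz (PCG energy lies below 1 kHz, so 4 kHz keeps all
content below Nyquist while keeping FFTs cheap):

* S1–S4 as stacks of two or three low-frequency resonances — real heart
  tones have rich spectral envelopes, which is exactly what makes a
  high-order all-pole fit informative;
* split S1/S2 as exactly two damped sinusoids 40–45 ms apart (the merge
  rule of the segmenter joins them into one window);
* ejection click and opening snap as brief higher-frequency transients;
* the three murmurs as broadband noise bursts differing in band and
  duration, and the diastolic rumble as all-sub-150-Hz noise.

Tone centers follow a coarse log-spaced ladder (adjacent ratios ≈ 1.35) so
that the per-realization frequency jitter of ±10% cannot move one class
into its neighbour's band; duration jitters by ±20% and amplitude by ±20%;
white noise is added at 25 dB SNR, a clean bedside recording level. The
table is chosen for spectral distinctness under jitter — it is *not* a
hemodynamic model, and passing tests on it demonstrates the pipeline's
mechanics, not clinical performance. Real recordings differ in ways the
generator deliberately omits: multi-cycle structure, respiration and
handling noise, inter-patient variability of tone morphology, and timing
cues (a split tone differs from its parent mainly in timing, which
spectral-envelope features cannot see; the synthetic split classes are
therefore given shifted resonances).

A dataset is a pure function of `(per_class_count, sample_rate, seed)`;
the study-scale dataset is 6 recordings per class, 72 in total.

## Problem sizes and runtime

The test suite and the acceptance script use: 200 random autocorrelation
sequences for the Levinson–Durbin oracle check; 20 signals of 8192 samples
for order-24 parameter recovery (coefficient RMSE below 0.05, spectrum
match against the true filter at or above 99%); 60 seeded tones for the
order-monotonicity property; 10 seeds × 5000 evaluations for the sphere
benchmark; and the 72-recording dataset with 15 nests × 20 generations
(about 215 fitness evaluations, each a 72-fold leave-one-out) for the
end-to-end comparison against the fixed-kernel baselines
(SVM-poly `u = 3`, SVM-rbf `σ = 1`, SVM-quad, all with `C = 1` and all 24
coefficients).

## Known limitations

* The generator's spectra are qualitative; clinical fidelity was never the
  goal, and results on it do not transfer to patients.
* Segmentation assumes tones separated by quieter intervals; continuous
  murmurs spanning a whole cycle would merge into one window.
* LOO fitness with full retraining is honest but expensive; the fitness
  cache only helps when positions decode to the same genome.
* Cardiac-cycle state labelling (which window is S1 versus S2) is out of
  scope: windows are classified independently.
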