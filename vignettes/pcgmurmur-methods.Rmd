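---
title: "Methods: segmentation and murmur classification of pediatric phonocardiograms"
author: "pcgmurmur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and murmur classification of pediatric phonocardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgmurmur)
```

## The problem

A phonocardiogram (PCG) records the acoustic waveform of the heart. The
first and second heart sounds, S1 and S2, mark the closure of the
atrioventricular and semilunar valves; between them lie two "closed-valve"
intervals — CAV, the systolic interval from the end of S1 to the start of
S2, and CSV, the diastolic interval from the end of S2 to the start of the
next S1. Pathological murmurs of congenital heart disease (CHD) — septal
defects, patent ductus arteriosus, patent foramen ovale and the like — live
in precisely these intervals, which makes them the natural place to look for
discriminative features. The difficulty in children is twofold: murmurs of
moderate and severe disease can overlap S1/S2 in both time and frequency,
defeating plain envelope or wavelet segmentation, and pediatric heart rates
are fast and widely distributed, so the adult assumption that systole is
always shorter than diastole does not hold.

`pcgmurmur` implements a complete screening chain for this setting:
denoising, heart-sound segmentation, closed-valve feature extraction, and a
small neural-network classifier, plus a synthetic PCG generator that makes
every stage testable without clinical recordings (none are publicly
deposited for this problem).

## Preprocessing and denoising

Recordings are resampled to the canonical analysis rate of 2 kHz (heart
sound energy lies well below 1 kHz) with polyphase FIR anti-alias
resampling from the `signal` package, and peak-normalized to ±1 so that
amplitude differences between subjects and devices drop out. An all-zero
recording is rejected rather than passed through: nothing downstream is
defined on silence.

Denoising is wavelet shrinkage: a 5-level discrete wavelet transform with
the Daubechies 6 basis, soft thresholding
$W_{\text{new}} = \operatorname{sgn}(W)\,(|W|-T)$ for $|W| \ge T$ (zero
otherwise) of all detail coefficients, and inverse transform. The threshold
is the universal rule $T = \hat\sigma\sqrt{2\ln n}$ with
$\hat\sigma = \operatorname{median}(|d_1|)/0.6745$ estimated from the
finest-scale details. Two choices here were genuinely open and are package
decisions: one *global* threshold estimated from level-1 details is applied
to all levels (per-level thresholds are a defensible alternative; the global
variant is the classical construction), and the approximation band is never
thresholded, because it carries the low-frequency S1/S2 energy. Boundary
handling is symmetric signal extension, which minimizes edge artifacts on
short records; with $T = 0$ the analysis–synthesis chain reproduces the
input to ~1e-15, which the test suite asserts.

No R wavelet package is declared as a dependency: the transform is part of
the method's core and is implemented in the package (a dozen-line filter
bank), with perfect reconstruction and band-energy tests guarding it.

## Segmentation

The segmentation chain is:

1. **Band decomposition.** The denoised signal is decomposed into per-level
   band reconstructions A1–A5 and D1–D5, each the inverse transform of one
   coefficient band with all others zeroed, so that
   $A5 + D1 + \dots + D5$ equals the input exactly. At 2 kHz, D4 covers
   roughly 62.5–125 Hz and D5 31.25–62.5 Hz — the heart-sound bands.
2. **Hadamard recombination.** $S = D4 \cdot D5$ element-wise. S1 and S2
   are broadband and excite both bands *simultaneously in time*, so their
   product is large; murmur energy (typically 100–600 Hz) reaches D4 only
   marginally and D5 barely at all, so the product suppresses it in both
   frequency *and* time — this is what lets the method survive murmurs
   that overlap S1/S2.
3. **Envelope.** The recombined signal is normalized to ±1 and framed into
   20 ms windows at 10 ms hops (N = 40 samples per frame at 2 kHz); each
   frame's average Shannon energy
   $E_s = -\tfrac1N \sum s^2 \log s^2$ (with $0\log 0 := 0$) is computed and
   the frame series z-scored. Shannon energy emphasizes medium-intensity
   components, compressing both the noise floor and the dominant peaks.
4. **Instants.** Envelope peaks (sign change of the first difference,
   plateaus resolved to the leftmost sample) are candidate instants. Two
   constraints filter them: a candidate must be the envelope maximum within
   a 100 ms range centered on it, and adjacent candidates closer than
   180 ms are resolved by dropping the lower-magnitude one. The envelope is
   only sampled every 10 ms, so each surviving peak is refined by fitting a
   parabola through the three envelope samples around it — this matters at
   high heart rates, where the diastolic gap approaches the 180 ms bound
   and a 10 ms quantization error can push a legitimate pair under it.
   Gaps *longer* than 500 ms are flagged rather than repaired: removing a
   candidate can only widen a gap, and a slow heart (60 bpm has a ~620 ms
   diastolic gap) produces them legitimately.
5. **Heart rate.** With instants alternating S1, S2, S1, …, each two-step
   span $p_{i+2}-p_i$ is one cardiac cycle, and
   $\mathrm{HR} = 60 \big/ \tfrac{1}{M-2}\sum_{i=1}^{M-2}(p_{i+2}-p_i)$.
6. **Labeling.** The pediatric rule: at HR ≤ 130 bpm systole (S1→S2) is the
   shorter of the two gaps in any consecutive triple; above 130 bpm it is
   the longer one. Each triple votes for one of the two alternating label
   assignments and the majority wins; a tie (or all-equal gaps) is an
   error, not a guess. The boundary itself, 130 exactly, takes the low-rate
   branch.
7. **Durations and intervals.** Windows of 120 ms (S1) and 100 ms (S2) are
   centered on each instant; envelope points below 10% of the instant's
   energy are marked, and the marked points nearest the instant on each
   side become the sound's start and end (clamped to the window edge and
   flagged if a side never crosses). The 10% rule is applied to the raw
   (pre-z-score) average Shannon energy: z-scored values are negative over
   most of the record, and "10% of" a negative number is not a meaningful
   threshold. CAV and CSV then follow per cycle from the S1/S2 boundaries;
   edge cycles missing a flanking instant are discarded.

## Features

Ten features per recording, each averaged over all complete cycles: the
maximum, minimum and mean absolute amplitude of the denoised signal over
CAV and over CSV (6 time-domain features), and the maximum and mean Welch
power spectral density of the CAV and CSV samples (4 frequency-domain
features). The *denoised PCG* — not the recombined product — is the signal
sampled here: the product exists to sharpen localization, while the murmur
content that separates the classes lives in the denoised waveform.

The Welch estimator uses a Hann window with 50% overlap and a segment
length of 128 samples (64 ms at 2 kHz), falling back to a single
full-interval periodogram when an interval is shorter than one segment —
diastole at high rates would otherwise be unmeasurable. PSD max/mean are
taken over the full 0–1000 Hz band. Per-cycle PSDs are reduced to max/mean
first and averaged across cycles second. Cycles whose CAV or CSV came out
empty (clamped boundaries crossing) are excluded from the averages.

## Classifier

A 10–10–1 perceptron: 10 inputs, 10 hyperbolic-tangent hidden units, one
linear output, trained to 0/1 targets under mean squared error by
Levenberg–Marquardt — each iteration solves the damped normal equations
$(J^\top J + \mu I)\,\delta = J^\top r$ and accepts the step only if the
error drops, multiplying $\mu$ by 10 on rejection and dividing by 10 on
acceptance. The conventional "initial learning rate 0.01" is realized as
the initial damping $\mu_0 = 0.01$, since damped Gauss–Newton has no
classical learning rate. Stopping: MSE ≤ 1e-6, 1000 iterations, or damping
overflow. Weights initialize uniformly in [−0.5, 0.5] from a seed; one
training run per fold, no restarts.

Features are min–max scaled to ±1 before training. Under leave-one-out
(jack-knife) evaluation the scaler is fitted *inside each fold* on the
n−1 training rows only — fitting it globally leaks the held-out sample's
range into training; the global variant remains available via
`scale_per_fold = FALSE` for comparison. Evaluation trains one network per
sample (86 networks for an 86-subject cohort); each sample's verdict comes
from the network that never saw it, thresholded at 0.5 (a score of exactly
0.5 maps to class 0). Accuracy, sensitivity and specificity follow from the
pooled confusion counts. For a future unseen subject, prediction uses a
single network trained on all samples — how the fold networks would combine
for new data is otherwise undefined.

## The synthetic generator

`synthesize_pcg()` emulates what the pipeline needs to see, with ground
truth: per cycle an S1 burst (100 ms, centered at 80 Hz) at the cycle onset
and an S2 burst (80 ms, 120 Hz, amplitude 0.8) at the systolic fraction;
±2% seeded beat-to-beat jitter; optionally a murmur (Gaussian noise
band-passed to 100–600 Hz, gated onto CAV with 10 ms cosine ramps, RMS set
relative to S1); and white noise at a configurable SNR (default 20 dB).
The systolic fraction is 0.38 of the cycle at HR ≤ 130 and 0.55 above, so
the labeling hypothesis holds by construction in each regime; in the
low-rate regime systole is additionally floored at 0.2 s, because real
pediatric systole does not shrink proportionally with the cycle — a
proportional systole at ~125 bpm would fall under the 180 ms instant
spacing that real hearts (and hence the method's adjacency rule) respect. Bursts are
sums of five cosine components at 0.4–1.3× the center frequency under a
Hann window: real heart sounds are spectrally dense over ~20–150 Hz, and a
burst must excite D4 and D5 simultaneously for the Hadamard product to
represent it — a pure tone would sit in one band and vanish from the
product, which is physiologically wrong, not conservative. Cosine phase
about the burst center keeps each burst even-symmetric so its amplitude
peak is exactly the ground-truth instant.

What the generator does *not* model: valve mechanics, S3/S4, respiratory
modulation, crying and motion artifacts, device coloration, diastolic or
continuous murmurs. Passing tests on this generator therefore demonstrate
that the chain recovers what it is designed to recover under controlled
morphology and noise — not clinical-grade performance on real pediatric
recordings, which no public data set currently allows us to measure.

Default study conditions used by the tests and the acceptance script:
cohorts of 24 normal + 62 murmur subjects, 20 s recordings, heart rates
drawn from 70–125 bpm (clear of the 130 bpm regime boundary, where the
labeling rule's branch and the generator's geometry would disagree within
the ±2 bpm estimation error), murmur levels 0.5–1.2, 20 dB SNR.
Segmentation is additionally exercised at 75, 100 and 143 bpm to cover
both branches of the labeling rule.

## Numerical choices and degenerate inputs

- $0 \log 0 := 0$ in the Shannon energy (an explicit branch, not an
  epsilon inside the log).
- Envelope timestamps are frame centers; instants are parabola-refined
  peak times on that grid.
- Wavelet minimum length: 5 levels require ≥ 192 samples; shorter inputs
  error with the required minimum named.
- Fewer than 3 surviving instants, all-equal labeling gaps, all-zero
  recordings, zero-length audio, upsampling requests, negative thresholds
  and non-finite features are all hard errors, not warnings.
- All times are seconds internally; report surfaces round to 4 decimals.
- Every stochastic component (weights, jitter, murmur, noise, cohort
  draws) is seeded; equal seeds give bit-identical results.

## Known limitations

Strong non-stationary artifacts (crying, stethoscope friction) are beyond
the universal-threshold denoiser, murmur severity is not graded, S3/S4 are
not modeled, and the classifier's excellent synthetic-cohort accuracy
reflects the generator's clean class separation rather than expected
clinical accuracy. The 86-network jack-knife quantifies generalization of
the *training procedure*, not of one fixed network.
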