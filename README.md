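# pcgmurmur

Heart-sound analysis for pediatric congenital heart disease (CHD)
screening. The package takes a phonocardiogram (PCG) — a WAV recording
from an electronic stethoscope — and runs a complete chain:

1. **Denoising** — 5-level Daubechies-6 wavelet decomposition with
   soft thresholding, `W_new = sgn(W)(|W| − T)` for `|W| ≥ T`, using the
   universal threshold `T = σ̂√(2 ln n)`.
2. **Segmentation** — the S1/S2 heart sounds are located from the
   Hadamard product `S = D4 ∘ D5` of the 62.5–125 Hz and 31.25–62.5 Hz
   detail bands (energy survives only where both bands are active, which
   suppresses murmurs that overlap the heart sounds), enveloped by framed
   average Shannon energy `E_s = −(1/N) Σ s² log s²` and z-scored. Heart
   rate comes from the mean two-step instant span,
   `HR = 60 / mean(p[i+2] − p[i])`, and S1/S2 are told apart by the
   pediatric rule that systole is the shorter intra-triple gap at
   HR ≤ 130 bpm and the longer one above. The closed-valve intervals —
   CAV (S1 end → S2 start, systole) and CSV (S2 end → next S1 start,
   diastole) — follow from the 10% Shannon-energy boundaries around each
   sound.
3. **Features** — 10 per recording, averaged over cycles: max, min and
   mean |amplitude| of the denoised signal over CAV and CSV, plus max and
   mean Welch power spectral density (Hann window, 50% overlap) of each.
4. **Classification** — a 10-10-1 perceptron (tanh hidden layer, linear
   output) trained by Levenberg–Marquardt on MSE, evaluated by
   leave-one-out jack-knife: one network per held-out subject, verdicts
   thresholded at 0.5, summarized as
   `Acc = (TP+TN)/(TP+FP+TN+FN)`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`.

A seeded synthetic PCG generator (`synthesize_pcg()`,
`synthesize_cohort()`) produces recordings with ground-truth instants,
boundaries, intervals and labels, so the whole chain is testable without
clinical data.

## Worked example

```r
library(pcgmurmur)

sim <- synthesize_pcg(heart_rate = 95, duration = 20,
                      murmur_level = 0.9, seed = 42)
den <- denoise_pcg(normalize_amplitude(sim$signal))
seg <- segment_pcg(den)
seg
#> PCG segmentation
#>   62 instants (31 S1, 31 S2), 30 complete cycles
#>   heart rate: 94.6 bpm

round(pcg_features(den, seg), 4)
#>      cav_max      cav_min  cav_meanabs      csv_max      csv_min  csv_meanabs
#>       0.5072      -0.4884       0.0918       0.0568      -0.0315       0.0038
#>  cav_psd_max cav_psd_mean  csv_psd_max csv_psd_mean
#>       0.0001       0.0000       0.0000       0.0000
```

The simulated recording carries a systolic murmur at 0.9× the S1
amplitude; the nominal 95 bpm rate is recovered as 94.6 bpm, and all 30
complete cycles contribute to the features. The murmur shows exactly where
it should: the systolic (CAV) amplitude and spectral features dwarf the
diastolic (CSV) ones — `cav_meanabs` is ~24× `csv_meanabs` — which is the
separation the classifier feeds on.

Evaluating the metric definitions on a reference confusion outcome (24
normal subjects with 2 false predictions, 62 CHD subjects with 4):

```r
classification_metrics(tp = 58, fp = 2, tn = 22, fn = 4)
#>    accuracy sensitivity specificity
#>    93.02326    93.54839    91.66667
```

A command-line front end over the same functions lives at
`inst/cli/pcgmurmur.R` (subcommands `simulate`, `segment`, `features`,
`evaluate`).

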