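---
title: "Decoding hand and wrist movements from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand and wrist movements from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgmotion)
```

## The problem

Surface electromyography (sEMG) measures the electrical activity of muscle
groups non-invasively at the skin, and is the standard control signal for
myoelectric prosthetic hands. A pattern-recognition controller must map short
windows of the multichannel signal to one of many intended movements —
here up to 41 hand and wrist movements plus rest — quickly enough for the
prosthesis to feel responsive, and reliably enough that it does not execute
unintended movements mid-use.

`emgmotion` implements that pipeline end to end in the layout used by the
Ninapro database family (DB5: 2 Myo armbands, 16 channels at 200 Hz; DB7:
12 Delsys Trigno electrodes at 2 kHz): per-sample movement labels
(`stimulus`, 0 = rest) and repetition indices (1–6, 0 during rest)
synchronized with the signal matrix. The acquisition protocol records each
movement as six repetitions of 5 s activity followed by 3 s of rest, which
makes roughly half the samples rest and forces imbalance-aware evaluation.

## Pipeline

1. **Segmentation.** A sliding window of `window_ms` with stride
   `stride_ms` (defaults mirror the experimental grid: windows of 100, 200,
   400, 800, 1000 ms; stride 100 ms, or 50 ms for the 100 ms window). A
   window gets the modal label of its samples; ties break in favour of rest,
   then the smallest class index — conservative towards "no movement". The
   count of windows obeys `floor((N - W)/S) + 1` exactly.
2. **Repetition split.** Movement windows route by repetition (train on
   repetitions 1, 3, 4, 6; evaluate on 2 and 5). Rest windows follow the
   nearest preceding movement repetition so both splits keep their share of
   rest; leading rest defaults to train. No sample from an evaluation
   repetition can influence fitting (the leakage test scales test-interior
   samples by 10× and asserts the training features are bitwise unchanged).
3. **Features.** Per channel and window, six time-domain statistics: RMS,
   mean absolute value (MAV), MAV slope, zero crossings (ZC), slope sign
   changes (SSC), waveform length (WL). ZC counts strict sign changes whose
   amplitude step is at least a noise threshold `T`; SSC counts strict local
   extrema with at least one neighbouring step `≥ T`. Both are therefore
   non-increasing in `T` and invariant under joint positive scaling of
   signal and threshold.
4. **Standardization.** Each feature column is z-scored with mean and
   population standard deviation estimated on the training split only;
   zero-variance columns are centred and flagged.
5. **Classifier.** A feed-forward network, input → 512 → 256 → 256 →
   `n_classes`, each hidden layer followed by batch normalization, ReLU and
   20 % dropout; linear + softmax output. He-uniform initialization; Adam
   with learning rate 0.005 and decay 1e-5; mean categorical cross-entropy.
6. **Evaluation.** Overall accuracy, and macro-averaged recall (reported as
   the balanced accuracy), precision and F1 from the confusion matrix.
   Per-class recalls are banded at ≥ 0.8 / 0.6–0.8 / < 0.6, the practical
   usability grouping.
7. **Usage simulation.** The trained model slides across an uncut signal —
   rest, movements, transitions — and the continuity of its predictions is
   summarized per movement span.

## Tunable parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `window_ms` | 200 | ms | middle of the 100–1000 ms grid; larger windows trade response time for accuracy |
| `stride_ms` | 100 (50 at 100 ms windows) | ms | overlapping windows add training samples and decision rate |
| `T` (noise threshold) | 0.01 for DB5-style data; 1e-8 / 1e-6 for DB7-style intact / amputee | amplitude units as stored | the DB5 value is the conventional one for Myo-scale data; the DB7 values are the grid-search optima for those groups; always overridable, and `threshold_search()` re-derives it |
| hidden widths | 512, 256, 256 | units | the reference architecture |
| dropout | 0.2 | — | regularization of the reference architecture |
| learning rate / decay | 0.005 / 1e-5 | — | Adam schedule `lr/(1 + decay·t)`; a weight-decay reading of the same number is available via `decay_type = "weight"` |
| epochs / batch size | 100 / 256 | — | not specified by the reference description; fixed here for reproducibility rather than tuned — no early stopping, no validation split |
| continuity margin | 2 | windows | one window of boundary context plus one for the majority-label lag when classifying errors as transitional vs mid-movement |

## The synthetic generator

Real Ninapro recordings require a download agreement, so every part of the
package is exercised on a bundled generator that reproduces the protocol's
*label structure* exactly (movement/rest block lengths, repetition indices,
one block per class × repetition) and the *statistical structure* the
classifier exploits: amplitude-modulated zero-mean Gaussian noise, with per
class and channel standard deviation
`baseline_noise_sd · (1 + activation[class, channel] · (1 + jitter))` during
movement and `baseline_noise_sd` at rest. Per-repetition and per-subject
multiplicative jitter (`envelope_jitter_sd`, default 0.1 — about the scale
of the between-repetition amplitude variation visible in real recordings)
provides the variability that makes the held-out repetitions a genuine
test. The default activation matrix gives every class a distinct two-channel
signature plus a class-specific gain.

What the generator deliberately does **not** model: the sEMG power
spectrum (so spectral features would see no class information), motor-unit
firing statistics, electrode shift, cross-talk between channels, and
fatigue drift. Passing tests on synthetic data therefore demonstrate that
the pipeline is implemented correctly and recovers known amplitude
signatures under the stated protocol — not that it attains any particular
accuracy on real sEMG. With real Ninapro MAT files the same pipeline runs
unchanged through `read_ninapro_mat()`.

Rest occupies exactly 3/8 of the samples under the 5 s/3 s block structure;
`inter_class_rest_s` inserts extra rest between class blocks, approaching
the roughly one-half rest share of the full acquisition including
inter-exercise pauses.

## Numerical choices and degenerate inputs

* **ZC/SSC summation range.** The crossing indicator references the next
  (and for SSC the previous) sample, so the sums run over the indices where
  all referenced samples exist: pairs 1..n−1 for ZC, interior points
  2..n−1 for SSC. Exact zeros never cross (strict inequalities).
* **MAV slope.** Defined as the difference of MAVs over adjacent equal
  sub-segments; the sub-segment count is a parameter with default 2 (one
  difference per window), keeping the feature dimension at six per channel
  for every window size.
* **Standard deviation estimator.** Population (divide by n), declared so
  that worked examples are reproducible to the last digit.
* **Macro averages on empty denominators.** Classes absent from the truth
  of a split have undefined recall and are excluded from the macro
  averages (and listed in the report); classes present but never predicted
  contribute precision 0. Macro F1 is the harmonic mean of the two macro
  values, not the mean of per-class F1.
* **Prediction ties.** Exact probability ties resolve to the lowest class
  index, deterministically.
* **Batch normalization.** After the linear map, before ReLU (the common
  reading of "each layer followed by" normalization and activation);
  epsilon 1e-3, running-statistics momentum 0.99; inference uses running
  statistics and no dropout.
* **Softmax and loss.** Max-subtracted softmax; probabilities clipped at
  1e-12 before the logarithm.
* **Windows longer than the recording** yield an empty window set with a
  warning rather than an error, so sweeps over window sizes degrade
  gracefully on short inputs.
* **Threshold grid search.** Nine candidates, 1e-4 to 1e-12 by factors of
  10. To avoid fitting the threshold on evaluation data, the default search
  trains on repetitions {1, 3, 4} and scores balanced accuracy on
  repetition {6}; scoring directly on the evaluation repetitions remains
  available by passing those as `score_reps`. Ties resolve to the larger
  (more conservative) threshold.

## Design decisions that were genuinely open

* **Label dialect.** Ninapro files carry both raw (`stimulus`) and refined
  (`restimulus`) annotations. The reader prefers the refined labels — the
  recommended movement-aligned annotation — records which was used, and
  accepts a `field_map` override.
* **Channel subsetting.** DB5's two armbands arrive as one 16-column
  matrix; a channel subset is expressed as a column-index list, with "first
  8" as the 8-channel default since nothing distinguishes the armbands in
  the file itself.
* **Sampling rate.** Not stored in all Ninapro files; it is a required
  argument (200 for DB5-style, 2000 for DB7-style) unless present in the
  file.
* **Transition windows.** Windows straddling movement/rest boundaries are
  kept (they are what the usage simulation must handle); a strict mode
  drops non-unanimous windows for ablation.
* **Per-subject modelling.** One model per subject is the default, matching
  per-participant training and mean ± SD reporting across subjects; pooling
  recordings before training remains possible by concatenating feature
  tables.
* **Model persistence.** The classifier is saved as a single RDS archive
  (weights, spec, standardizer, class list) plus a human-readable JSON
  manifest.

## Problem sizes used in the tests

The suite runs on synthetic data sized so the full check completes in a few
minutes of one CPU: the movement-recovery check uses the full protocol
(8 channels at 200 Hz, 10 movements + rest, six 5 s/3 s repetitions,
~4 800 windows per recording at 200 ms/100 ms) with 25 training epochs —
enough for the separable synthetic signatures to converge — and three
seeds; sweep-reproducibility and threshold-search checks use shorter 1 s/0.5 s
blocks with three classes. The vignette's own examples below are smaller
still.

## A worked example

```{r example}
cfg <- synthetic_config(n_channels = 2, fs = 200, movement_classes = 1:3,
                        movement_s = 1, rest_s = 0.5,
                        activation = rbind(c(4, 0.5), c(0.5, 4), c(3, 3)),
                        seed = 99)
rec <- generate_recording(cfg)
rec

ws <- segment(rec, window_ms = 200, stride_ms = 100)
sp <- split_by_repetition(ws, train_reps = c(1, 3, 4, 6), test_reps = c(2, 5))
train <- extract_features(sp$train, T = 1e-3)
test <- extract_features(sp$test, T = 1e-3)

model <- emg_dnn(train, epochs = 60, batch_size = 64, seed = 4)
evaluate(model, test)
```

```{r usage}
trace <- simulate_usage(model, rec, 200, 100, threshold = 1e-3)
continuity_stats(trace, margin_windows = 2)
```

## Known limitations

* The generator's amplitude-only signal model means frequency-domain
  information is absent by construction; conclusions about feature choice
  on real sEMG cannot be drawn from it.
* Training is plain R matrix code: fast enough for feature-table inputs
  (seconds to a couple of minutes per model) but not for raw-signal deep
  learning.
* The v7.3 (HDF5) MAT dialect is read through the system `python` with
  `h5py`; classic v5 files need no external tools.
* Offline segmentation only; no ring-buffer/online implementation, no
  latency measurement, and no prosthesis control interface.
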