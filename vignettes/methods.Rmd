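---
title: "Screening single-lead ECG segments for anomalies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening single-lead ECG segments for anomalies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgscreen)
```

## The screening task

`ecgscreen` addresses triage, not diagnosis: given long single-lead ECG
recordings, decide per 15-second window whether anything in it warrants a
cardiologist's attention, and per recording whether the patient should be
alerted. The binary framing is deliberate. A personal monitoring device does
not need to distinguish a premature ventricular contraction from a
bundle-branch block; it needs to not miss either. All 21 anomaly classes in
the MIT-BIH annotation vocabulary — beat-level alterations, rhythm changes,
and signal-quality events — are therefore pooled into a single *anomalous*
class, and the asymmetric cost of errors (a missed anomaly is worse than a
false alert) shapes several choices below.

## Data conventions

Recordings are 360 Hz, 11-bit ADC over ±5 mV with code 1024 at 0 V, read
from the two-file tabular export: a sample table (one row per time point,
one integer column per lead) and an annotation table (`Time, Sample, Type`).
Both comma- and whitespace-delimited variants are accepted by the same
sniffing parser, since the layout, not the delimiter, is the contract.
Values are kept as raw ADC integers internally; conversion to millivolts is
explicit (`adc_to_millivolts()`, the affine map $(v - 1024) \cdot 10/2048$)
and opt-in, so the raw signal survives untouched through segmentation — the
pipeline performs no filtering, resampling or baseline correction of any
kind. The annotation `Time` string is carried verbatim and never parsed; the
sample index is the only source of position.

Only the MLII lead is analysed. Requesting it from a recording that lacks it
raises a typed `lead_unavailable` condition, which callers use to exclude
such recordings (in MIT-BIH, four recordings carry only V1/V5 and are
excluded this way). A reader for the binary WFDB format is out of scope:
the tabular export is the tested contract.

## Segmentation and labeling

Windows are half-open, 0-based, left-aligned and non-overlapping:
window $i$ covers samples $[i \cdot 5400, (i+1) \cdot 5400)$, and an event
at sample $s$ belongs to window $\lfloor s / 5400 \rfloor$. A trailing
partial window is dropped — the network input length is fixed, and
half-hour recordings divide evenly so the rule is only exercised on
truncated inputs. A window is labeled anomalous iff it contains at least
one anomalous event; the full multiset of symbols per window is retained as
metadata, so windows carrying several pathologies remain inspectable even
though the classifier is binary.

Two edge cases the labeling rule must decide:

* **Unknown symbols error out.** A symbol the map does not classify raises
  `unknown_symbol` rather than defaulting to normal; silently normalizing
  an unrecognized annotation is exactly the failure mode a screening
  system must not have.
* **Unannotated windows are labeled normal**, flagged `annotated = FALSE`,
  counted in a message, and can be dropped with a switch. Labeling by
  absence of evidence is weaker than labeling by normal evidence, so the
  flag is kept visible.

The anomalous symbol set defaults to the 21 standard MIT-BIH codes
`L R A a J S V F ! e j E / f x Q | ~ + [ ]` with `N` normal. Signal-quality
codes (`~`, `|`) count as anomalous on the same footing as beats: a
low-quality stretch is itself a reason for human review.

## Architecture

The network is four blocks of `Conv1D → BatchNorm → MaxPool(4) → ReLU`
followed by `AvgPool(2) → Flatten → Dropout(0.6) → Dense(2, L2=0.001)` and
a softmax. Three conventions are fixed by the published output shapes
rather than stated anywhere explicitly, and `shape_trace()` documents all
of them:

* **Valid (unpadded) convolution**: $5400 \to 666$ under kernel 80 stride 8
  forces $\lfloor (L - k)/s \rfloor + 1$.
* **Stride-1 convolutions after block 1**: $166 \to 163$ with kernel 4.
* **Non-overlapping pooling** (stride = pool size): $666 \to 166$ with
  pool 4.

One cell of the published table is internally inconsistent: the fourth
block prints kernel size 4 but an output length of 8 from an input of 9,
which valid convolution can only produce with kernel 2 — and with kernel 4
the trace would collapse to length 0 at the head's average pooling, i.e.
the printed network could not run at all. We follow the shape column, which
is what the framework actually printed, and default block 4 to kernel 2.

Further architecture decisions where the source is silent:

* **No convolution biases.** Batch normalization directly follows every
  convolution and its shift parameter absorbs any bias exactly.
* **Batch norm** uses learned scale/shift, $\epsilon = 10^{-5}$, and
  running-moment momentum 0.9 for inference.
* **Initialization** is Glorot-uniform with the model seed; dense bias
  zero.
* **Input units** default to millivolts (an affine, order-preserving map of
  the ADC codes); a config flag feeds raw ADC instead. The first batch
  norm absorbs global scale either way, so this choice is cosmetic for
  learning but keeps inputs in a physically meaningful range.
* **Tie-breaking**: a softmax tie (exactly 0.5/0.5) predicts *anomalous*,
  consistent with the recall-first design goal.

## Training protocol

Defaults: categorical cross-entropy plus the dense layer's L2 penalty,
Adam at learning rate $10^{-3}$, batch size 32, 200 epochs, no early
stopping, and a stratified 70/30 train/validation monitor carved from the
training pool. The optimizer, batch size and loss are not stated in the
source and are chosen as the least surprising defaults consistent with a
softmax head; all are overridable through `train_config()` and recorded in
run manifests. Everything stochastic — weight init, epoch shuffles,
dropout masks — runs off one seed, so a run is exactly repeatable;
learning curves log loss and accuracy on both sides every epoch.

Class imbalance is handled by undersampling only: the majority class of
the training pool is thinned to match the minority
(`undersample_balance()`), and everything left over joins the test pool.
One bookkeeping note: in the source material the conventional-split test
set is printed as 640 normal / 426 anomalous (60/40), which does not equal
the leftover count implied by its own totals (3175 − 1465 = 1710
anomalous). We do not guess which subsampling produced the printed figure;
the implementation keeps all leftovers and provides `subsample_test()` to
thin a test pool to any target composition, 60/40 by default.

Two split designs mirror the two evaluation protocols:

* **Segment-wise** (`split_segmentwise()`): windows assigned at random,
  stratified per class; windows of one patient can appear on both sides.
  This is the conventional hold-out design and is the optimistic one —
  signal patterns of a test patient may have been seen in training.
* **Patient-wise** (`split_patientwise()`): whole recordings on one side.
  Evaluation then measures generalization to unseen patients, the setting
  an actual deployment faces. `audit_split_leakage()` verifies
  record-disjointness and is also exposed as a CLI audit.

Stratified $k$-fold plans (`make_folds()`, default $k = 10$) partition any
pool into folds whose sizes differ by at most one, each id validated
exactly once; ties everywhere are broken by `(record_id, segment_index)`
order so identical inputs and seeds give byte-identical manifests.

## Metrics and the patient-level rule

`metrics()` computes per-class accuracy, precision, recall and F1 from the
2×2 matrix, treating each class in turn as positive, plus overall accuracy.
Zero-denominator cases (no true, or no predicted, members of a class)
report `NA`, never a silent 0. Full precision is kept internally; reported
copies are rounded half-up to 2 decimals to match conventional table
formatting.

Two cells of the published conventional-split results are inconsistent
with their own matrix and are handled as documented discrepancies rather
than targets: the overall accuracy (printed 89.51%, matrix 957/1066 =
89.77%) and the anomalous precision (printed 86.78%, matrix 374/431 =
86.77%). Every other published metric cell in both evaluations is
reproduced exactly by integer arithmetic, and the golden tests assert the
matrix-consistent values.

The patient-level rule is an existential relaxation: a recording is truly
anomalous iff it has one truly anomalous window, and is flagged iff one
window is predicted anomalous. Patient-level recall therefore can never
fall below segment-level anomalous recall — a property the test suite
checks on random predictions — and in practice is much higher, which is
the key argument for segment-level screening feeding a per-recording
alert.

## The synthetic generator

Clinical recordings cannot be redistributed with the package, so every
pipeline stage is exercised against a synthetic generator
(`simulate_recording()`, `make_benchmark()`, `simulate_dataset()`) that
emits exactly the two-file format the readers consume. A beat is a sum of
five Gaussian bumps (P, Q, R, S, T) with amplitudes giving ≈1.25 mV
peak-to-peak, placed on an RR process with mean 0.8 s (75 bpm) and 0.04 s
jitter, plus white baseline noise (0.02 mV sd) — numbers a clinician would
recognize as an unremarkable resting rhythm. Three anomaly types fire as
independent per-beat Bernoulli draws: `V` (premature — the preceding RR is
shortened to 0.6 of its value and returned as a compensatory pause — wide,
inverted, large, no P wave), `A` (premature timing, normal shape), and `|`
(an artifact burst replacing the beat). Beat timing, anomaly draws and
noise run on three separate seeded streams, so event placement is
reproducible independently of the noise realization.

What the generator does *not* emulate matters for interpreting results:
morphological variability between patients and electrodes, baseline
wander, the subtler anomaly classes (conduction blocks, fusion beats), and
class-conditional overlap. Synthetic PVCs are grossly separable from
synthetic normal beats by design. Passing the learnability benchmark
therefore shows the implementation — shapes, gradients, optimization, data
plumbing — is correct; it says nothing about clinical accuracy, which is
why the published MIT-BIH headline numbers are reproducible only through
the documented harness on the real data and are not asserted by tests.

## Problem sizes used by tests and the acceptance run

Unit tests run miniature configurations (windows of a few hundred samples,
two-block networks) chosen to exercise every code path in seconds. The
end-to-end benchmark uses 20 recordings of 300 s — 10 clean, 10 with PVCs
at 0.3 per beat — giving 400 windows of 5400 samples, the full published
architecture, and 20 epochs: large enough that an implementation error
(wrong gradient, leaking split, mislabeled window) would be visible, small
enough to run routinely on one CPU. The acceptance script holds out 6 of
the 20 recordings patient-wise, balances the remaining pool by
undersampling, trains once, and reports segment- and patient-level results
on the unseen recordings.

## Known limitations

* The CNN runs on CPU in double precision; training at the full MIT-BIH
  scale (thousands of windows, 200 epochs) is feasible but takes hours,
  not minutes.
* Only the tabular export format is read; binary WFDB files must be
  converted externally.
* The generator's anomalies are caricatures tuned for separability, not
  physiological fidelity; no multi-lead synthesis, no colored noise.
* Checkpoints (`saveRDS`) are R-native and not portable across
  architectures by contract.
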