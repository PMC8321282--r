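# ecgscreen

Binary anomaly screening of single-lead ECG segments with a four-block 1D
convolutional neural network, implemented from scratch in R.

## The problem

Ambulatory and personal ECG devices produce far more signal than
cardiologists can read. A practical triage system does not need to name the
arrhythmia — it needs to decide, for every short stretch of signal, *normal*
or *suspicious*, and to alert the patient when any stretch of a recording is
suspicious, so that only flagged recordings reach a specialist. Missing a
true anomaly costs far more than a false alert, so the design goal is high
recall for the anomalous class, even at some cost in accuracy.

`ecgscreen` implements such a screening pipeline end to end for
MIT-BIH-style data: half-hour two-lead recordings sampled at 360 Hz with
11-bit ADC values over ±5 mV (code 1024 = 0 V), accompanied by expert beat
and rhythm annotations. The analysis uses the Modified Lead II (MLII)
channel only, cut into fixed 15-second windows of 5400 samples. A window is
labeled **anomalous** as soon as one annotated event in it belongs to any of
21 anomaly classes — beat alterations (PVC, APB, bundle-branch blocks,
escape and paced beats, ...), rhythm changes, and signal-quality events
alike — and **normal** only if every annotated peak is normal.

## The model

The classifier is a 1D CNN of four convolutional blocks, each
`Conv1D → BatchNorm → MaxPool(4) → ReLU`, followed by
`AvgPool(2) → Flatten → Dropout(0.6) → Dense(2, L2 = 0.001)` with a softmax
over (normal, anomalous). Convolutions are valid (no padding); the first
uses kernel 80 with stride 8 and 128 filters, so an input of length
L = 5400 maps to ⌊(L − 80)/8⌋ + 1 = 666 positions. The full shape trace:

```
<model_config> input (5400;1), 4 conv blocks, 2 classes
  conv1d_1       (666;128)
  batch_norm_1   (666;128)
  max_pool_1     (166;128)
  relu_1         (166;128)
  conv1d_2       (163;256)
  batch_norm_2   (163;256)
  max_pool_2     (40;256)
  relu_2         (40;256)
  conv1d_3       (37;256)
  batch_norm_3   (37;256)
  max_pool_3     (9;256)
  relu_3         (9;256)
  conv1d_4       (8;512)
  batch_norm_4   (8;512)
  max_pool_4     (2;512)
  relu_4         (2;512)
  avg_pool       (1;512)
  flatten        (512)
  dropout        (512)
  dense          (2)
```

The network, its backward pass, and the Adam optimizer are written in R with
the hot kernels (im2col, batch-norm, max-pool) in C++; all matrix products
go through BLAS. Training is fully seeded: identical seeds give identical
weights, shuffles, dropout masks and learning curves.

Evaluation uses the standard per-class metrics from the 2×2 confusion
matrix (TP/TN/FP/FN per evaluated class):

- Accuracy = (TP + TN) / (TP + TN + FP + FN)
- Precision = TP / (TP + FP)
- Recall = TP / (TP + FN)
- F1 = 2·TP / (2·TP + FP + FN)

Two split designs are provided: the conventional segment-wise random split,
and a patient-wise split in which all windows of a recording stay on one
side, so the model is evaluated only on patients it has never seen. A
patient-level alerting rule aggregates window predictions: a recording is
flagged as soon as one of its windows is predicted anomalous.

## Worked example

```r
library(ecgscreen)

# simulate a 2-minute annotated recording with ventricular ectopy
cfg <- synthetic_config(duration_s = 120,
                        anomalies = default_anomalies(v_rate = 0.1),
                        seed = 7)
sim <- simulate_recording(cfg, record_id = "demo")
sim$recording
#> <ecg_recording 'demo'> 43200 samples x 1 lead(s) [MLII] @ 360 Hz (adc)
sim$annotations
#> <ecg_annotations 'demo'> 149 events [symbols: N V]

# fixed 15-s windows, labeled from the annotations they contain
ds <- build_segment_dataset(sim$recording, sim$annotations)
ds
#> <segment_dataset> 8 segments of 5400 samples (2 normal, 6 anomalous) from 1 recording(s)

# metrics from any confusion matrix, e.g. a patient-wise evaluation with
# rows true-normal (241, 194) and true-anomalous (77, 1288)
metrics(confusion_from_counts(241, 194, 77, 1288))
#> Confusion matrix (rows = truth, cols = predicted):
#>            predicted
#> truth       normal anomalous
#>   normal       241       194
#>   anomalous     77      1288
#> Overall accuracy: 84.94%
#>   normal    recall  55.40%  precision  75.79%  F1  64.01%
#>   anomalous recall  94.36%  precision  86.91%  F1  90.48%
```

The 84.94% overall accuracy with 94.36% anomalous recall is the
screening-oriented trade-off in action: nineteen of twenty truly anomalous
windows are caught, at the price of a higher false-alert rate on normal
windows.

Training and evaluating the full network on a synthetic benchmark:

```r
pool <- simulate_dataset(n_records = 20, n_clean = 10, duration_s = 300,
                         pvc_rate = 0.3, seed = 100)   # 400 segments
fit  <- train_on_pool(pool, model_config(), train_config(epochs = 20, seed = 11))
tail(fit$history, 1)
#>    epoch  train_loss   val_loss train_acc  val_acc
#> 20    20 0.004045691 0.06116639       100 99.16667
```

A command-line front end wraps the same functions; see
`inst/cli/ecgscreen help` for the `simulate`, `segment`, `build-dataset`,
`audit-split`, `train`, `evaluate` and `metrics-from-confusion`
subcommands.

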