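# ecgrhythm

Classification of 10-second single-lead ECG strips into five rhythm
categories — normal sinus rhythm (NSR), sinus tachycardia (ST), sinus
bradycardia (SB), supraventricular tachycardia (SVT, pooled with atrial
tachycardia), and ventricular tachycardia (VT) — for rapid arrhythmia
triage in home-monitoring settings, where single-lead patches and watches
are the dominant hardware. NSR, ST, and SB share P-QRS-T morphology and
differ in rate; SVT matches ST in rate but lacks visible P waves; VT shows
a wide, distorted QRS. The classifier therefore has to read rate and
morphology simultaneously, with no R-peak detection or manual interval
features.

## Method

Each strip is resampled to 250 Hz (2500 samples), z-score normalized over
the full 10 s, and decomposed into 1 s sliding windows with a 5-point
stride — 451 windows per strip. Every window is scored by a lightweight
transformer encoder whose positional information is a learnable Time2Vec
embedding

```
t2v(τ)_i = ω_i τ + φ_i            (i = 0, linear trend)
t2v(τ)_i = sin(ω_i τ + φ_i)       (1 ≤ i ≤ k, periodic)
```

summed element-wise with a learned projection of the signal samples. The
encoder stacks identical layers of multi-head scaled dot-product attention
`softmax(QKᵀ/√d_k)V` and a position-wise feed-forward net
`max(0, xW₁+b₁)W₂+b₂`, each wrapped in residual connections and layer
normalization. A mean-pooled two-layer softmax head yields window-level
class probabilities, and the recording label is the majority vote

```
ŷ = argmax_c Σ_j 1[C_j(x) = c]
```

over its windows — robust by construction to a minority of noise-corrupted
windows. Evaluation reports the 5×5 confusion matrix and per-class
one-vs-rest Accuracy, Sensitivity, Specificity, Precision, F1, and ROC AUC.

The forward pass, backpropagation, and Adam (with linear warmup) are
implemented in the package itself (R plus fused RcppArmadillo kernels for
the encoder); a seed-controlled synthetic five-rhythm generator with
patient-wise train/validation/test partitioning makes the whole pipeline
trainable and testable with no external downloads. WFDB (formats 16/212)
and CSV readers/writers handle real single-lead records.

## Worked example

```r
library(ecgrhythm)

ds  <- generate_dataset(synth_config(per_class_count = 40, seed = 1,
                                     noise = noise_off()))
fit <- fit_rhythm_model(dataset_partition(ds, "train"),
                        reduced_model_config(),
                        reduced_train_control(seed = 1),
                        val_records = dataset_partition(ds, "validation"))
ev  <- evaluate_model(fit, dataset_partition(ds, "test"))
print(ev)
#> Per-class metrics (%):
#>  class   acc  se    sp   pre    f1   auc
#>    NSR  95.0  75 100.0 100.0  85.7 0.996
#>     ST  97.5 100  96.9  88.9  94.1 0.996
#>     SB  97.5 100  96.9  88.9  94.1 1.000
#>    SVT 100.0 100 100.0 100.0 100.0 1.000
#>     VT 100.0 100 100.0 100.0 100.0 1.000
#> Overall accuracy: 95.0%
```

Forty clean synthetic recordings per class are split patient-wise
60/20/20; the reduced model (d_model 64, 2 encoder layers, 4 heads,
52,939 trainable parameters) trains in a few minutes of single-threaded
CPU and classifies the 40 held-out recordings. Rows are one-vs-rest
percentages per class: 38 of 40 strips are voted correctly; the two missed
recordings are NSR strips near the rate-band edges, voted ST and SB — the
expected confusion direction, since the sinus classes adjoin on a
heart-rate continuum. `predict_recording(fit, rec)` returns the vote
breakdown for one strip; `count_parameters(fit$model)` gives the exact
trainable parameter count recorded in the model card.

A thin command-line surface over the same functions lives in
`inst/cli/ecgrhythm-cli.R` (subcommands `generate`, `train`, `predict`,
`evaluate`).

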