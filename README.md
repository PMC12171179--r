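# cadfuse

Non-invasive prediction of coronary artery stenosis severity (≥ 75% vs
< 75%, the usual threshold for percutaneous intervention) from four
bedside data streams: tongue photographs, facial photographs, radial pulse
pressure waveforms, and a 50-value clinical laboratory panel.

`cadfuse` implements the full modelling stack for clinicians and
methodologists working on multimodal cardiovascular risk models:

* **Adaptive-weight late fusion network.** Each modality is encoded by a
  dedicated branch — a residual convolutional network with single-head
  self-attention for each image (3×3 conv → BN → ReLU → 2×2 max-pool →
  4 residual blocks → global average pool → dense → self-attention,
  embedding dimension 128), a 64-unit LSTM over the 6-s pulse segment, and
  a dense encoder over 15 screened clinical features. The decision layer
  fuses the four 128-dim embeddings with learnable weights
  `w = softmax(r)`, fused = `[w_t e_t, w_f e_f, w_p e_p, w_c e_c]` (length
  512), regularised by `R = Σ r_m²`, followed by a 2-logit head. Five
  alternative fusion rules (concat, max, mean, sum, attention) are
  available for comparison.
* **Radial pulse fiducial analysis.** Smoothing, baseline-drift removal, a
  stability-scored 6-s segment from each 30-s recording at 50 Hz, beat
  segmentation, and the 15 classical pulse-graph parameters
  (h1, h3, h4, h5, t, t1, t4, t5, h3/h1, h1/t1, h4/h1, t1/t, t4/t5,
  w1/t, w2/t).
* **Clinical screening and classical baselines.** Mann–Whitney/chi-square
  group screening, random-forest top-15 feature selection, and LR / RF /
  SVM / KNN / XGBoost baselines on hand-crafted features.
* **Interpretation.** Grad-CAM for the image branches; input-gradient
  saliency with top-20% marking for the pulse branch.
* **Ablation harnesses** over architecture modules, data modalities,
  fusion strategies and learning rates, plus a deterministic end-to-end
  pipeline runner.
* **Synthetic cohort generator** with planted, known class signal in every
  modality, so the whole stack is testable without clinical data (none are
  public for this task).

The network engine (convolutions, batch norm, residual blocks, attention,
LSTM, exact reverse-mode gradients, Adam) is implemented in the package on
BLAS matrix operations with C++ kernels for the convolution patch assembly
and the LSTM recurrence; every gradient is verified against finite
differences in the test suite.

## Worked example

Generate a 200-patient synthetic cohort, train the fusion model at a small
experiment profile, and inspect it:

```r
library(cadfuse)

spec <- cohort_spec(n_patients = 200, seed = 42, image_size = c(16, 16))
cohort <- generate_cohort(spec, "cohort_demo")

cfg <- fusion_config(image_size = c(16, 16), conv_channels = 8,
                     lstm_hidden = 24, attention_tokens = 8)
fit <- cadfuse_fit(cohort$manifest, cfg,
                   train_spec(epochs = 20, batch_size = 8, seed = 1))
fit
#> Multimodal fusion classifier (tongue + face + pulse + clinical)
#>   fusion: adaptive | embedding: 128 | fused length: 512 
#>   trained 16 epochs on 140 patients (best epoch 11 )
#>   fusion weights: tongue=0.261, face=0.260, pulse=0.236, clinical=0.242 

evaluate_model(fit, cohort$manifest, "internal")
#>    model    split  n       auc       acc        f1    recall
#> 1 fusion internal 30 0.9333333 0.6333333 0.4210526 0.2666667
evaluate_model(fit, cohort$manifest, "external")
#>    model    split  n       auc       acc  f1    recall
#> 1 fusion external 30 0.8622222 0.6666667 0.5 0.3333333
```

The printed fusion weights are the softmax-normalised learnable modality
weights (`coef(fit)` returns them; they sum to 1 and start uniform at
0.25; training stopped early at its best internal-AUC epoch). The
evaluation rows report rank-based AUC, accuracy at threshold 0.5, and
F1/recall of the severe-stenosis class. At this short training length the
ranking (AUC) is already strong while the 0.5-threshold metrics lag —
probabilities are still shrunk toward 0.5, a calibration effect discussed
in the methods vignette.

Pulse feature extraction and interpretation:

```r
feats <- pulse_features_table(cohort$manifest)   # 15 parameters per patient
cam <- gradcam_image(fit, cohort$manifest, "P0001", "tongue")
sal <- pulse_saliency(fit, cohort$manifest, "P0001")
length(sal$marked_indices)
#> [1] 60        # top 20% of the 300-sample segment
```

A command-line wrapper for every stage (`simulate`, `pulse-features`,
`screen`, `select-features`, `baselines`, `train`, `evaluate`, `explain`,
`run`) is installed at `system.file("cli", "cadfuse", package = "cadfuse")`.

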