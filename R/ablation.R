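## Ablation harnesses: architecture modules, data modalities, fusion
## strategies and learning rates. Every variant shares the same seed and
## training specification so rows are directly comparable.

## evaluation rows computed from an already-prepared dataset
eval_from_dataset <- function(fit, ds, name) {
  out <- list()
  for (sp in c("internal", "external")) {
    idx <- which(ds$split == sp)
    if (length(idx) < 2 || length(unique(ds$y[idx])) < 2) next
    p <- predict_probs(fit$model, slice_batch(ds$inputs, idx))
    out[[sp]] <- eval_report_row(name, sp, p, ds$y[idx])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

MODULE_VARIANTS <- list(
  "lstm+resnet+attention" = c(lstm = TRUE, resnet = TRUE, attention = TRUE),
  "resnet+attention" = c(lstm = FALSE, resnet = TRUE, attention = TRUE),
  "lstm+attention" = c(lstm = TRUE, resnet = FALSE, attention = TRUE),
  "lstm+resnet" = c(lstm = TRUE, resnet = TRUE, attention = FALSE),
  "attention" = c(lstm = FALSE, resnet = FALSE, attention = TRUE),
  "resnet" = c(lstm = FALSE, resnet = TRUE, attention = FALSE),
  "lstm" = c(lstm = TRUE, resnet = FALSE, attention = FALSE))

#' Architecture-module ablation
#'
#' Trains the seven module variants (all combinations of LSTM, residual
#' blocks and self-attention that keep at least one of the three): without
#' the LSTM, the pulse modality enters through a dense encoder on its 15
#' extracted fiducial parameters; without residual blocks, the image
#' branches are plain convolution stacks; without attention, the
#' self-attention layers are removed. All variants keep all four
#' modalities, the same seed and the same training specification.
#'
#' @param manifest a `cohort_manifest`.
#' @param config base [fusion_config()].
#' @param train a [train_spec()].
#' @return data.frame: 7 variants x available evaluation splits, with
#'   `auc`, `acc`, `f1`, `recall` columns.
#' @export
module_ablation <- function(manifest, config = fusion_config(),
                            train = train_spec()) {
  ## two dataset variants: raw-segment pulse (LSTM) vs extracted parameters
  cfg_nolstm <- config; cfg_nolstm$use_lstm <- FALSE
  ds <- list("TRUE" = prepare_dataset(manifest, config, seed = train$seed),
             "FALSE" = prepare_dataset(manifest, cfg_nolstm, seed = train$seed))
  rows <- list()
  for (vn in names(MODULE_VARIANTS)) {
    v <- MODULE_VARIANTS[[vn]]
    cfg <- config
    cfg$use_lstm <- unname(v["lstm"])
    cfg$use_resnet <- unname(v["resnet"])
    cfg$use_attention <- unname(v["attention"])
    d <- ds[[as.character(cfg$use_lstm)]]
    fit <- cadfuse_fit(manifest, cfg, train, dataset = d)
    rows[[vn]] <- eval_from_dataset(fit, d, vn)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

DATA_SUBSETS <- list(
  "lab+tongue" = c("tongue", "clinical"),
  "lab+face" = c("face", "clinical"),
  "lab+pulse" = c("pulse", "clinical"),
  "lab+tongue+face" = c("tongue", "face", "clinical"),
  "lab+tongue+pulse" = c("tongue", "pulse", "clinical"),
  "lab+face+pulse" = c("face", "pulse", "clinical"),
  "lab+tongue+face+pulse" = c("tongue", "face", "pulse", "clinical"))

#' Data-modality ablation
#'
#' Trains the seven modality subsets (clinical data always included);
#' absent modalities are removed from the fusion layer and the classifier
#' head is resized accordingly.
#'
#' @inheritParams module_ablation
#' @return data.frame: 7 subsets x available evaluation splits.
#' @export
data_ablation <- function(manifest, config = fusion_config(),
                          train = train_spec()) {
  ds <- prepare_dataset(manifest, config, seed = train$seed)  # superset
  rows <- list()
  for (vn in names(DATA_SUBSETS)) {
    cfg <- config
    cfg$modalities <- DATA_SUBSETS[[vn]]
    fit <- cadfuse_fit(manifest, cfg, train, dataset = ds)
    rows[[vn]] <- eval_from_dataset(fit, ds, vn)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fusion-strategy ablation
#'
#' Trains the same branches under the six decision-layer strategies:
#' concatenation, element-wise max / mean / sum, attention over the four
#' modality embeddings, and the learnable adaptive weighting.
#'
#' @inheritParams module_ablation
#' @return data.frame: 6 strategies x available evaluation splits.
#' @export
fusion_ablation <- function(manifest, config = fusion_config(),
                            train = train_spec()) {
  ds <- prepare_dataset(manifest, config, seed = train$seed)
  rows <- list()
  for (st in FUSION_STRATEGIES) {
    cfg <- config
    cfg$fusion <- st
    fit <- cadfuse_fit(manifest, cfg, train, dataset = ds)
    rows[[st]] <- eval_from_dataset(fit, ds, st)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Learning-rate sweep
#'
#' Trains the same model under each learning rate of the grid and returns
#' the per-epoch training curves (loss and internal AUC).
#'
#' @inheritParams module_ablation
#' @param rates learning-rate grid.
#' @return data.frame of training-log rows with a `learning_rate` column;
#'   one row per epoch per rate.
#' @export
lr_sweep <- function(manifest, config = fusion_config(), train = train_spec(),
                     rates = c(0.001, 0.005, 0.01, 0.05)) {
  ds <- prepare_dataset(manifest, config, seed = train$seed)
  rows <- list()
  for (r in rates) {
    tr <- train
    tr$learning_rate <- r
    tr$patience <- Inf  # full curves for every rate
    fit <- cadfuse_fit(manifest, config, tr, dataset = ds)
    lg <- fit$log
    lg$learning_rate <- r
    rows[[as.character(r)]] <- lg
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
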