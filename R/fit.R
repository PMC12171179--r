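## Model fitting: dataset assembly, the training loop and the fitted-model
## methods.

#' Training hyper-parameters
#'
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate (default 0.001, the best-
#'   performing rate in the sweep harness's default grid).
#' @param seed integer seed controlling initialisation, feature screening
#'   and batch shuffling.
#' @param patience early-stopping patience in epochs on the internal-split
#'   AUC (ignored when the manifest has no internal split); `Inf` disables
#'   early stopping.
#' @param class_weights use inverse-frequency class weights in the loss.
#' @return object of class `train_spec`.
#' @export
train_spec <- function(epochs = 30, batch_size = 16, learning_rate = 0.001,
                       seed = 1, patience = 5, class_weights = TRUE) {
  assert_that(learning_rate >= 0, "learning rate must be non-negative")
  assert_that(epochs >= 1 && batch_size >= 1, "invalid epochs/batch size")
  structure(as.list(environment()), class = "train_spec")
}

## z-score each row of a matrix (per-recording pulse normalisation)
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2))
  s[s < 1e-8] <- 1
  (x - mu) / s
}

## channel-first (3, H, W, N) tensor in [0, 1] for the conv branches
load_images_tensor <- function(manifest, paths, image_size) {
  H <- image_size[1]; W <- image_size[2]
  n <- length(paths)
  a <- array(0, c(3, H, W, n))
  for (i in seq_len(n)) {
    a[, , , i] <- aperm(read_image(file.path(manifest$root, paths[i]),
                                   size = image_size), c(3, 1, 2)) / 255
  }
  a
}

## Assemble the network inputs for every patient in a manifest.
## `preproc` (from a previous fit) freezes clinical feature selection and
## all scaling statistics; when NULL they are learned on the train split.
prepare_dataset <- function(manifest, cfg, seed = 1, preproc = NULL) {
  rec <- manifest$records
  n <- nrow(rec)
  assert_that(n > 0, "empty manifest")
  y <- as.integer(rec$label)
  split <- rec$split
  train_idx <- which(split == "train")
  inputs <- list()
  if ("tongue" %in% cfg$modalities) {
    inputs$tongue <- load_images_tensor(manifest, rec$tongue_path, cfg$image_size)
  }
  if ("face" %in% cfg$modalities) {
    inputs$face <- load_images_tensor(manifest, rec$face_path, cfg$image_size)
  }
  if ("pulse" %in% cfg$modalities) {
    if (cfg$use_lstm) {
      segs <- t(vapply(seq_len(n), function(i) {
        r <- read_pulse_csv(file.path(manifest$root, rec$pulse_path[i]))
        extract_stable_segment(preprocess_pulse(r))$pressure
      }, numeric(round(6 / (1 / 50)))))
      inputs$pulse <- zscore_rows(segs)
    } else {
      pf <- pulse_features_table(manifest)
      pm <- as.matrix(pf[, PULSE_FEATURE_NAMES])
      pm[is.na(pm)] <- 0
      if (is.null(preproc$pf_scaler)) {
        assert_that(length(train_idx) > 0, "no train split to fit scalers on")
        pf_scaler <- minmax_fit(pm[train_idx, , drop = FALSE])
      } else pf_scaler <- preproc$pf_scaler
      inputs$pulse <- unname(minmax_apply(pm, pf_scaler))
    }
  }
  selection <- preproc$selection
  clin_scaler <- preproc$clin_scaler
  if ("clinical" %in% cfg$modalities) {
    tab <- read_clinical_table(manifest)
    tab <- tab[rec$patient_id, manifest$features, drop = FALSE]
    if (is.null(selection)) {
      assert_that(length(train_idx) > 0, "no train split to screen features on")
      sel <- select_top_features(tab[train_idx, , drop = FALSE], y[train_idx],
                                 k = cfg$n_clinical_in,
                                 seed = derive_seed(seed, "screen"))
      selection <- sel$selected
    }
    cm <- as.matrix(tab[, selection, drop = FALSE])
    if (is.null(clin_scaler)) clin_scaler <- minmax_fit(cm[train_idx, , drop = FALSE])
    inputs$clinical <- unname(minmax_apply(cm, clin_scaler))
  }
  list(inputs = inputs, y = y, split = split, ids = rec$patient_id,
       preproc = list(selection = selection, clin_scaler = clin_scaler,
                      pf_scaler = if ("pulse" %in% cfg$modalities && !cfg$use_lstm)
                        pf_scaler else NULL))
}

slice_batch <- function(inputs, idx) {
  lapply(inputs, function(x) {
    if (length(dim(x)) == 4L) x[, , , idx, drop = FALSE]
    else x[idx, , drop = FALSE]
  })
}

predict_probs <- function(model, inputs, chunk = 64) {
  n <- if (length(dim(inputs[[1]])) == 4L) dim(inputs[[1]])[4] else nrow(inputs[[1]])
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    fw <- model_fwd(model, slice_batch(inputs, idx), train = FALSE)
    e <- exp(fw$logits - apply(fw$logits, 1, max))
    out[idx] <- (e / rowSums(e))[, 2]
  }
  out
}

#' Fit the multimodal fusion classifier
#'
#' Trains the configured network with Adam on the manifest's train split,
#' using weighted cross-entropy (plus `reg_lambda * R` under adaptive
#' fusion, where R is the sum of squared raw fusion weights). Clinical
#' feature screening, min-max scaling and pulse preprocessing are fitted on
#' the train split and frozen into the returned object. When an internal
#' split is present, the internal AUC is monitored per epoch and the
#' best-scoring parameters are restored (early stopping).
#'
#' @param manifest a `cohort_manifest` with a non-empty two-class train
#'   split.
#' @param config a [fusion_config()].
#' @param train a [train_spec()].
#' @param dataset optional pre-assembled dataset (internal use by the
#'   ablation harnesses to avoid reloading files).
#' @param verbose print per-epoch progress.
#' @return object of class `cadfuse`: the trained parameters, configuration,
#'   preprocessing state and a per-epoch training `log` (loss, internal
#'   AUC, normalised fusion weights and R).
#' @export
cadfuse_fit <- function(manifest, config = fusion_config(),
                        train = train_spec(), dataset = NULL,
                        verbose = FALSE) {
  if (is.null(dataset)) {
    tr0 <- manifest$records$split == "train"
    assert_that(any(tr0), "train split is empty")
    assert_that(length(unique(manifest$records$label[tr0])) == 2,
                "train split must contain both classes")
  }
  ds <- dataset %||% prepare_dataset(manifest, config, seed = train$seed)
  tr <- which(ds$split == "train")
  assert_that(length(tr) > 0, "train split is empty")
  assert_that(length(unique(ds$y[tr])) == 2,
              "train split must contain both classes")
  int <- which(ds$split == "internal")

  set.seed(derive_seed(train$seed, "init"))
  model <- init_model(config)
  opt <- adam_init(model$params)
  cw <- if (train$class_weights) {
    tab <- table(factor(ds$y[tr], levels = 0:1))
    as.numeric(length(tr) / (2 * pmax(tab, 1)))
  } else c(1, 1)

  n_tr <- length(tr)
  log_rows <- list()
  best <- list(auc = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(train$epochs)) {
    ord <- tr[sample.int(n_tr)]
    ep_loss <- 0; nb <- 0
    for (s in seq(1, n_tr, by = train$batch_size)) {
      idx <- ord[s:min(s + train$batch_size - 1, n_tr)]
      fw <- model_fwd(model, slice_batch(ds$inputs, idx), train = TRUE,
                      keep_cache = TRUE)
      l <- ce_loss(fw$logits, ds$y[idx], cw)
      loss <- l$loss + if (!is.null(fw$weights))
        config$reg_lambda * fw$weights$R else 0
      bw <- model_bwd(model, fw, l$dlogits)
      up <- adam_step(model$params, bw$grads, opt, train$learning_rate)
      model$params <- up$params; opt <- up$opt
      model$state <- apply_state_updates(model$state, fw$state_updates)
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    int_auc <- NA_real_
    if (length(int) > 1 && length(unique(ds$y[int])) == 2) {
      int_auc <- metric_auc(predict_probs(model, slice_batch(ds$inputs, int)),
                            ds$y[int])
    }
    wrow <- if (config$fusion == "adaptive") {
      wn <- softmax_vec(model$params[["fusion.raw"]])
      c(setNames(as.list(wn), paste0("w_", config$modalities)),
        R = sum(model$params[["fusion.raw"]]^2))
    } else NULL
    log_rows[[epoch]] <- as.data.frame(c(list(epoch = epoch, loss = ep_loss,
                                              internal_auc = int_auc), wrow))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f internal AUC %s", epoch, ep_loss,
                      ifelse(is.na(int_auc), "-", sprintf("%.3f", int_auc))))
    }
    if (!is.na(int_auc)) {
      if (int_auc >= best$auc - 1e-12) {
        ## ties keep the later (longer-trained, better-calibrated) snapshot
        improved <- int_auc > best$auc + 1e-9
        best <- list(auc = int_auc, params = model$params,
                     state = model$state, epoch = epoch)
        if (improved) stale <- 0L else stale <- stale + 1L
      } else {
        stale <- stale + 1L
      }
      if (is.finite(train$patience) && stale >= train$patience) break
    }
  }
  if (is.finite(best$auc)) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(list(model = model, config = config, train = train,
                 preproc = ds$preproc,
                 log = do.call(rbind, log_rows),
                 best_epoch = if (is.finite(best$auc)) best$epoch else
                   length(log_rows),
                 n_train = n_tr),
            class = "cadfuse")
}

#' @export
print.cadfuse <- function(x, ...) {
  cfg <- x$config
  cat("Multimodal fusion classifier (", paste(cfg$modalities, collapse = " + "),
      ")\n", sep = "")
  cat("  fusion:", cfg$fusion,
      "| embedding:", cfg$embed_dim,
      "| fused length:", fused_length(cfg), "\n")
  cat("  trained", nrow(x$log), "epochs on", x$n_train, "patients",
      "(best epoch", x$best_epoch, ")\n")
  if (cfg$fusion == "adaptive") {
    w <- coef(x)
    cat("  fusion weights:", paste(sprintf("%s=%.3f", names(w), w),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cadfuse <- function(object, ...) {
  print(object)
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object)
}

#' Normalised fusion weights of a fitted model
#'
#' For adaptive fusion, the softmax-normalised learnable modality weights
#' (they sum to 1); for other strategies, `NULL`.
#'
#' @param object a fitted `cadfuse` model.
#' @param ... unused.
#' @export
coef.cadfuse <- function(object, ...) {
  if (object$config$fusion != "adaptive") return(NULL)
  setNames(softmax_vec(object$model$params[["fusion.raw"]]),
           object$config$modalities)
}

#' Predict stenosis-class probabilities
#'
#' @param object a fitted `cadfuse` model.
#' @param manifest a `cohort_manifest` of patients to score.
#' @param type `"prob"` (probability of class 1), `"class"` (0/1 at 0.5) or
#'   `"logit"` (the two raw logits).
#' @param split optional split filter (`"train"`, `"internal"`,
#'   `"external"`).
#' @param ... unused.
#' @return named vector (or matrix for `"logit"`) indexed by patient id.
#' @export
predict.cadfuse <- function(object, manifest, type = c("prob", "class", "logit"),
                            split = NULL, ...) {
  type <- match.arg(type)
  ds <- prepare_dataset(manifest, object$config, seed = object$train$seed,
                        preproc = object$preproc)
  keep <- if (is.null(split)) seq_along(ds$y) else which(ds$split %in% split)
  assert_that(length(keep) > 0, "no patients in requested split")
  inputs <- slice_batch(ds$inputs, keep)
  if (type == "logit") {
    fw <- model_fwd(object$model, inputs, train = FALSE)
    rownames(fw$logits) <- ds$ids[keep]
    return(fw$logits)
  }
  p <- setNames(predict_probs(object$model, inputs), ds$ids[keep])
  if (type == "class") as.integer(p >= 0.5) else p
}

#' Evaluate a fitted model on one split
#'
#' @param object a fitted `cadfuse` model.
#' @param manifest a `cohort_manifest`.
#' @param split `"train"`, `"internal"` or `"external"`.
#' @param model_name label for the report row.
#' @return one-row data.frame: `model`, `split`, `n`, `auc`, `acc`, `f1`,
#'   `recall` (AUC rank-based; accuracy at threshold 0.5; F1 and recall for
#'   the positive class).
#' @export
evaluate_model <- function(object, manifest, split = "internal",
                           model_name = "fusion") {
  rec <- manifest$records
  keep <- rec$split %in% split
  assert_that(any(keep), "split not present in manifest: ", split)
  labels <- rec$label[keep]
  assert_that(length(unique(labels)) == 2,
              "AUC undefined: split ", split, " lacks a class")
  p <- predict(object, manifest, type = "prob", split = split)
  eval_report_row(model_name, paste(split, collapse = "+"), p, labels)
}

#' Plot training diagnostics
#'
#' Left panel: training loss and internal AUC per epoch; right panel (for
#' adaptive fusion): trajectory of the normalised modality weights.
#'
#' @param x a fitted `cadfuse` model.
#' @param ... unused.
#' @export
plot.cadfuse <- function(x, ...) {
  lg <- x$log
  has_w <- any(grepl("^w_", names(lg)))
  op <- graphics::par(mfrow = c(1, if (has_w) 2 else 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$epoch, lg$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "training loss")
  if (has_w) {
    wc <- grep("^w_", names(lg), value = TRUE)
    graphics::matplot(lg$epoch, as.matrix(lg[, wc]), type = "l", lty = 1,
                      xlab = "epoch", ylab = "normalised weight",
                      main = "fusion weights", ylim = c(0, 1))
    graphics::legend("topright", legend = sub("^w_", "", wc),
                     col = seq_along(wc), lty = 1, cex = 0.8)
  }
  invisible(x)
}

#' Save / load a fitted model
#'
#' The parameter archive is a single RDS file accompanied by a JSON sidecar
#' holding the configuration and an integrity hash; loading verifies the
#' hash.
#'
#' @param object a fitted `cadfuse` model.
#' @param path output `.rds` path (sidecar written as `<path>.json`).
#' @export
save_cadfuse <- function(object, path) {
  assert_that(inherits(object, "cadfuse"), "not a cadfuse model")
  saveRDS(object, path)
  side <- list(config = object$config[setdiff(names(object$config), "")],
               hash = file_md5(path))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_cadfuse
#' @export
load_cadfuse <- function(path) {
  assert_that(file.exists(path), "model file not found: ", path)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path)
    assert_that(identical(side$hash, file_md5(path)),
                "model archive does not match its sidecar hash")
  }
  obj <- readRDS(path)
  assert_that(inherits(obj, "cadfuse"), "file is not a cadfuse model")
  obj
}
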