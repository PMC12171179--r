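## Model assembly: modality branches, decision-layer fusion and the
## classification head.

FUSION_STRATEGIES <- c("concat", "max", "mean", "sum", "attention", "adaptive")
ALL_MODALITIES <- c("tongue", "face", "pulse", "clinical")

#' Configuration of the multimodal fusion network
#'
#' Default dimensions: 3x3 convolution to
#' 64 channels, 2x2 max pooling, four 64-channel residual blocks, global
#' average pooling and a dense layer to a 128-dimensional embedding with
#' single-head self-attention for each image branch; a 64-unit LSTM plus a
#' dense layer for the pulse branch; a dense encoder for the 15 screened
#' clinical features; and an adaptive-weight decision layer producing a
#' 512-dimensional fused representation and 2 logits.
#'
#' @param image_size `c(H, W)`, both even (required by the 2x2 pooling).
#' @param conv_channels convolutional width of the image branches.
#' @param embed_dim branch embedding length.
#' @param lstm_hidden LSTM hidden width.
#' @param n_residual_blocks residual blocks per image branch.
#' @param n_clinical_in clinical features entering the clinical branch
#'   (after screening).
#' @param fusion one of `"concat"`, `"max"`, `"mean"`, `"sum"`,
#'   `"attention"`, `"adaptive"`.
#' @param attention_tokens tokens the embedding is reshaped into for branch
#'   self-attention; must divide `embed_dim`.
#' @param reg_lambda weight of the regularisation term R (sum of squared
#'   raw fusion weights; adaptive fusion only).
#' @param modalities modality subset in use (clinical data ablations).
#' @param use_lstm,use_resnet,use_attention module toggles for the
#'   architecture ablations: without the LSTM the pulse enters through a
#'   dense encoder on its 15 extracted parameters; without residual blocks
#'   the image branches are plain conv stacks; without attention the
#'   self-attention layers are dropped.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(image_size = c(64, 64),
                          conv_channels = 64,
                          embed_dim = 128,
                          lstm_hidden = 64,
                          n_residual_blocks = 4,
                          n_clinical_in = 15,
                          fusion = "adaptive",
                          attention_tokens = 8,
                          reg_lambda = 1e-4,
                          modalities = ALL_MODALITIES,
                          use_lstm = TRUE,
                          use_resnet = TRUE,
                          use_attention = TRUE) {
  assert_that(all(image_size %% 2 == 0), "image dimensions must be even")
  assert_that(fusion %in% FUSION_STRATEGIES,
              "unknown fusion strategy: ", fusion)
  assert_that(embed_dim %% attention_tokens == 0,
              "embed_dim must be divisible by attention_tokens")
  assert_that(length(modalities) >= 1 && all(modalities %in% ALL_MODALITIES),
              "invalid modality set")
  modalities <- ALL_MODALITIES[ALL_MODALITIES %in% modalities]
  structure(as.list(environment()), class = "fusion_config")
}

image_branch_layers <- function(prefix, cfg) {
  ly <- list(spec_conv3(paste0(prefix, ".conv1"), 3, cfg$conv_channels),
             spec_bn2d(paste0(prefix, ".bn1"), cfg$conv_channels),
             spec_relu4(),
             spec_maxpool2())
  if (cfg$use_resnet) {
    for (i in seq_len(cfg$n_residual_blocks)) {
      ly <- c(ly, list(spec_resblock(paste0(prefix, ".res", i), cfg$conv_channels)))
    }
  }
  ly <- c(ly, list(spec_gap(),
                   spec_dense(paste0(prefix, ".fc"), cfg$conv_channels,
                              cfg$embed_dim)))
  if (cfg$use_attention) {
    ly <- c(ly, list(spec_attn(paste0(prefix, ".attn"), cfg$attention_tokens,
                               cfg$embed_dim / cfg$attention_tokens,
                               out = "flatten")))
  }
  ly
}

pulse_branch_layers <- function(cfg) {
  if (cfg$use_lstm) {
    list(spec_lstm("pulse.lstm", 1, cfg$lstm_hidden),
         spec_dense("pulse.fc", cfg$lstm_hidden, cfg$embed_dim))
  } else {
    ## architecture-ablation fallback: dense encoder over the 15 extracted
    ## fiducial pulse parameters
    list(spec_dense("pulse.fc", length(PULSE_FEATURE_NAMES), cfg$embed_dim,
                    act = "relu"))
  }
}

clinical_branch_layers <- function(cfg) {
  list(spec_dense("clinical.fc", cfg$n_clinical_in, cfg$embed_dim, act = "relu"))
}

fused_length <- function(cfg) {
  k <- length(cfg$modalities)
  if (cfg$fusion %in% c("concat", "adaptive")) k * cfg$embed_dim else cfg$embed_dim
}

## Build an untrained model: layer specs plus freshly initialised flat
## parameter and state lists. Draws from the current RNG stream.
init_model <- function(cfg) {
  branches <- list()
  for (m in cfg$modalities) {
    branches[[m]] <- switch(m,
      tongue = image_branch_layers("tongue", cfg),
      face = image_branch_layers("face", cfg),
      pulse = pulse_branch_layers(cfg),
      clinical = clinical_branch_layers(cfg))
  }
  P_ <- do.call(c, unname(lapply(branches, stack_init)))
  S_ <- do.call(c, unname(lapply(branches, stack_state_init)))
  if (cfg$fusion == "adaptive") {
    P_[["fusion.raw"]] <- numeric(length(cfg$modalities))
  }
  fusion_attn <- NULL
  if (cfg$fusion == "attention") {
    fusion_attn <- spec_attn("fusion.attn", length(cfg$modalities),
                             cfg$embed_dim, out = "mean")
    P_ <- c(P_, layer_init(fusion_attn))
  }
  head <- spec_dense("head", fused_length(cfg), 2)
  P_ <- c(P_, layer_init(head))
  list(config = cfg, branches = branches, fusion_attn = fusion_attn,
       head = head, params = P_, state = S_)
}

softmax_vec <- function(x) { e <- exp(x - max(x)); e / sum(e) }

## Full forward pass. `batch` is a named list of modality inputs:
## tongue/face (3, H, W, N) in [0,1]; pulse (N, T) z-scored (or (N, 15)
## scaled pulse features without the LSTM); clinical (N, n_clinical_in).
model_fwd <- function(model, batch, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  P_ <- model$params; S_ <- model$state
  E <- list(); caches <- list(); updates <- list()
  for (m in cfg$modalities) {
    f <- stack_fwd(model$branches[[m]], P_, S_, batch[[m]], train,
                   keep = keep_cache)
    E[[m]] <- f$y
    if (keep_cache) caches[[m]] <- f$caches
    updates <- c(updates, f$state_updates)
  }
  k <- length(E)
  N <- nrow(E[[1]])
  weights <- NULL
  fus_cache <- NULL
  if (cfg$fusion == "concat") {
    fused <- do.call(cbind, unname(E))
  } else if (cfg$fusion == "adaptive") {
    raw <- P_[["fusion.raw"]]
    wn <- softmax_vec(raw)
    fused <- do.call(cbind, lapply(seq_len(k), function(j) wn[j] * E[[j]]))
    weights <- list(raw = raw, normalized = setNames(wn, cfg$modalities),
                    R = sum(raw^2))
  } else if (cfg$fusion %in% c("mean", "sum")) {
    fused <- Reduce(`+`, E)
    if (cfg$fusion == "mean") fused <- fused / k
  } else if (cfg$fusion == "max") {
    fused <- E[[1]]
    src <- matrix(1L, N, cfg$embed_dim)
    if (k > 1) for (j in 2:k) {
      upd <- E[[j]] > fused
      fused[upd] <- E[[j]][upd]
      src[upd] <- j
    }
    fus_cache <- src
  } else if (cfg$fusion == "attention") {
    tok <- do.call(cbind, unname(E))  # token-major rows: one token per modality
    fa <- attn_fwd(model$fusion_attn, P_, tok)
    fused <- fa$y
    fus_cache <- fa$cache
  }
  hf <- dense_fwd(model$head, P_, fused)
  list(logits = hf$y, embeddings = E, fused = fused, weights = weights,
       caches = if (keep_cache) list(branches = caches, fusion = fus_cache,
                                     head = hf$cache) else NULL,
       state_updates = updates)
}

## Backward pass from dlogits. Returns flat grads; optionally input
## gradients for chosen modalities and per-layer gradient records for one
## modality (Grad-CAM capture).
model_bwd <- function(model, fw, dlogits, input_grads = character(0),
                      record_modality = NULL) {
  cfg <- model$config
  P_ <- model$params
  k <- length(cfg$modalities)
  hb <- dense_bwd(model$head, P_, fw$caches$head, dlogits)
  grads <- hb$grads
  dfused <- hb$dx
  E <- fw$embeddings
  dE <- list()
  if (cfg$fusion == "concat") {
    for (j in seq_len(k)) {
      dE[[j]] <- dfused[, (j - 1) * cfg$embed_dim + seq_len(cfg$embed_dim),
                        drop = FALSE]
    }
  } else if (cfg$fusion == "adaptive") {
    raw <- P_[["fusion.raw"]]
    wn <- softmax_vec(raw)
    dwn <- numeric(k)
    for (j in seq_len(k)) {
      blk <- dfused[, (j - 1) * cfg$embed_dim + seq_len(cfg$embed_dim),
                    drop = FALSE]
      dE[[j]] <- wn[j] * blk
      dwn[j] <- sum(blk * E[[j]])
    }
    draw <- wn * (dwn - sum(dwn * wn)) + 2 * cfg$reg_lambda * raw
    grads[["fusion.raw"]] <- draw
  } else if (cfg$fusion %in% c("mean", "sum")) {
    scale <- if (cfg$fusion == "mean") 1 / k else 1
    for (j in seq_len(k)) dE[[j]] <- dfused * scale
  } else if (cfg$fusion == "max") {
    src <- fw$caches$fusion
    for (j in seq_len(k)) {
      dj <- dfused
      dj[src != j] <- 0
      dE[[j]] <- dj
    }
  } else if (cfg$fusion == "attention") {
    ab <- attn_bwd(model$fusion_attn, P_, fw$caches$fusion, dfused)
    grads <- c(grads, ab$grads)
    for (j in seq_len(k)) {
      dE[[j]] <- ab$dx[, (j - 1) * cfg$embed_dim + seq_len(cfg$embed_dim),
                       drop = FALSE]
    }
  }
  dinputs <- list(); records <- NULL
  for (j in seq_len(k)) {
    m <- cfg$modalities[j]
    record <- !is.null(record_modality) && m == record_modality
    sb <- stack_bwd(model$branches[[m]], P_, fw$caches$branches[[m]], dE[[j]],
                    record = record)
    grads <- c(grads, sb$grads)
    if (m %in% input_grads) dinputs[[m]] <- sb$dx
    if (record) records <- sb$grad_at
  }
  list(grads = grads, dinputs = dinputs, records = records)
}

## Weighted softmax cross-entropy. y in {0,1}; class_w length-2 weights.
## Returns loss (plus the adaptive regulariser term added by the caller)
## and dlogits.
ce_loss <- function(logits, y, class_w = c(1, 1)) {
  N <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  w <- class_w[y + 1]
  wsum <- sum(w)
  eps <- 1e-12
  loss <- sum(-w * log(p[cbind(seq_len(N), y + 1)] + eps)) / wsum
  dlog <- p
  dlog[cbind(seq_len(N), y + 1)] <- dlog[cbind(seq_len(N), y + 1)] - 1
  dlog <- dlog * (w / wsum)
  list(loss = loss, dlogits = dlog, prob = p)
}

## Adam optimizer state and update over the flat parameter list.
adam_init <- function(P_) {
  list(m = lapply(P_, function(p) p * 0), v = lapply(P_, function(p) p * 0),
       t = 0)
}

adam_step <- function(P_, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    P_[[nm]] <- P_[[nm]] - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = P_, opt = opt)
}

apply_state_updates <- function(S_, updates) {
  for (nm in names(updates)) S_[[nm]] <- updates[[nm]]
  S_
}
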