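init_tiny <- function(cfg = tiny_config(), seed = 5) {
  set.seed(seed)
  cadfuse:::init_model(cfg)
}

test_that("default architecture exposes the declared dimensions", {
  cfg <- fusion_config()  # 64x64, 64 channels, embed 128, 15 clinical
  expect_equal(cfg$conv_channels, 64)
  expect_equal(cfg$lstm_hidden, 64)
  expect_equal(cfg$n_residual_blocks, 4)
  expect_equal(cfg$n_clinical_in, 15)
  expect_equal(cadfuse:::fused_length(cfg), 512)
  set.seed(1)
  model <- cadfuse:::init_model(cfg)
  N <- 2L
  batch <- list(tongue = array(runif(3 * 64 * 64 * N), c(3, 64, 64, N)),
                face = array(runif(3 * 64 * 64 * N), c(3, 64, 64, N)),
                pulse = matrix(rnorm(N * 300), N, 300),
                clinical = matrix(runif(N * 15), N, 15))
  fw <- cadfuse:::model_fwd(model, batch, train = FALSE)
  expect_identical(dim(fw$logits), c(N, 2L))
  for (m in cfg$modalities) {
    expect_identical(dim(fw$embeddings[[m]]), c(N, 128L))
  }
  expect_identical(dim(fw$fused), c(N, 512L))
  expect_identical(dim(model$params[["pulse.lstm.Wh"]]), c(256L, 64L))
  expect_equal(sum(grepl("^tongue\\.res", names(model$params))) / 8, 4)
})

test_that("analytic gradients match finite differences through every layer", {
  for (strat in c("adaptive", "attention")) {
    cfg <- tiny_config(fusion = strat, reg_lambda = 1e-3)
    model <- init_tiny(cfg)
    set.seed(42)
    batch <- tiny_batch(3, cfg = cfg)
    y <- c(0L, 1L, 1L)
    cw <- c(1.2, 0.8)
    fw <- cadfuse:::model_fwd(model, batch, train = TRUE, keep_cache = TRUE)
    l <- cadfuse:::ce_loss(fw$logits, y, cw)
    bw <- cadfuse:::model_bwd(model, fw, l$dlogits, input_grads = "pulse")
    loss_of <- function(m2, b2 = batch) {
      f <- cadfuse:::model_fwd(m2, b2, train = TRUE)
      cadfuse:::ce_loss(f$logits, y, cw)$loss +
        if (!is.null(f$weights)) cfg$reg_lambda * f$weights$R else 0
    }
    eps <- 1e-5
    set.seed(7)
    for (nm in sample(names(bw$grads), 12)) {
      g <- bw$grads[[nm]]
      i <- sample(length(g), 1)
      m2 <- model
      m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      lp <- loss_of(m2)
      m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
      lm <- loss_of(m2)
      expect_lt(abs((lp - lm) / (2 * eps) - g[i]), 1e-5)
    }
    ## input-space gradient (pulse saliency path)
    i <- 17
    b2 <- batch
    b2$pulse[i] <- b2$pulse[i] + eps
    lp <- loss_of(model, b2)
    b2$pulse[i] <- b2$pulse[i] - 2 * eps
    lm <- loss_of(model, b2)
    expect_lt(abs((lp - lm) / (2 * eps) - bw$dinputs$pulse[i]), 1e-6)
  }
})

test_that("residual blocks with zeroed weights are the identity", {
  cfg <- tiny_config()
  model <- init_tiny(cfg)
  for (nm in grep("^tongue\\.res1", names(model$params), value = TRUE)) {
    if (grepl("gamma$", nm)) next  # BN scale stays 1
    model$params[[nm]] <- model$params[[nm]] * 0
  }
  x <- array(runif(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  sp <- cadfuse:::spec_resblock("tongue.res1", 4)
  out <- cadfuse:::resblock_fwd(sp, model$params, model$state, x, train = FALSE)
  expect_equal(out$y, x * (x > 0))  # conv path zero; skip + final ReLU
})

test_that("branch contracts hold: shapes, zero inputs, affinity, order", {
  cfg <- tiny_config()
  model <- init_tiny(cfg)
  ## clinical branch affine-before-activation contract
  da <- matrix(runif(8), 2, 4); db <- matrix(runif(8), 2, 4)
  model$params[["clinical.fc.b"]] <- model$params[["clinical.fc.b"]] * 0
  W <- model$params[["clinical.fc.W"]]
  expect_equal((da + db) %*% W, da %*% W + db %*% W)
  f0 <- cadfuse:::stack_fwd(model$branches$clinical, model$params, model$state,
                            matrix(0, 2, 4), train = FALSE)
  expect_true(all(f0$y == 0))  # zero vector, zero bias -> zero embedding
  ## LSTM zero sequence with zeroed weights -> embedding equals the bias
  model$params[["pulse.lstm.Wx"]] <- model$params[["pulse.lstm.Wx"]] * 0
  model$params[["pulse.lstm.Wh"]] <- model$params[["pulse.lstm.Wh"]] * 0
  model$params[["pulse.lstm.b"]] <- model$params[["pulse.lstm.b"]] * 0
  fz <- cadfuse:::stack_fwd(model$branches$pulse, model$params, model$state,
                            matrix(0, 2, 20), train = FALSE)
  expect_equal(fz$y[1, ], model$params[["pulse.fc.b"]])
  ## order sensitivity on a ramp input
  model2 <- init_tiny(cfg)
  ramp <- matrix(seq(-1, 1, length.out = 20), 1, 20)
  fr <- cadfuse:::stack_fwd(model2$branches$pulse, model2$params, model2$state,
                            ramp, train = FALSE)
  frev <- cadfuse:::stack_fwd(model2$branches$pulse, model2$params, model2$state,
                              ramp[, 20:1, drop = FALSE], train = FALSE)
  expect_gt(max(abs(fr$y - frev$y)), 1e-6)
  ## identical zero images give identical embeddings
  z <- array(0, c(3, 8, 8, 2))
  fi <- cadfuse:::stack_fwd(model2$branches$tongue, model2$params, model2$state,
                            z, train = FALSE)
  expect_equal(fi$y[1, ], fi$y[2, ])
})

test_that("fusion strategies follow their algebraic contracts", {
  cfg <- tiny_config(fusion = "adaptive")
  model <- init_tiny(cfg)
  set.seed(31)
  batch <- tiny_batch(2, cfg = cfg)
  fw <- cadfuse:::model_fwd(model, batch, train = FALSE)
  ## equal raw weights: fused = 0.25 * concat, weights normalised to 1
  expect_equal(unname(fw$weights$normalized),
               rep(0.25, 4), tolerance = 1e-12)
  expect_equal(fw$weights$R, 0)
  cfg_c <- cfg; cfg_c$fusion <- "concat"
  model_c <- model
  model_c$config <- cfg_c
  fwc <- cadfuse:::model_fwd(model_c, batch, train = FALSE)
  expect_equal(fw$fused, 0.25 * fwc$fused)
  ## function equivalence up to head rescaling at initialisation
  model_c2 <- model_c
  model_c2$params[["head.W"]] <- model_c2$params[["head.W"]] * 0.25
  fwc2 <- cadfuse:::model_fwd(model_c2, batch, train = FALSE)
  expect_equal(fw$logits, fwc2$logits, tolerance = 1e-12)
  ## max fusion returns a dominating embedding unchanged
  cfg_m <- tiny_config(fusion = "max", use_attention = FALSE)
  model_m <- init_tiny(cfg_m)
  ## push the tongue embedding up so it dominates every coordinate
  model_m$params[["tongue.fc.b"]] <- model_m$params[["tongue.fc.b"]] + 50
  fwm <- cadfuse:::model_fwd(model_m, tiny_batch(2, cfg = cfg_m), train = FALSE)
  expect_equal(fwm$fused, fwm$embeddings$tongue)
  ## unknown strategy rejected at config time
  expect_error(fusion_config(fusion = "geometric"), "fusion")
})

test_that("training updates keep the adaptive weights on the simplex", {
  g <- test_cohort("small")
  cfg <- exp_profile(image_size = c(16, 16))
  fit <- cadfuse_fit(g$manifest, cfg,
                     train_spec(epochs = 2, batch_size = 8, seed = 2))
  w <- coef(fit)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  wl <- fit$log[, grep("^w_", names(fit$log))]
  expect_equal(unname(rowSums(as.matrix(wl))), rep(1, nrow(wl)),
               tolerance = 1e-12)
  expect_true(all(fit$log$R >= 0))
})

test_that("raising the weight regulariser shrinks R", {
  g <- test_cohort("small")
  final_R <- function(lambda, seed) {
    cfg <- exp_profile(reg_lambda = lambda)
    fit <- cadfuse_fit(g$manifest, cfg,
                       train_spec(epochs = 2, batch_size = 8, seed = seed))
    utils::tail(fit$log$R, 1)
  }
  for (s in 1:2) {
    r_small <- final_R(1e-4, s)
    r_big <- final_R(5, s)
    expect_gte(r_small, 0)
    expect_lt(r_big, r_small)
  }
})
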