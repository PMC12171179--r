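## fixtures shared across interpretability tests, trained once per run:
## a tongue+pulse model where all class signal sits in the coating region,
## and a pulse-only model where the signal lives in waveform dynamics
trained_tongue_model <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      g <- test_cohort("strong_tongue")
      cfg <- exp_profile(image_size = c(32, 32),
                         modalities = c("tongue", "pulse"))
      fit <<- cadfuse_fit(g$manifest, cfg,
                          train_spec(epochs = 10, batch_size = 8, seed = 4,
                                     patience = Inf))
    }
    fit
  }
})

trained_pulse_model <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      g <- test_cohort("dynamics")
      cfg <- exp_profile(image_size = c(12, 12), modalities = "pulse")
      fit <<- cadfuse_fit(g$manifest, cfg,
                          train_spec(epochs = 20, batch_size = 8, seed = 2,
                                     patience = Inf))
    }
    fit
  }
})

test_that("Grad-CAM matches the closed form on a one-layer toy model", {
  ## toy branch: identity feature maps -> GAP -> linear head
  C <- 5; H <- 4; W <- 4
  set.seed(6)
  A <- array(runif(C * H * W), c(C, H, W, 1))
  Wh <- matrix(rnorm(C * 2), C, 2)
  layers <- list(cadfuse:::spec_gap(), cadfuse:::spec_dense("head", C, 2))
  P_ <- list(head.W = Wh, head.b = c(0, 0))
  fw <- cadfuse:::stack_fwd(layers, P_, list(), A, train = FALSE)
  dlog <- matrix(c(0, 1), 1, 2)  # explain class 1
  bw <- cadfuse:::stack_bwd(layers, P_, fw$caches, dlog, record = TRUE)
  cam <- cadfuse:::gradcam_from_maps(A, bw$grad_at[[1]])
  ## closed form: alpha_k = w_k / (H W); CAM = relu(sum_k alpha_k A_k)
  expected <- matrix(0, H, W)
  for (k in seq_len(C)) expected <- expected + Wh[k, 2] / (H * W) * A[k, , , 1]
  expected[expected < 0] <- 0
  expect_equal(cam, expected, tolerance = 1e-12)
  ## constant feature maps under any head give a flat (all-zero) map
  Aconst <- array(1, c(C, H, W, 1))
  fw2 <- cadfuse:::stack_fwd(layers, P_, list(), Aconst, train = FALSE)
  bw2 <- cadfuse:::stack_bwd(layers, P_, fw2$caches, dlog, record = TRUE)
  cam2 <- cadfuse:::gradcam_from_maps(Aconst, bw2$grad_at[[1]])
  expect_equal(max(cam2) - min(cam2), 0)
})

test_that("image saliency maps are normalised and leave the model untouched", {
  fit <- trained_tongue_model()
  g <- test_cohort("strong_tongue")
  id <- g$manifest$records$patient_id[1]
  before <- fit$model$params
  cam <- gradcam_image(fit, g$manifest, id, "tongue")
  expect_s3_class(cam, "saliency_map")
  expect_identical(dim(cam$map), c(32L, 32L))
  expect_gte(min(cam$map), 0)
  expect_lte(max(cam$map), 1)
  expect_true(cam$target_class %in% 0:1)
  expect_identical(fit$model$params, before)
  expect_error(gradcam_image(fit, g$manifest, id, "face"), "face")
})

test_that("confident tongue-class CAMs carry positive mass in the coating", {
  fit <- trained_tongue_model()
  g <- test_cohort("strong_tongue")
  ids <- utils::head(g$manifest$records$patient_id, 12)
  mass <- vapply(ids, function(id)
    max(gradcam_image(fit, g$manifest, id)$map), numeric(1))
  expect_gte(mean(mass > 0), 0.9)
  ## class-1 CAMs concentrate on the coating region where the signal lives
  mk <- tongue_region_masks(32, 32)
  pos <- g$manifest$records$patient_id[g$manifest$records$label == 1][1:6]
  enr <- vapply(pos, function(id) {
    m <- gradcam_image(fit, g$manifest, id, "tongue", target_class = 1)$map
    mean(m[mk$coating]) / max(mean(m[!mk$coating]), 1e-9)
  }, numeric(1))
  expect_gt(median(enr), 1.5)
})

test_that("Grad-CAM agrees with counterfactual occlusion importance", {
  fit <- trained_tongue_model()
  g <- test_cohort("strong_tongue")
  ds <- cadfuse:::prepare_dataset(g$manifest, fit$config,
                                  seed = fit$train$seed,
                                  preproc = fit$preproc)
  donor <- cadfuse:::slice_batch(ds$inputs, which(ds$y == 0)[1])
  rhos <- vapply(which(ds$y == 1)[1:6], function(i) {
    cam <- gradcam_image(fit, g$manifest, ds$ids[i], "tongue",
                         target_class = 1)
    single <- cadfuse:::slice_batch(ds$inputs, i)
    base <- cadfuse:::model_fwd(fit$model, single, train = FALSE)$logits[1, 2]
    occ <- matrix(0, 4, 4); camp <- matrix(0, 4, 4)
    for (r in 1:4) for (cc in 1:4) {
      rows <- (r - 1) * 8 + 1:8; cols <- (cc - 1) * 8 + 1:8
      b2 <- single
      b2$tongue[, rows, cols, ] <- donor$tongue[, rows, cols, ]
      occ[r, cc] <- base -
        cadfuse:::model_fwd(fit$model, b2, train = FALSE)$logits[1, 2]
      camp[r, cc] <- mean(cam$map[rows, cols])
    }
    suppressWarnings(cor(as.vector(occ), as.vector(camp), method = "spearman"))
  }, numeric(1))
  expect_gt(median(rhos, na.rm = TRUE), 0.5)
})

test_that("pulse saliency marks exactly the top 20% with stable ties", {
  fit <- trained_tongue_model()
  g <- test_cohort("strong_tongue")
  id <- g$manifest$records$patient_id[2]
  ps <- pulse_saliency(fit, g$manifest, id)
  expect_length(ps$importance, 300)
  expect_length(ps$marked_indices, 60)  # ceil(0.2 * 300)
  expect_setequal(ps$marked_indices,
                  cadfuse:::top_k_idx(ps$importance, 60))
  ## constant importance: the earliest indices win
  expect_identical(cadfuse:::top_k_idx(rep(1, 300), 60), 1:60)
  ## gradient x input variant runs with the same marking contract
  ps2 <- pulse_saliency(fit, g$manifest, id, method = "gradient_x_input")
  expect_length(ps2$marked_indices, 60)
})

test_that("marked pulse points concentrate where the class signal lives", {
  fit <- trained_pulse_model()
  g <- test_cohort("dynamics")
  ds <- cadfuse:::prepare_dataset(g$manifest, fit$config,
                                  seed = fit$train$seed,
                                  preproc = fit$preproc)
  set.seed(10)
  ids <- sample(which(ds$y == 1), 20)
  excess <- vapply(ids, function(i) {
    ps <- pulse_saliency(fit, g$manifest, ds$ids[i], target_class = 1)
    x <- ps$segment
    ## tidal-region windows of each beat, located from the segment itself
    pk <- pracma::findpeaks(x, minpeakdistance = 20,
                            minpeakheight = unname(quantile(x, 0.75)))
    win <- rep(FALSE, length(x))
    for (p in sort(pk[, 2])) {
      lo <- min(max(p + 2, 1), length(x)); hi <- min(p + 15, length(x))
      win[lo:hi] <- TRUE  # ~0.04-0.30 s after the systolic peak
    }
    mean(ps$marked_indices %in% which(win)) - mean(win)
  }, numeric(1))
  ## permutation reference: marked sets drawn uniformly have excess ~ 0
  expect_gt(mean(excess), 0)
  expect_lt(2 * pnorm(-abs(mean(excess) / (sd(excess) / sqrt(length(excess))))),
            0.05)
})

test_that("overlays are written with matching metadata and no side effects", {
  fit <- trained_tongue_model()
  g <- test_cohort("strong_tongue")
  id <- g$manifest$records$patient_id[3]
  out <- file.path(tempdir(), "overlays")
  unlink(out, recursive = TRUE)
  save_cadfuse(fit, file.path(tempdir(), "m.rds"))
  h0 <- cadfuse:::file_md5(file.path(tempdir(), "m.rds"))
  files <- render_overlays(fit, g$manifest, id, out)
  expect_true(all(file.exists(files)))
  img <- read_image(file.path(out, "tongue_cam.png"))
  expect_identical(dim(img), c(32L, 32L, 3L))
  meta <- jsonlite::read_json(file.path(out, "saliency.json"))
  expect_equal(meta$pulse$n_marked, 60)
  expect_equal(length(meta$pulse$marked_indices), 60)
  ## rendering is pure visualisation: the saved model is unchanged
  save_cadfuse(fit, file.path(tempdir(), "m.rds"))
  expect_identical(cadfuse:::file_md5(file.path(tempdir(), "m.rds")), h0)
})
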