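## Model interpretation: Grad-CAM for the image branches and input-gradient
## saliency with top-20% marking for the pulse branch.

prepare_single <- function(object, manifest, patient_id) {
  ds <- prepare_dataset(manifest, object$config, seed = object$train$seed,
                        preproc = object$preproc)
  i <- match(patient_id, ds$ids)
  assert_that(!is.na(i), "patient not in manifest: ", patient_id)
  list(inputs = slice_batch(ds$inputs, i), y = ds$y[i])
}

predicted_class <- function(logits) which.max(logits[1, ]) - 1L

## index (within a branch layer list) of the spatial feature map feeding
## global average pooling: Grad-CAM's target layer
gap_position <- function(layers) {
  idx <- which(vapply(layers, function(l) l$type == "gap", logical(1)))
  assert_that(length(idx) == 1, "branch has no global average pooling layer")
  idx
}

gradcam_from_maps <- function(A, dA) {
  ## A, dA: (C, H', W', 1); channel weights = spatially averaged gradients
  d <- dim(A)
  Am <- matrix(A, d[1], d[2] * d[3])
  dAm <- matrix(dA, d[1], d[2] * d[3])
  alpha <- rowMeans(dAm)
  cam <- matrix(colSums(Am * alpha), d[2], d[3])
  cam[cam < 0] <- 0
  cam
}

normalize01 <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' Grad-CAM saliency map for an image branch
#'
#' Computes the gradient of the target-class logit with respect to the last
#' spatial feature map of the branch (the output of the final residual
#' block), weights each channel by its spatially averaged gradient, sums,
#' rectifies, upsamples bilinearly to the input size and normalises to
#' \[0, 1\] (an all-zero map is left as zeros).
#'
#' @param object a fitted `cadfuse` model.
#' @param manifest a `cohort_manifest`.
#' @param patient_id patient to explain.
#' @param modality `"tongue"` or `"face"`.
#' @param target_class logit to explain (0 or 1); default the predicted
#'   class.
#' @return object of class `saliency_map`: `map` (H x W in \[0,1\]),
#'   `target_class`, `modality`.
#' @export
gradcam_image <- function(object, manifest, patient_id,
                          modality = c("tongue", "face"),
                          target_class = NULL) {
  modality <- match.arg(modality)
  assert_that(modality %in% object$config$modalities,
              "model was trained without the ", modality, " branch")
  sg <- prepare_single(object, manifest, patient_id)
  fw <- model_fwd(object$model, sg$inputs, train = FALSE, keep_cache = TRUE)
  if (is.null(target_class)) target_class <- predicted_class(fw$logits)
  dlog <- matrix(0, 1, 2)
  dlog[1, target_class + 1] <- 1
  bw <- model_bwd(object$model, fw, dlog, record_modality = modality)
  layers <- object$model$branches[[modality]]
  gp <- gap_position(layers)
  ## activations entering gap: recompute forward to that point
  part <- stack_fwd(layers[seq_len(gp - 1)], object$model$params,
                    object$model$state, sg$inputs[[modality]], train = FALSE)
  A <- part$y
  dA <- bw$records[[gp]]
  cam <- normalize01(gradcam_from_maps(A, dA))
  H <- object$config$image_size[1]; W <- object$config$image_size[2]
  structure(list(map = normalize01(bilinear_resize(cam, H, W)),
                 target_class = target_class, modality = modality,
                 patient_id = patient_id),
            class = "saliency_map")
}

#' Input-gradient saliency for the pulse branch
#'
#' Grad-CAM is not well defined for a recurrent branch, so pulse saliency
#' is computed in input space: the absolute gradient of the target-class
#' logit with respect to each timestep of the (z-scored) 6-s segment,
#' optionally multiplied by the input. The top 20% of timesteps by
#' importance are marked (`ceil(0.2 * length)` points; ties broken by
#' earlier index).
#'
#' @inheritParams gradcam_image
#' @param method `"gradient"` (default) or `"gradient_x_input"`.
#' @param top_frac fraction of timesteps to mark (default 0.2).
#' @return object of class `pulse_saliency`: `importance` (length = segment
#'   length), `marked_indices` (sorted), `target_class`, `segment` (the
#'   z-scored input).
#' @export
pulse_saliency <- function(object, manifest, patient_id, target_class = NULL,
                           method = c("gradient", "gradient_x_input"),
                           top_frac = 0.2) {
  method <- match.arg(method)
  assert_that("pulse" %in% object$config$modalities && object$config$use_lstm,
              "pulse saliency requires a model with the LSTM pulse branch")
  sg <- prepare_single(object, manifest, patient_id)
  fw <- model_fwd(object$model, sg$inputs, train = FALSE, keep_cache = TRUE)
  if (is.null(target_class)) target_class <- predicted_class(fw$logits)
  dlog <- matrix(0, 1, 2)
  dlog[1, target_class + 1] <- 1
  bw <- model_bwd(object$model, fw, dlog, input_grads = "pulse")
  g <- as.numeric(bw$dinputs$pulse)
  x <- as.numeric(sg$inputs$pulse)
  imp <- if (method == "gradient") abs(g) else abs(g * x)
  n_mark <- ceiling(top_frac * length(imp))
  marked <- sort(top_k_idx(imp, n_mark))
  structure(list(importance = imp, marked_indices = marked,
                 target_class = target_class, segment = x,
                 patient_id = patient_id, method = method),
            class = "pulse_saliency")
}

heat_rgb <- function(v) {
  ramp <- grDevices::colorRamp(c("#000080", "#d62728", "#ffd700"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

overlay_heatmap <- function(img, map, alpha_max = 0.55) {
  base <- img / 255
  hv <- as.numeric(map)
  hcol <- heat_rgb(hv)
  alpha <- alpha_max * hv
  out <- base
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * base[, , ch] + alpha * hcol[, ch]
  }
  out * 255
}

## simple raster plot of a pulse curve with marked saliency points
render_pulse_raster <- function(ps, height = 160) {
  x <- ps$segment
  n <- length(x)
  W <- n + 20; H <- height
  img <- array(1, c(H, W, 3))
  rng <- range(x)
  ypix <- round((1 - (x - rng[1]) / diff(rng)) * (H - 21)) + 10
  xpix <- 10 + seq_len(n)
  for (i in seq_len(n - 1)) {  # vertical fill between successive samples
    ys <- ypix[i]:ypix[i + 1]
    img[ys, xpix[i], ] <- 0.2
  }
  for (m in ps$marked_indices) {  # 3x3 black dots at marked points
    yy <- pmin(pmax(ypix[m] + (-1:1), 1), H)
    xx <- pmin(pmax(xpix[m] + (-1:1), 1), W)
    img[yy, xx, ] <- 0
  }
  img * 255
}

#' Write saliency overlays for one patient
#'
#' Renders `tongue_cam.png` and `face_cam.png` (heat colormap alpha-blended
#' over the input image), `pulse_saliency.png` (the segment with black dots
#' at the marked points) and `saliency.json` (marked indices and the
#' normalised maps). Pure visualisation: no model state is touched.
#'
#' @param object a fitted `cadfuse` model.
#' @param manifest a `cohort_manifest`.
#' @param patient_id patient to explain.
#' @param out_dir output directory (created if absent).
#' @param target_class logit to explain; default the predicted class.
#' @return invisibly, the list of files written.
#' @export
render_overlays <- function(object, manifest, patient_id, out_dir,
                            target_class = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  meta <- list(patient_id = patient_id)
  i <- match(patient_id, manifest$records$patient_id)
  assert_that(!is.na(i), "patient not in manifest: ", patient_id)
  for (m in intersect(c("tongue", "face"), object$config$modalities)) {
    cam <- gradcam_image(object, manifest, patient_id, m, target_class)
    img <- read_image(file.path(manifest$root,
                                manifest$records[[paste0(m, "_path")]][i]),
                      size = object$config$image_size)
    f <- file.path(out_dir, paste0(m, "_cam.png"))
    write_image(overlay_heatmap(img, cam$map), f)
    files <- c(files, f)
    meta[[paste0(m, "_cam")]] <- list(target_class = cam$target_class,
                                      map = round(cam$map, 4))
  }
  if ("pulse" %in% object$config$modalities && object$config$use_lstm) {
    ps <- pulse_saliency(object, manifest, patient_id, target_class)
    f <- file.path(out_dir, "pulse_saliency.png")
    write_image(render_pulse_raster(ps), f)
    files <- c(files, f)
    meta$pulse <- list(target_class = ps$target_class,
                       n_marked = length(ps$marked_indices),
                       marked_indices = ps$marked_indices)
  }
  jf <- file.path(out_dir, "saliency.json")
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}
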