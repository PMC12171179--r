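## Shared synthetic cohorts, generated once per test run and cached in the
## session temporary directory.

.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function(name) {
  if (!is.null(.cohort_cache[[name]])) return(.cohort_cache[[name]])
  spec <- switch(name,
    small = cohort_spec(n_patients = 24, seed = 101, image_size = c(16, 16)),
    noiseless = cohort_spec(n_patients = 6, seed = 103, image_size = c(16, 16),
                            pulse_noise_sd = 0, drift_amplitude = 0,
                            hrv_sd = 0, pulse_tidal_jitter_effect = 0),
    strong_tongue = cohort_spec(n_patients = 90, seed = 105,
                                image_size = c(32, 32),
                                tongue_effect = 45, face_effect = 0,
                                pulse_effect = 0,
                                pulse_tidal_jitter_effect = 0,
                                clinical_effects = c(),
                                binary_rates = list(),
                                image_noise_sd = 6),
    dynamics = cohort_spec(n_patients = 160, seed = 107,
                           image_size = c(12, 12),
                           tongue_effect = 0, face_effect = 0,
                           pulse_effect = 0,
                           pulse_tidal_jitter_effect = 0.045,
                           pulse_noise_sd = 0.01, image_noise_sd = 2,
                           clinical_effects = c(),
                           binary_rates = list(hypertension_like = c(0.5, 0.5))),
    stop("unknown test cohort: ", name))
  out <- generate_cohort(spec, file.path(tempdir(), paste0("cohort_", name)))
  out$spec <- spec
  .cohort_cache[[name]] <- out
  out
}

## small fully-specified config used across network tests
tiny_config <- function(...) {
  fusion_config(image_size = c(8, 8), conv_channels = 4, embed_dim = 16,
                lstm_hidden = 6, n_residual_blocks = 2, n_clinical_in = 4,
                attention_tokens = 4, ...)
}

tiny_batch <- function(N = 3, T_ = 20, cfg = tiny_config()) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  list(tongue = array(runif(3 * H * W * N), c(3, H, W, N)),
       face = array(runif(3 * H * W * N), c(3, H, W, N)),
       pulse = matrix(rnorm(N * T_), N, T_),
       clinical = matrix(runif(N * cfg$n_clinical_in), N, cfg$n_clinical_in))
}

## experiment profile shared by the heavier property tests: small rasters
## and narrow branches so a full training run takes seconds
exp_profile <- function(image_size = c(16, 16), ...) {
  fusion_config(image_size = image_size, conv_channels = 8, lstm_hidden = 24,
                attention_tokens = 8, ...)
}

heldout_auc <- function(fit, ds) {
  ho <- which(ds$split != "train")
  p <- cadfuse:::predict_probs(fit$model, cadfuse:::slice_batch(ds$inputs, ho))
  metric_auc(p, ds$y[ho])
}
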