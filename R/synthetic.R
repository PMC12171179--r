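## Class-conditional synthetic multimodal cohort generator.
##
## The generator emulates the structure of the clinical data streams --
## tongue photographs with a coating region, facial photographs with
## forehead/nose/cheek regions, 30-s radial pulse recordings with
## percussion/tidal/dicrotic morphology, and a 50-column clinical panel --
## while planting class signal at known, configurable places:
##   * tongue: hue shift of the coating region for label 1;
##   * face: brightness shift of the three facial regions for label 1;
##   * pulse: shift of the tidal-to-percussion amplitude ratio h3/h1, and
##     optionally a high-frequency ripple that leaves the fiducial
##     parameters untouched (signal living purely in waveform dynamics);
##   * clinical: standardised mean shifts on named marker columns and
##     class-dependent rates on binary risk-factor columns.
## Every draw is deterministic under the spec's seed, so cohorts are
## file-hash reproducible.

#' Specification of a synthetic multimodal cohort
#'
#' Defaults describe the reference study condition used throughout the
#' package's validation experiments: a balanced cohort with moderate signal
#' in all four modalities.
#'
#' @param n_patients cohort size.
#' @param prevalence fraction of label-1 (stenosis >= 75 percent) patients;
#'   strictly inside (0, 1).
#' @param seed integer seed; identical spec + seed give bit-identical files.
#' @param image_size `c(H, W)`, both even.
#' @param tongue_effect hue shift (degrees) of the coating region for label 1.
#' @param face_effect brightness shift (0-255 units) of the facial regions
#'   for label 1.
#' @param pulse_effect additive shift of the mean h3/h1 ratio for label 1.
#' @param pulse_ripple_effect amplitude (relative to h1) of an 8-Hz ripple
#'   added for label 1.
#' @param pulse_tidal_shift_effect shift (s) of the mean tidal-wave centre
#'   for label 1 (leaks partially into the notch-timing parameter t4).
#' @param pulse_tidal_jitter_effect extra cycle-to-cycle standard deviation
#'   (s) of the tidal-wave centre for label 1: a waveform-dynamics signal
#'   that leaves every per-patient mean fiducial parameter unchanged
#'   (amplitudes are fixed and timing jitter is zero-mean), so it is
#'   invisible to the averaged 15-parameter table but visible to a
#'   sequence model.
#' @param clinical_effects named numeric vector of standardised mean
#'   differences planted on clinical columns (label 1 minus label 0).
#' @param binary_rates named list of `c(p0, p1)` Bernoulli rates for binary
#'   risk-factor columns.
#' @param n_clinical total clinical columns (remainder are standard-normal
#'   noise).
#' @param image_noise_sd pixel noise (0-255 units).
#' @param pulse_noise_sd white noise on the pressure series (units of h1).
#' @param drift_amplitude,drift_freq baseline drift sinusoid (units of h1, Hz).
#' @param heart_period_s mean cardiac cycle length (s).
#' @param hrv_sd per-cycle standard deviation of the cycle length (s).
#' @param duration_s recording length (s).
#' @param sampling_interval sampling interval (s), default 1/50.
#' @param split_frac train/internal/external fractions (sum to 1).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100,
                        prevalence = 0.5,
                        seed = 1,
                        image_size = c(64, 64),
                        tongue_effect = 10,
                        face_effect = 5,
                        pulse_effect = 0.08,
                        pulse_ripple_effect = 0,
                        pulse_tidal_shift_effect = 0,
                        pulse_tidal_jitter_effect = 0.045,
                        clinical_effects = c(fibrinogen_like = 0.4,
                                             d_dimer_like = 0.3,
                                             fdp_like = 0.25,
                                             myoglobin_like = 0.35),
                        binary_rates = list(hypertension_like = c(0.45, 0.55),
                                            diabetes_like = c(0.30, 0.40)),
                        n_clinical = 50,
                        image_noise_sd = 10,
                        pulse_noise_sd = 0.02,
                        drift_amplitude = 0.1,
                        drift_freq = 0.1,
                        heart_period_s = 0.8,
                        hrv_sd = 0.01,
                        duration_s = 30,
                        sampling_interval = 1 / 50,
                        split_frac = c(train = 0.7, internal = 0.15, external = 0.15)) {
  assert_that(prevalence > 0 && prevalence < 1,
              "prevalence must be strictly between 0 and 1")
  assert_that(all(image_size %% 2 == 0), "image dimensions must be even")
  assert_that(n_clinical >= length(clinical_effects) + length(binary_rates),
              "n_clinical smaller than the number of keyed effects")
  assert_that(all(is.finite(c(tongue_effect, face_effect, pulse_effect,
                              pulse_ripple_effect, clinical_effects))),
              "effect sizes must be finite")
  assert_that(abs(sum(split_frac) - 1) < 1e-8, "split fractions must sum to 1")
  assert_that(heart_period_s > 0.4 && heart_period_s < 2,
              "cycle period incompatible with segment analysis")
  structure(as.list(environment()), class = "cohort_spec")
}

## ---- images -----------------------------------------------------------

paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    m <- img[, , ch]; m[mask] <- rgb[ch]; img[, , ch] <- m
  }
  img
}

hsv255 <- function(h_deg, s, v) {
  grDevices::col2rgb(grDevices::hsv((h_deg %% 360) / 360, min(max(s, 0), 1),
                                    min(max(v, 0), 1)))[, 1]
}

add_pixel_noise <- function(img, sd) {
  if (sd > 0) img <- img + array(rnorm(length(img), 0, sd), dim(img))
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

#' Draw one synthetic tongue image
#'
#' An elliptical tongue body on a dark background with a central coating
#' region; for `class = 1` the coating hue is shifted by
#' `spec$tongue_effect` degrees.
#'
#' @param class label 0 or 1.
#' @param spec a [cohort_spec()].
#' @return `H x W x 3` array, values 0-255.
#' @export
synth_tongue_image <- function(class, spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  mk <- tongue_region_masks(H, W)
  img <- array(0, c(H, W, 3))
  img <- paint(img, !logical(H * W), c(45, 38, 38) + rnorm(3, 0, 2))
  body <- hsv255(355 + rnorm(1, 0, 4), 0.42 + rnorm(1, 0, 0.03),
                 0.72 + rnorm(1, 0, 0.04))
  img <- paint(img, mk$tongue, body)
  coat_h <- 45 + rnorm(1, 0, 3) + if (class == 1) spec$tongue_effect else 0
  coat <- hsv255(coat_h, 0.25 + rnorm(1, 0, 0.03), 0.82 + rnorm(1, 0, 0.04))
  img <- paint(img, mk$coating, coat)
  add_pixel_noise(img, spec$image_noise_sd)
}

#' Draw one synthetic face image
#'
#' An elliptical face on a dark background; for `class = 1` the forehead,
#' nose and cheek regions are brightened by `spec$face_effect` (0-255
#' units).
#'
#' @inheritParams synth_tongue_image
#' @return `H x W x 3` array, values 0-255.
#' @export
synth_face_image <- function(class, spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  mk <- face_region_masks(H, W)
  img <- array(0, c(H, W, 3))
  img <- paint(img, !logical(H * W), c(60, 55, 60) + rnorm(3, 0, 2))
  skin <- c(214, 176, 150) + rnorm(3, 0, 4)
  img <- paint(img, mk$face, skin)
  if (class == 1 && spec$face_effect != 0) {
    shift <- mk$forehead | mk$nose | mk$cheek_left | mk$cheek_right
    for (ch in 1:3) {
      m <- img[, , ch]; m[shift] <- m[shift] + spec$face_effect
      img[, , ch] <- m
    }
  }
  add_pixel_noise(img, spec$image_noise_sd)
}

## ---- pulse ------------------------------------------------------------

## Morphology constants of one synthetic cycle (seconds, fractions of h1):
## percussion bump at t1c, tidal bump at t3c, dicrotic bump at t5c; the
## dicrotic notch emerges as the composite minimum between the tidal and
## dicrotic bumps.
PULSE_SHAPE <- list(t1c = 0.11, s1 = 0.040,
                    t3c = 0.24, s3 = 0.055,
                    t5c = 0.42, s5 = 0.045, dic = 0.25)

gauss_bump <- function(t, centre, sigma) exp(-(t - centre)^2 / (2 * sigma^2))

#' Synthesise one pulse recording with per-cycle ground truth
#'
#' The recording is a sum over cycles of three Gaussian bumps (percussion,
#' tidal, dicrotic), plus sinusoidal baseline drift and white noise, and --
#' for `class = 1` with `pulse_ripple_effect > 0` -- an 8-Hz ripple. The
#' tidal-to-percussion bump ratio is drawn with mean
#' `0.48 + pulse_effect * class`. Ground-truth landmarks (onset, peak, tidal
#' and notch positions, amplitudes) are measured on the noiseless sampled
#' signal by bracketed searches around the known bump centres, independently
#' of the package's extraction pipeline.
#'
#' @inheritParams synth_tongue_image
#' @return list with `recording` (a [pulse_recording()]) and `truth`, a
#'   per-cycle data.frame of ground-truth landmarks (`onset_idx`,
#'   `peak_idx`, `h1`, `h3`, `h3_over_h1`, `t1`, `t`, `t4`, `h4`, `h5`,
#'   `bump_ratio`).
#' @export
synth_pulse <- function(class, spec) {
  dt <- spec$sampling_interval
  n <- round(spec$duration_s / dt)
  tt <- (seq_len(n) - 1) * dt
  sh <- PULSE_SHAPE

  patient_period <- spec$heart_period_s + rnorm(1, 0, 0.04)
  patient_h1 <- max(rnorm(1, 1, 0.08), 0.5)
  patient_r <- 0.48 + spec$pulse_effect * class + rnorm(1, 0, 0.04)
  patient_r <- min(max(patient_r, 0.15), 0.85)
  t3c <- sh$t3c + spec$pulse_tidal_shift_effect * class + rnorm(1, 0, 0.005)
  t3_jitter <- 0.004 + spec$pulse_tidal_jitter_effect * class

  onsets <- c(); periods <- c(); s <- 0
  while (s + 1.2 * patient_period < spec$duration_s + patient_period) {
    p <- max(patient_period + rnorm(1, 0, spec$hrv_sd), 0.5)
    onsets <- c(onsets, s); periods <- c(periods, p); s <- s + p
  }
  clean <- numeric(n)
  amps <- matrix(0, length(onsets), 2)  # h1 bump, ratio per cycle
  for (i in seq_along(onsets)) {
    a1 <- patient_h1 * (1 + rnorm(1, 0, 0.02))
    r <- min(max(patient_r + rnorm(1, 0, 0.01), 0.1), 0.9)
    amps[i, ] <- c(a1, r)
    o <- onsets[i]
    t3i <- t3c + rnorm(1, 0, t3_jitter)
    clean <- clean + a1 * (gauss_bump(tt, o + sh$t1c, sh$s1) +
                           r * gauss_bump(tt, o + t3i, sh$s3) +
                           sh$dic * gauss_bump(tt, o + sh$t5c, sh$s5))
  }
  x <- clean
  if (class == 1 && spec$pulse_ripple_effect > 0) {
    x <- x + patient_h1 * spec$pulse_ripple_effect *
      sin(2 * pi * 8 * tt + runif(1, 0, 2 * pi))
  }
  if (spec$drift_amplitude > 0) {
    x <- x + spec$drift_amplitude * sin(2 * pi * spec$drift_freq * tt +
                                        runif(1, 0, 2 * pi))
  }
  if (spec$pulse_noise_sd > 0) x <- x + rnorm(n, 0, spec$pulse_noise_sd)

  ## ground truth from the noiseless sampled signal, bracketed by known centres
  win <- function(lo, hi) {
    lo <- max(1L, round(lo / dt) + 1L); hi <- min(n, round(hi / dt) + 1L)
    if (lo > hi) integer(0) else lo:hi
  }
  truth <- list()
  for (i in seq_along(onsets)) {
    o <- onsets[i]; p <- periods[i]
    if (o + p + 0.2 > spec$duration_s || i == length(onsets)) next
    wpk <- win(o + sh$t1c - 0.08, o + sh$t1c + 0.08)
    pk <- wpk[which.max(clean[wpk])]
    won <- win(o - 0.3 * p, o + 0.05)
    on_ <- won[which.min(clean[won])]
    wtd <- win(o + t3c - 0.06, o + t3c + 0.08)
    td <- wtd[which.max(clean[wtd])]
    wnt <- win(o + t3c + 0.02, o + sh$t5c - 0.01)
    ntc <- wnt[which.min(clean[wnt])]
    wdc <- win(o + sh$t5c - 0.06, o + sh$t5c + 0.08)
    dc <- wdc[which.max(clean[wdc])]
    wnext <- win(o + p - 0.3 * p, o + p + 0.05)
    nxt <- wnext[which.min(clean[wnext])]
    base <- clean[on_]
    truth[[length(truth) + 1]] <- data.frame(
      cycle = i, onset_idx = on_, peak_idx = pk,
      h1 = clean[pk] - base, h3 = clean[td] - base,
      h3_over_h1 = (clean[td] - base) / (clean[pk] - base),
      t1 = (pk - on_) * dt, t = (nxt - on_) * dt,
      t4 = (ntc - on_) * dt, h4 = clean[ntc] - base, h5 = clean[dc] - base,
      bump_ratio = amps[i, 2])
  }
  list(recording = pulse_recording(x, dt), truth = do.call(rbind, truth))
}

## ---- clinical ---------------------------------------------------------

clinical_feature_names <- function(spec) {
  informative <- names(spec$clinical_effects)
  binary <- names(spec$binary_rates)
  n_noise <- spec$n_clinical - length(informative) - length(binary)
  c(informative, binary, sprintf("lab_%02d", seq_len(n_noise)))
}

#' Draw one synthetic clinical feature vector
#'
#' Informative columns are standard normal with a class-shifted mean (the
#' standardised effect from `spec$clinical_effects`); binary risk-factor
#' columns are Bernoulli with class-dependent rates; all remaining columns
#' are standard-normal noise.
#'
#' @inheritParams synth_tongue_image
#' @return named numeric vector of length `spec$n_clinical`.
#' @export
synth_clinical <- function(class, spec) {
  nm <- clinical_feature_names(spec)
  x <- rnorm(spec$n_clinical)
  names(x) <- nm
  for (f in names(spec$clinical_effects)) {
    if (class == 1) x[f] <- x[f] + spec$clinical_effects[[f]]
  }
  for (f in names(spec$binary_rates)) {
    x[f] <- as.numeric(runif(1) < spec$binary_rates[[f]][class + 1])
  }
  x
}

## ---- cohort -----------------------------------------------------------

## stratified split: within each class, allocate internal/external counts by
## rounding and give the remainder to train
assign_splits <- function(labels, frac) {
  split <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    nc <- length(idx)
    n_int <- max(if (nc >= 3) 1L else 0L, round(frac[["internal"]] * nc))
    n_ext <- max(if (nc >= 3) 1L else 0L, round(frac[["external"]] * nc))
    split[idx[seq_len(n_int)]] <- "internal"
    split[idx[n_int + seq_len(n_ext)]] <- "external"
    split[idx[(n_int + n_ext + 1):nc]] <- "train"
  }
  split
}

#' Generate a synthetic multimodal cohort on disk
#'
#' Writes tongue/face PNGs, pulse CSVs, the clinical table, ground-truth
#' tables and a manifest under `out_dir`. Identical spec + seed produce
#' bit-identical files.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if absent).
#' @return list with `manifest` (a validated `cohort_manifest`) and
#'   `ground_truth`: `$patients` (per-patient latent summaries),
#'   `$cycles` (per-cycle pulse landmarks), `$informative_clinical`.
#' @export
generate_cohort <- function(spec, out_dir) {
  assert_that(inherits(spec, "cohort_spec"), "not a cohort_spec")
  n <- spec$n_patients
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("tongue", "face", "pulse")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  set.seed(derive_seed(spec$seed, "cohort"))

  n1 <- round(n * spec$prevalence)
  assert_that(n1 >= 1 && n1 <= n - 1,
              "degenerate prevalence for this cohort size")
  labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  split <- assign_splits(labels, spec$split_frac)
  ids <- sprintf("P%04d", seq_len(n))

  clin <- matrix(0, n, spec$n_clinical,
                 dimnames = list(ids, clinical_feature_names(spec)))
  cycles <- list(); pats <- list()
  for (i in seq_len(n)) {
    write_image(synth_tongue_image(labels[i], spec),
                file.path(out_dir, "tongue", paste0(ids[i], ".png")))
    write_image(synth_face_image(labels[i], spec),
                file.path(out_dir, "face", paste0(ids[i], ".png")))
    sp <- synth_pulse(labels[i], spec)
    write_pulse_csv(sp$recording, file.path(out_dir, "pulse", paste0(ids[i], ".csv")))
    tr <- sp$truth; tr$patient_id <- ids[i]
    cycles[[i]] <- tr
    clin[i, ] <- synth_clinical(labels[i], spec)
    pats[[i]] <- data.frame(patient_id = ids[i], label = labels[i],
                            split = split[i],
                            mean_h1 = mean(tr$h1),
                            mean_h3_over_h1 = mean(tr$h3_over_h1))
  }
  clin_df <- data.frame(patient_id = ids, clin, check.names = FALSE)
  data.table::fwrite(clin_df, file.path(out_dir, "clinical.csv"))
  cycles <- do.call(rbind, cycles)
  pats <- do.call(rbind, pats)
  data.table::fwrite(cycles, file.path(out_dir, "ground_truth_cycles.csv"))
  data.table::fwrite(pats, file.path(out_dir, "ground_truth_patients.csv"))

  rec <- data.frame(patient_id = ids,
                    tongue_path = file.path("tongue", paste0(ids, ".png")),
                    face_path = file.path("face", paste0(ids, ".png")),
                    pulse_path = file.path("pulse", paste0(ids, ".csv")),
                    label = labels, split = split)
  data.table::fwrite(rec, file.path(out_dir, "manifest.csv"))
  manifest <- read_manifest(file.path(out_dir, "manifest.csv"))
  list(manifest = manifest,
       ground_truth = list(patients = pats, cycles = cycles,
                           informative_clinical = c(names(spec$clinical_effects),
                                                    names(spec$binary_rates))))
}
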