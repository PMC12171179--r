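make_periodic <- function(period = 0.8, duration = 30, dt = 1 / 50,
                          amp = 1, noise = 0) {
  tt <- seq(0, duration - dt, by = dt)
  onsets <- seq(0, duration, by = period)
  x <- numeric(length(tt))
  for (o in onsets) {
    x <- x + amp * exp(-(tt - o - 0.11)^2 / (2 * 0.04^2)) +
      0.5 * amp * exp(-(tt - o - 0.24)^2 / (2 * 0.055^2)) +
      0.25 * amp * exp(-(tt - o - 0.42)^2 / (2 * 0.045^2))
  }
  if (noise > 0) x <- x + rnorm(length(x), 0, noise)
  pulse_recording(x, dt)
}

test_that("preprocessing removes DC and slow drift but keeps the pulse band", {
  dt <- 1 / 50
  const <- pulse_recording(rep(3.5, 500), dt)
  out <- preprocess_pulse(const, smooth_window = 3, drift_cutoff = 0.5)
  expect_lt(max(abs(out$pressure)), 1e-6)
  expect_equal(length(out$pressure), 500)

  ## 0.1-Hz drift under a 0.5-Hz cutoff: residual drift < 5% of original
  rec <- make_periodic()
  tt <- seq_along(rec$pressure) * dt
  drift <- 2 * sin(2 * pi * 0.1 * tt)
  noisy <- pulse_recording(rec$pressure + drift, dt)
  cleaned <- preprocess_pulse(noisy, smooth_window = 1, drift_cutoff = 0.5)
  ## project the residual onto the drift sinusoid
  resid <- cleaned$pressure - (rec$pressure - mean(rec$pressure))
  amp_resid <- 2 * abs(mean(resid * sin(2 * pi * 0.1 * tt)))
  expect_lt(amp_resid / 2, 0.05)

  ## neutral settings are the identity
  ident <- preprocess_pulse(rec, smooth_window = 1, drift_cutoff = 0)
  expect_equal(ident$pressure, rec$pressure)
  expect_error(preprocess_pulse(const, smooth_window = 500), "window")
})

test_that("stable segment is exactly 6 s and ties break to the earliest onset", {
  rec <- make_periodic()
  seg <- extract_stable_segment(rec)
  expect_s3_class(seg, "pulse_segment")
  expect_equal(length(seg$pressure), 300)
  expect_equal(seg$duration, 6)
  ## perfectly periodic recording: all windows tie, earliest eligible wins
  expect_lte(seg$onset_index, round(0.8 / (1 / 50)) + 1)
  expect_error(extract_stable_segment(pulse_recording(sin(1:100), 1 / 50)),
               "shorter")
})

test_that("segment selection avoids an artifact burst (brute-force oracle)", {
  set.seed(4)
  rec <- make_periodic(noise = 0.01)
  x <- rec$pressure
  burst <- 400:560  # 3.2-s amplitude artifact: shorter than one window
  x[burst] <- x[burst] * 2.5
  rec2 <- pulse_recording(x, rec$sampling_interval)
  seg <- extract_stable_segment(rec2)
  ## independent exhaustive scan over all windows
  dt <- rec2$sampling_interval
  peaks <- pracma::findpeaks(x, minpeakdistance = round(0.4 / dt),
                             minpeakheight = unname(quantile(x, 0.75)))
  pk <- sort(peaks[, 2])
  best <- Inf; best_s <- NA
  for (s in seq_len(length(x) - 299)) {
    inw <- pk[pk >= s & pk <= s + 299]
    if (length(inw) < 2) next
    v <- var(x[inw])
    if (v < best - 1e-15) { best <- v; best_s <- s }
  }
  expect_equal(seg$onset_index, best_s)
  ## the selected window excludes the burst
  expect_true(seg$onset_index > max(burst) || seg$onset_index + 299 < min(burst))
})

test_that("cycle segmentation recovers the generated beats", {
  rec <- make_periodic(period = 0.8)
  seg <- extract_stable_segment(rec)
  cycles <- segment_cycles(seg)
  expect_true(length(cycles) %in% c(6, 7))  # floor(6 / 0.8) with edge trim
  expect_error(segment_cycles(pulse_recording(rep(1, 300), 1 / 50)),
               "extraction failed|peaks")
  ## onsets at true diastolic minima within 2 samples on noiseless input
  g <- test_cohort("noiseless")
  man <- g$manifest
  tr <- g$ground_truth$cycles
  pid <- man$records$patient_id[1]
  rec2 <- read_pulse_csv(file.path(man$root,
                                   man$records$pulse_path[
                                     man$records$patient_id == pid]))
  seg2 <- extract_stable_segment(preprocess_pulse(rec2, 1, 0))
  onsets <- vapply(segment_cycles(seg2), function(cc)
    cc$onset_index + seg2$onset_index - 1L, integer(1))
  truth_onsets <- tr$onset_idx[tr$patient_id == pid]
  matched <- vapply(onsets, function(o) min(abs(truth_onsets - o)), numeric(1))
  expect_lte(max(matched), 2)
})

test_that("main-wave widths match the analytic Gaussian crossings", {
  ## isolated Gaussian main wave, amplitude A, sd sigma, fine sampling
  A <- 2; sigma <- 0.05; dt <- 0.002
  tt <- seq(0, 0.8, by = dt)
  y <- A * exp(-(tt - 0.3)^2 / (2 * sigma^2))
  cyc <- structure(list(pressure = y, sampling_interval = dt, onset_index = 1L),
                   class = "pulse_cycle")
  f <- pulse_cycle_features(cyc)
  expect_equal(f$h1, A, tolerance = 1e-3)
  w1_true <- 2 * sigma * sqrt(2 * log(3 / 2))
  w2_true <- 2 * sigma * sqrt(2 * log(5 / 4))
  expect_equal(f$w1_over_t * f$t, w1_true, tolerance = 0.01)
  expect_equal(f$w2_over_t * f$t, w2_true, tolerance = 0.01)
  expect_true(f$w2_over_t <= f$w1_over_t)
})

test_that("fiducial parameters are recovered on noiseless synthetic cycles", {
  g <- test_cohort("noiseless")
  man <- g$manifest
  tr <- g$ground_truth$cycles
  errs <- list()
  for (pid in man$records$patient_id) {
    rec <- read_pulse_csv(file.path(man$root,
                                    man$records$pulse_path[
                                      man$records$patient_id == pid]))
    seg <- extract_stable_segment(preprocess_pulse(rec, 1, 0))
    for (cc in segment_cycles(seg)) {
      f <- pulse_cycle_features(cc)
      onset <- cc$onset_index + seg$onset_index - 1L
      i <- which(tr$patient_id == pid & tr$onset_idx == onset)
      if (!length(i)) next
      errs[[length(errs) + 1]] <- c(
        h1 = abs(f$h1 - tr$h1[i]) / tr$h1[i],
        r = abs(f$h3_over_h1 - tr$h3_over_h1[i]) / tr$h3_over_h1[i],
        t1t = abs(f$t1_over_t - tr$t1[i] / tr$t[i]) / (tr$t1[i] / tr$t[i]))
    }
  }
  e <- do.call(rbind, errs)
  expect_gt(nrow(e), 20)
  expect_lt(median(e[, "h1"]), 0.02)
  expect_lt(median(e[, "r"]), 0.02)
  expect_lt(median(e[, "t1t"]), 0.02)
})

test_that("cycle features satisfy the structural invariants", {
  set.seed(8)
  sp <- cohort_spec(n_patients = 4, pulse_noise_sd = 0.01)
  for (cl in 0:1) {
    sim <- synth_pulse(cl, sp)
    seg <- extract_stable_segment(preprocess_pulse(sim$recording))
    for (cc in segment_cycles(seg)) {
      f <- pulse_cycle_features(cc)
      expect_gt(f$h1, 0)
      if (!f$degenerate) {
        expect_true(0 < f$t1 && f$t1 < f$t4 && f$t4 < f$t)
        expect_lt(abs(f$t4 + f$t5 - f$t), cc$sampling_interval + 1e-9)
        expect_true(f$h3_over_h1 >= 0 && f$h3_over_h1 <= 1)
      }
      expect_lte(f$w2_over_t, f$w1_over_t + 1e-12)
    }
  }
})

test_that("a notchless cycle is flagged degenerate with missing ratios", {
  dt <- 1 / 50
  tt <- seq(0, 0.8 - dt, by = dt)
  y <- exp(-(tt - 0.2)^2 / (2 * 0.06^2))  # single bump, no notch, no dicrotic
  cyc <- structure(list(pressure = y, sampling_interval = dt, onset_index = 1L),
                   class = "pulse_cycle")
  f <- pulse_cycle_features(cyc)
  expect_true(f$degenerate)
  expect_true(is.na(f$h4) && is.na(f$t4_over_t5))
})

test_that("t4/t5 equals one for a symmetric notch position", {
  dt <- 0.01
  n <- 100
  y <- numeric(n)
  y[1:50] <- sin(seq(0, pi, length.out = 50))        # main wave
  y[50:100] <- 0.4 * sin(seq(0, pi, length.out = 51)) # dicrotic wave
  ## notch at exactly mid-cycle
  cyc <- structure(list(pressure = y, sampling_interval = dt, onset_index = 1L),
                   class = "pulse_cycle")
  f <- pulse_cycle_features(cyc)
  expect_equal(f$t4_over_t5, 1, tolerance = 0.05)
})

test_that("the per-patient feature table has the 15 canonical columns", {
  g <- test_cohort("noiseless")
  tab <- pulse_features_table(g$manifest, smooth_window = 1, drift_cutoff = 0)
  expect_equal(nrow(tab), nrow(g$manifest$records))
  expect_identical(names(tab), c("patient_id", cadfuse:::PULSE_FEATURE_NAMES))
  expect_equal(ncol(tab) - 1, 15)
  expect_false(anyNA(tab[, c("h1", "h3_over_h1", "t1_over_t")]))
})
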