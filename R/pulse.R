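## Radial pulse waveform processing.
##
## A recording is smoothed and detrended, a stable 6-s segment is selected,
## the segment is cut into single-beat cycles at diastolic minima, and each
## cycle yields the standard fiducial parameter set:
##   amplitudes h1 (percussion/main wave), h3 (tidal wave), h4 (dicrotic
##   notch), h5 (dicrotic wave); times t (cycle length), t1 (onset-to-peak),
##   t4 (onset-to-notch, systolic), t5 (notch-to-end, diastolic); widths
##   w1/w2 of the main wave at 2/3 and 4/5 of h1; and the derived ratios
##   h3/h1, h1/t1, h4/h1, t1/t, t4/t5, w1/t, w2/t.

#' Construct a pulse pressure recording
#'
#' @param pressure numeric pressure series (arbitrary units).
#' @param sampling_interval seconds between samples (default 1/50 s).
#' @return object of class `pulse_recording` with fields `pressure`,
#'   `sampling_interval` and `duration`.
#' @export
pulse_recording <- function(pressure, sampling_interval = 1 / 50) {
  assert_that(is.numeric(pressure) && length(pressure) > 1,
              "pressure must be a numeric series")
  assert_that(sampling_interval > 0, "sampling_interval must be positive")
  structure(list(pressure = as.numeric(pressure),
                 sampling_interval = sampling_interval,
                 duration = length(pressure) * sampling_interval),
            class = "pulse_recording")
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat(sprintf("Pulse recording: %.1f s at %.0f Hz (%d samples)\n",
              x$duration, 1 / x$sampling_interval, length(x$pressure)))
  invisible(x)
}

#' Smooth a pulse recording and remove baseline drift
#'
#' Applies a centred moving average of `smooth_window` samples (edges use the
#' available partial window), then removes slow baseline drift by
#' subtracting a low-frequency trend: the forward-backward-filtered output
#' of a 2nd-order Butterworth low-pass at `drift_cutoff` Hz. With
#' `smooth_window = 1` and `drift_cutoff = 0` the recording passes through
#' unchanged.
#'
#' @param recording a [pulse_recording()].
#' @param smooth_window moving-average width in samples (odd recommended).
#' @param drift_cutoff low-pass cutoff (Hz) defining the drift trend;
#'   `0` disables detrending.
#' @return a [pulse_recording()] of identical length.
#' @export
preprocess_pulse <- function(recording, smooth_window = 3, drift_cutoff = 0.5) {
  assert_that(inherits(recording, "pulse_recording"), "not a pulse_recording")
  x <- recording$pressure
  n <- length(x)
  assert_that(smooth_window >= 1 && smooth_window < n,
              "smoothing window must be shorter than the recording")
  if (smooth_window > 1) {
    k <- floor(smooth_window / 2)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - k, 1)
    hi <- pmin(seq_len(n) + k, n)
    x <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (drift_cutoff > 0) {
    fs <- 1 / recording$sampling_interval
    wn <- drift_cutoff / (fs / 2)
    assert_that(wn < 1, "drift cutoff above Nyquist")
    bf <- signal::butter(2, wn, type = "low")
    ## centre first: filtfilt's edge transients scale with the DC offset
    mu <- mean(x)
    trend <- mu + signal::filtfilt(bf, x - mu)
    x <- x - trend
  }
  pulse_recording(x, recording$sampling_interval)
}

## systolic peak indices of a series (minimum inter-peak distance in s);
## the height floor uses an upper quantile rather than the range so that a
## single amplitude artifact cannot mask the regular beats
find_systolic_peaks <- function(x, dt, min_distance_s = 0.4) {
  if (max(x) - min(x) < 1e-12) return(integer(0))
  pk <- pracma::findpeaks(x, minpeakdistance = max(1L, round(min_distance_s / dt)),
                          minpeakheight = unname(stats::quantile(x, 0.75)))
  if (is.null(pk)) return(integer(0))
  sort(pk[, 2])
}

#' Extract the most stable 6-s segment of a recording
#'
#' Scans every 6-s window (stride of one sample) and returns the one whose
#' systolic peak amplitudes have minimal variance -- a direct measure of
#' beat-to-beat stability. Ties are broken by the earliest onset. Windows
#' with fewer than two detected peaks are not eligible.
#'
#' @param recording a preprocessed [pulse_recording()] of duration >= 6 s.
#' @param segment_s segment duration in seconds (default 6).
#' @return object of class `pulse_segment`: fields `pressure`,
#'   `sampling_interval`, `duration`, `onset_index` (1-based index into the
#'   parent recording).
#' @export
extract_stable_segment <- function(recording, segment_s = 6) {
  assert_that(inherits(recording, "pulse_recording"), "not a pulse_recording")
  dt <- recording$sampling_interval
  L <- round(segment_s / dt)
  x <- recording$pressure
  n <- length(x)
  assert_that(n >= L, "recording shorter than the ", segment_s, "-s segment")
  peaks <- find_systolic_peaks(x, dt)
  assert_that(length(peaks) >= 2, "too few pulse peaks for segment selection")
  ph <- x[peaks]
  ## window score via peaks contained in [s, s+L-1]
  best_s <- NA_integer_; best <- Inf
  for (s in seq_len(n - L + 1)) {
    inw <- peaks >= s & peaks <= s + L - 1
    if (sum(inw) < 2) next
    v <- stats::var(ph[inw])
    if (v < best - 1e-15) { best <- v; best_s <- s }
  }
  assert_that(!is.na(best_s), "no eligible ", segment_s, "-s window found")
  structure(list(pressure = x[best_s:(best_s + L - 1)],
                 sampling_interval = dt, duration = L * dt,
                 onset_index = best_s),
            class = c("pulse_segment", "pulse_recording"))
}

#' Cut a segment into single-beat cycles
#'
#' Systolic peaks are detected with a minimum inter-peak distance of
#' `min_distance_s` (default 0.4 s, bounding heart rate at 150 bpm); cycle
#' onsets are the diastolic minima between successive peaks. Partial cycles
#' at the window edges are discarded.
#'
#' @param segment a `pulse_segment` (or any [pulse_recording()]).
#' @param min_distance_s minimum seconds between systolic peaks.
#' @return list of `pulse_cycle` objects, each with `pressure` (onset to
#'   next onset, inclusive start / exclusive end), `sampling_interval` and
#'   `onset_index` into the segment.
#' @export
segment_cycles <- function(segment, min_distance_s = 0.4) {
  x <- segment$pressure
  dt <- segment$sampling_interval
  peaks <- find_systolic_peaks(x, dt, min_distance_s)
  if (length(peaks) < 2) stop_cadfuse("cycle extraction failed: fewer than 2 pulse peaks")
  onsets <- vapply(seq_len(length(peaks) - 1), function(i) {
    span <- peaks[i]:peaks[i + 1]
    span[which.min(x[span])]
  }, integer(1))
  if (length(onsets) < 2) stop_cadfuse("cycle extraction failed: fewer than 2 onsets")
  lapply(seq_len(length(onsets) - 1), function(i) {
    structure(list(pressure = x[onsets[i]:(onsets[i + 1] - 1)],
                   sampling_interval = dt, onset_index = onsets[i]),
              class = "pulse_cycle")
  })
}

## local maxima / minima indices of a short series (interior points)
local_extrema <- function(y) {
  n <- length(y)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  i <- 2:(n - 1)
  list(max = i[y[i] > y[i - 1] & y[i] >= y[i + 1]],
       min = i[y[i] < y[i - 1] & y[i] <= y[i + 1]])
}

## width of the main wave at `frac * h1` above baseline: contiguous time the
## waveform stays above the threshold around the peak, with linearly
## interpolated crossings
wave_width <- function(y, peak_idx, baseline, h1, frac, dt) {
  thr <- baseline + frac * h1
  n <- length(y)
  i <- peak_idx
  while (i > 1 && y[i - 1] > thr) i <- i - 1
  left <- if (i == 1) 1 else i - (y[i] - thr) / (y[i] - y[i - 1])
  j <- peak_idx
  while (j < n && y[j + 1] > thr) j <- j + 1
  right <- if (j == n) n else j + (y[j] - thr) / (y[j] - y[j + 1])
  (right - left) * dt
}

#' Compute the fiducial parameter set of one pulse cycle
#'
#' Baseline is the cycle-onset value. The main (percussion) wave is the
#' cycle maximum (`h1` above baseline, at time `t1`); the dicrotic notch is
#' the deepest local minimum after the main peak (`h4`, at `t4`); the
#' dicrotic wave is the first local maximum after the notch (`h5`); the
#' tidal wave (`h3`) is the highest local maximum strictly between the main
#' peak and the notch or, if no such maximum exists, the point of steepest
#' negative curvature on the descending limb (flagged `degenerate`).
#' `t5 = t - t4`; widths `w1`/`w2` are the contiguous durations above
#' `2/3 * h1` and `4/5 * h1`.
#'
#' @param cycle a `pulse_cycle` from [segment_cycles()].
#' @return object of class `pulse_features`: named list of the 15 parameters
#'   `h1, h3, h4, h5, t, t1, t4, t5, h3_over_h1, h1_over_t1, h4_over_h1,
#'   t1_over_t, t4_over_t5, w1_over_t, w2_over_t` plus a `degenerate` flag.
#'   When no notch is found, notch-dependent values are `NA`.
#' @export
pulse_cycle_features <- function(cycle) {
  y <- cycle$pressure
  dt <- cycle$sampling_interval
  n <- length(y)
  assert_that(n >= 5, "cycle too short")
  baseline <- y[1]
  t <- n * dt
  p <- which.max(y)
  h1 <- y[p] - baseline
  assert_that(h1 > 0, "non-positive main wave amplitude")
  t1 <- (p - 1) * dt
  ex <- local_extrema(y)
  degenerate <- FALSE
  notch <- ex$min[ex$min > p]
  h3 <- h4 <- h5 <- t4 <- t5 <- NA_real_
  if (length(notch)) {
    nt <- notch[which.min(y[notch])]
    t4 <- (nt - 1) * dt
    t5 <- t - t4
    h4 <- y[nt] - baseline
    dic <- ex$max[ex$max > nt]
    if (length(dic)) h5 <- y[dic[1]] - baseline
    tidal <- ex$max[ex$max > p & ex$max < nt]
    if (length(tidal)) {
      h3 <- y[tidal[which.max(y[tidal])]] - baseline
    } else if (nt - p >= 3) {
      ## steepest negative curvature on the descending limb
      seg <- p:nt
      curv <- diff(y[seg], differences = 2)
      h3 <- y[seg[which.min(curv) + 1]] - baseline
      degenerate <- TRUE
    } else {
      h3 <- y[p] - baseline
      degenerate <- TRUE
    }
  } else {
    degenerate <- TRUE
  }
  w1 <- wave_width(y, p, baseline, h1, 2 / 3, dt)
  w2 <- wave_width(y, p, baseline, h1, 4 / 5, dt)
  structure(list(h1 = h1, h3 = h3, h4 = h4, h5 = h5, t = t, t1 = t1,
                 t4 = t4, t5 = t5,
                 h3_over_h1 = h3 / h1,
                 h1_over_t1 = if (t1 > 0) h1 / t1 else NA_real_,
                 h4_over_h1 = h4 / h1,
                 t1_over_t = t1 / t,
                 t4_over_t5 = t4 / t5,
                 w1_over_t = w1 / t,
                 w2_over_t = w2 / t,
                 degenerate = degenerate),
            class = "pulse_features")
}

PULSE_FEATURE_NAMES <- c("h1", "h3", "h4", "h5", "t", "t1", "t4", "t5",
                         "h3_over_h1", "h1_over_t1", "h4_over_h1",
                         "t1_over_t", "t4_over_t5", "w1_over_t", "w2_over_t")

#' Per-patient mean pulse feature table
#'
#' For every patient in the manifest: preprocess the recording, extract the
#' stable 6-s segment, cut it into cycles and average each of the 15
#' fiducial parameters over the non-degenerate handling of cycles
#' (`NA` notch values are dropped from the mean).
#'
#' @param manifest a `cohort_manifest`.
#' @param smooth_window,drift_cutoff passed to [preprocess_pulse()].
#' @return data.frame with `patient_id` and the 15 parameter columns in
#'   canonical order.
#' @export
pulse_features_table <- function(manifest, smooth_window = 3, drift_cutoff = 0.5) {
  assert_that(inherits(manifest, "cohort_manifest"), "not a cohort_manifest")
  rows <- lapply(seq_len(nrow(manifest$records)), function(i) {
    rec <- read_pulse_csv(file.path(manifest$root, manifest$records$pulse_path[i]))
    seg <- extract_stable_segment(preprocess_pulse(rec, smooth_window, drift_cutoff))
    feats <- lapply(segment_cycles(seg), pulse_cycle_features)
    m <- sapply(PULSE_FEATURE_NAMES, function(f)
      mean(vapply(feats, function(x) x[[f]], numeric(1)), na.rm = TRUE))
    c(list(patient_id = manifest$records$patient_id[i]), as.list(m))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
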