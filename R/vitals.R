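#' One timestamped vital-sign measurement
#'
#' The unit of telemetry: heart rate, saturation, body temperature, a
#' timestamp (seconds since epoch) and a subject identifier.
#'
#' @param heart_rate_bpm beats per minute, > 0.
#' @param spo2_percent percent, in [0, 100].
#' @param temperature_c degrees Celsius.
#' @param timestamp seconds since epoch.
#' @param subject_id identifier string.
#' @return An object of class \code{vital_record}.
#' @export
vital_record <- function(heart_rate_bpm, spo2_percent, temperature_c,
                         timestamp = 0, subject_id = "anon") {
  hr <- as.numeric(heart_rate_bpm)
  sp <- as.numeric(spo2_percent)
  if (!is.finite(hr) || hr <= 0)
    stop("heart_rate_bpm must be a positive number", call. = FALSE)
  if (!is.finite(sp) || sp < 0 || sp > 100)
    stop("spo2_percent must be in [0, 100]", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 timestamp = as.numeric(timestamp),
                 heart_rate_bpm = hr, spo2_percent = sp,
                 temperature_c = as.numeric(temperature_c)),
            class = "vital_record")
}

#' @export
print.vital_record <- function(x, ...) {
  cat(sprintf("<vital_record> subject=%s t=%g  HR=%.1f bpm  SpO2=%.1f%%  T=%.4f C\n",
              x$subject_id, x$timestamp, x$heart_rate_bpm, x$spo2_percent,
              x$temperature_c))
  invisible(x)
}

#' @export
#' @method all.equal vital_record
all.equal.vital_record <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

# centered moving average with reflection padding; w coerced to odd >= 1
moving_average <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= 2L * n - 1L) return(rep(mean(x), n))
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  cs <- cumsum(c(0, padded))
  (cs[(w + 1L):(w + n)] - cs[1L:n]) / w
}

# detrend a channel (subtract the slow baseline) and lightly smooth it; the
# same linear filtering on both channels cancels exactly in the ratio R
detrend_channel <- function(x, fs, min_hr_bpm = 30, smooth_s = 0.15) {
  w_base <- round(fs * 2 * 60 / min_hr_bpm)
  d <- x - moving_average(x, w_base)
  moving_average(d, round(fs * smooth_s))
}

#' A train of detected PPG peak times
#'
#' @param peak_times strictly increasing times in seconds, within
#'   [0, source_duration].
#' @param source_duration length of the analyzed window in seconds.
#' @param note optional flag, e.g. \code{"no pulsatile activity"}.
#' @return An object of class \code{peak_train}.
#' @export
peak_train <- function(peak_times, source_duration, note = NULL) {
  pt <- as.numeric(peak_times)
  if (length(pt) > 0) {
    if (any(pt < 0 | pt > source_duration))
      stop("peak times must lie within [0, source_duration]", call. = FALSE)
    if (is.unsorted(pt, strictly = TRUE))
      stop("peak times must be strictly increasing", call. = FALSE)
  }
  structure(list(peak_times = pt, source_duration = as.numeric(source_duration),
                 note = note),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d peaks over %.2f s%s\n", length(x$peak_times),
              x$source_duration,
              if (is.null(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

# topographic prominence of local maxima of s at indices idx
peak_prominence <- function(s, idx) {
  vapply(idx, function(i) {
    v <- s[i]
    j <- i
    lmin <- v
    while (j > 1L && s[j - 1L] <= v) {
      j <- j - 1L
      if (s[j] < lmin) lmin <- s[j]
    }
    j <- i
    rmin <- v
    n <- length(s)
    while (j < n && s[j + 1L] <= v) {
      j <- j + 1L
      if (s[j] < rmin) rmin <- s[j]
    }
    v - max(lmin, rmin)
  }, numeric(1))
}

#' Detect pulsatile peaks in one PPG channel
#'
#' Baseline-removes and lightly smooths the channel, finds local maxima with
#' topographic prominence at least 0.3 times the detrended signal's
#' peak-to-peak range, and enforces a minimum separation of
#' \code{60 / max_hr_bpm} seconds (taller peaks win). Peak times are refined
#' to sub-sample precision by parabolic interpolation.
#'
#' @param x numeric sample vector (one channel), at least 2 s long.
#' @param sampling_rate_hz sample rate in Hz.
#' @param min_hr_bpm,max_hr_bpm admissible heart-rate band; sets the baseline
#'   window (2 longest beats) and the minimum peak separation.
#' @return A \code{\link{peak_train}}. A flat (zero-variance) channel yields
#'   an empty train flagged \code{"no pulsatile activity"}.
#' @export
detect_peaks <- function(x, sampling_rate_hz, min_hr_bpm = 30, max_hr_bpm = 220) {
  stopifnot(is.numeric(x), sampling_rate_hz > 0)
  if (!(min_hr_bpm > 0 && min_hr_bpm < max_hr_bpm))
    stop("need 0 < min_hr_bpm < max_hr_bpm", call. = FALSE)
  n <- length(x)
  dur <- n / sampling_rate_hz
  if (dur < 2) stop("need at least 2 s of signal", call. = FALSE)
  if (stats::var(x) == 0)
    return(peak_train(numeric(0), dur, note = "no pulsatile activity"))
  s <- detrend_channel(x, sampling_rate_hz, min_hr_bpm)
  ptp <- max(s) - min(s)
  if (ptp == 0)
    return(peak_train(numeric(0), dur, note = "no pulsatile activity"))
  cand <- which(diff(sign(diff(s))) < 0) + 1L
  if (length(cand) == 0L) return(peak_train(numeric(0), dur))
  prom <- peak_prominence(s, cand)
  cand <- cand[prom >= 0.3 * ptp]
  if (length(cand) == 0L) return(peak_train(numeric(0), dur))
  min_gap <- 60 / max_hr_bpm * sampling_rate_hz
  keep <- logical(length(cand))
  for (o in order(s[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[o]) < min_gap)) keep[o] <- TRUE
  }
  idx <- sort(cand[keep])
  # parabolic refinement around each sample-grid maximum
  delta <- vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(0)
    den <- s[i - 1L] - 2 * s[i] + s[i + 1L]
    if (den == 0) return(0)
    max(-0.5, min(0.5, 0.5 * (s[i - 1L] - s[i + 1L]) / den))
  }, numeric(1))
  peak_train((idx - 1 + delta) / sampling_rate_hz, dur)
}

#' Heart rate from a peak train
#'
#' 60 divided by the median inter-peak interval. The median (not the mean)
#' keeps a single missed or spurious beat from dragging the estimate.
#'
#' @param peaks a \code{\link{peak_train}} with at least 2 peaks.
#' @return Heart rate in beats per minute.
#' @examples
#' heart_rate_from_peaks(peak_train(c(0, 1, 2, 3), 4))  # 60
#' @export
heart_rate_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_train"))
  if (length(peaks$peak_times) < 2L)
    stop("insufficient signal: need at least 2 peaks to estimate heart rate",
         call. = FALSE)
  60 / stats::median(diff(peaks$peak_times))
}

#' Classify a heart rate against the adult resting range
#'
#' Normal is 60 to 100 bpm inclusive on both ends.
#'
#' @param hr heart rate in bpm, > 0.
#' @return One of \code{"below_normal"}, \code{"normal"}, \code{"above_normal"}.
#' @export
classify_heart_rate <- function(hr) {
  stopifnot(is.numeric(hr), all(hr > 0))
  ifelse(hr < 60, "below_normal", ifelse(hr > 100, "above_normal", "normal"))
}

#' AC/DC decomposition of a dual-wavelength PPG window
#'
#' Per channel, DC is the window mean of the raw signal (the mean of the slow
#' baseline). AC is the pulsatile peak-to-trough amplitude, estimated by
#' matched projection: the baseline-removed IR channel is fitted with a
#' truncated Fourier series (first three harmonics of the beat frequency
#' found by peak detection), that fitted beat waveform serves as the shared
#' reference pulse shape, and each channel's AC is its least-squares
#' projection coefficient onto the reference times the reference's
#' peak-to-trough range. Projection over the whole window averages wideband
#' noise down instead of letting it inflate a per-beat range statistic, and
#' because both channels are projected onto the same shape, any shape
#' estimation error cancels exactly in the ratio R (for noiseless
#' proportional channels the ratio is exact to machine precision).
#'
#' @param ppg a \code{\link{dual_ppg}} at least 2 s long.
#' @param min_hr_bpm,max_hr_bpm admissible heart-rate band for beat detection.
#' @param n_harmonics harmonics of the beat frequency kept in the reference
#'   pulse shape.
#' @return An object of class \code{ppg_components} with fields
#'   \code{ac_red}, \code{dc_red}, \code{ac_ir}, \code{dc_ir}.
#' @export
extract_components <- function(ppg, min_hr_bpm = 30, max_hr_bpm = 220,
                               n_harmonics = 3L) {
  stopifnot(inherits(ppg, "dual_ppg"))
  fs <- ppg$sampling_rate_hz
  if (length(ppg$red) / fs < 2) stop("need at least 2 s of signal", call. = FALSE)
  dc_red <- mean(ppg$red)
  dc_ir <- mean(ppg$ir)
  if (dc_red <= 0 || dc_ir <= 0)
    stop("invalid signal: non-positive DC level", call. = FALSE)
  peaks <- detect_peaks(ppg$ir, fs, min_hr_bpm, max_hr_bpm)
  if (length(peaks$peak_times) < 2L) {
    # no beat structure (e.g. pure DC input): AC is zero by definition
    return(ppg_components(0, dc_red, 0, dc_ir))
  }
  f0 <- 1 / stats::median(diff(peaks$peak_times))
  n_harmonics <- min(n_harmonics, floor(fs / 2 / f0))
  t <- (seq_along(ppg$red) - 1) / fs
  w_base <- round(fs * 2 * 60 / min_hr_bpm)
  d_red <- ppg$red - moving_average(ppg$red, w_base)
  d_ir <- ppg$ir - moving_average(ppg$ir, w_base)
  harmonic_fit <- function(y, tt) {
    basis <- do.call(cbind, lapply(seq_len(n_harmonics), function(k)
      cbind(sin(2 * pi * k * f0 * tt), cos(2 * pi * k * f0 * tt))))
    drop(basis %*% stats::lm.fit(basis, y)$coefficients)
  }
  # red/IR amplitude ratio by projection over the whole window; any edge
  # distortion from the baseline filter has the same shape on both channels
  # and cancels here
  ref <- harmonic_fit(d_ir, t)
  ref_ss <- sum(ref^2)
  if (ref_ss == 0) return(ppg_components(0, dc_red, 0, dc_ir))
  # the IR coefficient is exactly 1: ref is the OLS projection of d_ir
  coef_red <- sum(d_red * ref) / ref_ss
  # per-channel peak-to-trough from the filter's edge-unaffected interior
  # (drop half a baseline window, at most a quarter of the record, per side)
  n <- length(t)
  h <- min(w_base %/% 2L, n %/% 4L)
  keep <- (h + 1L):(n - h)
  ac_ir <- diff(range(harmonic_fit(d_ir[keep], t[keep])))
  if (ac_ir == 0) return(ppg_components(0, dc_red, 0, dc_ir))
  ppg_components(max(coef_red * ac_ir, 0), dc_red, ac_ir, dc_ir)
}

#' @rdname extract_components
#' @param ac_red,dc_red,ac_ir,dc_ir component amplitudes (DC > 0, AC >= 0).
#' @export
ppg_components <- function(ac_red, dc_red, ac_ir, dc_ir) {
  if (dc_red <= 0 || dc_ir <= 0)
    stop("DC components must be positive", call. = FALSE)
  if (ac_red < 0 || ac_ir < 0)
    stop("AC components must be non-negative", call. = FALSE)
  structure(list(ac_red = as.numeric(ac_red), dc_red = as.numeric(dc_red),
                 ac_ir = as.numeric(ac_ir), dc_ir = as.numeric(dc_ir)),
            class = "ppg_components")
}

#' Ratio of ratios R from AC/DC components
#'
#' \eqn{R = (AC_{red}/DC_{red}) / (AC_{IR}/DC_{IR})}; the dimensionless input
#' to the SpO2 calibration line. Scale-free in each channel.
#'
#' @param comps a \code{\link{ppg_components}}.
#' @return The ratio R.
#' @export
compute_ratio <- function(comps) {
  stopifnot(inherits(comps, "ppg_components"))
  if (comps$ac_ir == 0)
    stop("undefined ratio: IR AC component is zero", call. = FALSE)
  (comps$ac_red / comps$dc_red) / (comps$ac_ir / comps$dc_ir)
}

#' Quantize a temperature to a sensor's resolution grid
#'
#' Nearest integer multiple of \code{resolution_c}; exact half-steps round
#' away from zero. The default grid models a 12-bit digital thermometer
#' (0.0625 degC steps).
#'
#' @param temp_c temperature(s) in degC.
#' @param resolution_c grid step in degC, > 0.
#' @return Quantized temperature(s), exact multiples of the resolution.
#' @examples
#' quantize_temperature(36.66)  # 36.6875
#' @export
quantize_temperature <- function(temp_c, resolution_c = 0.0625) {
  stopifnot(is.numeric(temp_c), resolution_c > 0)
  # round() ties-to-even would pull half-steps toward even multiples;
  # floor(|x|/res + 0.5) implements half-away-from-zero on the grid
  steps <- floor(round(abs(temp_c) / resolution_c, 9) + 0.5)
  sign(temp_c) * steps * resolution_c
}

#' Process one PPG window plus a temperature reading into a vital record
#'
#' Composes the whole patient-side chain: peak detection and heart rate on the
#' IR channel, AC/DC decomposition and ratio-of-ratios saturation via the
#' chosen calibration line, and temperature quantization. Stage failures are
#' re-raised tagged with the failing stage.
#'
#' @param ppg a \code{\link{dual_ppg}}.
#' @param temp_c raw temperature reading in degC.
#' @param cal calibration preset name or \code{calibration_line}.
#' @param subject_id,timestamp record identity fields.
#' @param resolution_c temperature quantization step.
#' @param min_hr_bpm,max_hr_bpm admissible heart-rate band.
#' @return A \code{\link{vital_record}}.
#' @export
process_window <- function(ppg, temp_c, cal = calibration(),
                           subject_id = "anon", timestamp = 0,
                           resolution_c = 0.0625,
                           min_hr_bpm = 30, max_hr_bpm = 220) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE))
  }
  hr <- stage("heart-rate", {
    peaks <- detect_peaks(ppg$ir, ppg$sampling_rate_hz, min_hr_bpm, max_hr_bpm)
    heart_rate_from_peaks(peaks)
  })
  spo2 <- stage("spo2", {
    comps <- extract_components(ppg, min_hr_bpm, max_hr_bpm)
    spo2_from_ratio(compute_ratio(comps), cal)
  })
  temp <- stage("temperature", quantize_temperature(temp_c, resolution_c))
  vital_record(hr, as.numeric(spo2), temp, timestamp, subject_id)
}
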