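#' Simulation parameters for a dual-wavelength PPG window
#'
#' Bundles and validates everything the waveform generator needs. The
#' pulsatile (AC) amplitudes of the two channels are derived from the target
#' saturation: the IR perfusion index is set directly and the red AC/DC ratio
#' is scaled by the ratio R obtained by inverting the chosen calibration line,
#' so that a perfect extraction recovers \code{spo2_percent} exactly.
#'
#' @param heart_rate_bpm pulse rate in beats per minute, in [30, 220].
#' @param spo2_percent target saturation in percent, in [70, 100]; must be
#'   attainable (R > 0) on the chosen calibration line.
#' @param cal calibration preset name or \code{calibration_line}.
#' @param dc_red,dc_ir baseline (DC) intensities per channel, > 0, arbitrary units.
#' @param perfusion_index_ir peak-to-trough AC/DC ratio of the IR channel,
#'   in (0, 0.2]. Healthy fingertip perfusion is typically a few percent.
#' @param noise_sd standard deviation of additive white Gaussian noise, in the
#'   same intensity units as the DC levels; >= 0.
#' @param sampling_rate_hz sample rate in Hz, >= 25.
#' @param duration_s window length in seconds, >= 2.
#' @param seed integer seed driving all randomness of one synthesis call.
#' @return A validated list of class \code{sim_params}.
#' @export
sim_params <- function(heart_rate_bpm = 75, spo2_percent = 97,
                       cal = calibration(), dc_red = 1, dc_ir = 1,
                       perfusion_index_ir = 0.05, noise_sd = 0,
                       sampling_rate_hz = 100, duration_s = 10, seed = 1L) {
  cal <- calibration(cal)
  stopifnot(is.numeric(heart_rate_bpm), length(heart_rate_bpm) == 1L,
            is.numeric(spo2_percent), length(spo2_percent) == 1L)
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220)
    stop("heart_rate_bpm must be in [30, 220]", call. = FALSE)
  if (spo2_percent < 70 || spo2_percent > 100)
    stop("spo2_percent must be in [70, 100]", call. = FALSE)
  if (dc_red <= 0 || dc_ir <= 0)
    stop("DC intensities must be positive", call. = FALSE)
  if (perfusion_index_ir <= 0 || perfusion_index_ir > 0.2)
    stop("perfusion_index_ir must be in (0, 0.2]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (sampling_rate_hz < 25)
    stop("sampling_rate_hz must be >= 25 Hz", call. = FALSE)
  if (duration_s < 2) stop("duration_s must be >= 2 s", call. = FALSE)
  # fails here if spo2 is unattainable on the line
  r <- ratio_for_spo2(spo2_percent, cal)
  if (r * perfusion_index_ir > 0.2)
    stop("implied red perfusion index exceeds 0.2; lower perfusion_index_ir",
         call. = FALSE)
  structure(list(heart_rate_bpm = heart_rate_bpm, spo2_percent = spo2_percent,
                 calibration = cal, dc_red = dc_red, dc_ir = dc_ir,
                 perfusion_index_ir = perfusion_index_ir, noise_sd = noise_sd,
                 sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Dual-wavelength PPG container
#'
#' Red and infrared intensity samples on a common time base. When produced by
#' \code{\link{synthesize_ppg}} the generating parameters travel along in
#' \code{truth}, so extraction accuracy can be scored against ground truth.
#'
#' @param red,ir numeric sample vectors of equal length >= 2, all finite.
#' @param sampling_rate_hz sample rate in Hz.
#' @param truth optional \code{sim_params}.
#' @return An object of class \code{dual_ppg}.
#' @export
dual_ppg <- function(red, ir, sampling_rate_hz, truth = NULL) {
  stopifnot(is.numeric(red), is.numeric(ir))
  if (length(red) != length(ir) || length(red) < 2L)
    stop("red and ir must have equal length >= 2", call. = FALSE)
  if (!all(is.finite(red)) || !all(is.finite(ir)))
    stop("all PPG samples must be finite", call. = FALSE)
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0", call. = FALSE)
  structure(list(red = as.numeric(red), ir = as.numeric(ir),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 truth = truth),
            class = "dual_ppg")
}

#' @export
print.dual_ppg <- function(x, ...) {
  cat(sprintf("<dual_ppg> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$red), x$sampling_rate_hz,
              length(x$red) / x$sampling_rate_hz,
              if (is.null(x$truth)) "" else "  [with ground truth]"))
  invisible(x)
}

# Normalized pulse shape: fundamental plus a 0.3-amplitude second harmonic at
# phase -pi/2, giving a single systolic peak and a small late-diastole bump
# (a stylized dicrotic wave). Zero mean by construction; scaled to unit
# peak-to-trough (max 1.3, min -43/60 before scaling).
pulse_waveform <- function(theta) {
  p <- sin(theta) - 0.3 * cos(2 * theta)
  p / (1.3 + 43 / 60)
}

#' Synthesize a dual-wavelength PPG window with known ground truth
#'
#' Each channel is \code{DC * (1 + pi_ch * p(t)) + noise}, where \code{p} is a
#' zero-mean, unit peak-to-trough pulse shape at the fundamental frequency
#' \code{heart_rate_bpm / 60} Hz and \code{pi_ch} is the channel's
#' peak-to-trough AC/DC ratio. The red perfusion index is
#' \code{R * perfusion_index_ir} with R from the inverted calibration line, so
#' the configured saturation is encoded exactly in the AC/DC ratios.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return A \code{\link{dual_ppg}} with \code{truth = params}.
#' @examples
#' ppg <- synthesize_ppg(sim_params(heart_rate_bpm = 60, duration_s = 10))
#' @export
synthesize_ppg <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- round(params$sampling_rate_hz * params$duration_s)
  t <- (seq_len(n) - 1) / params$sampling_rate_hz
  f <- params$heart_rate_bpm / 60
  p <- pulse_waveform(2 * pi * f * t)
  r <- ratio_for_spo2(params$spo2_percent, params$calibration)
  pi_ir <- params$perfusion_index_ir
  pi_red <- r * pi_ir
  red <- params$dc_red * (1 + pi_red * p)
  ir <- params$dc_ir * (1 + pi_ir * p)
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(params$seed, stats::rnorm(2L * n, 0, params$noise_sd))
    red <- red + noise[seq_len(n)]
    ir <- ir + noise[n + seq_len(n)]
  }
  dual_ppg(red, ir, params$sampling_rate_hz, truth = params)
}

#' Synthesize quantized body-temperature readings
#'
#' Models a digital thermometer with a datasheet accuracy bound and a fixed
#' conversion resolution (default values mirror a 12-bit sensor: +/-0.5 degC
#' accuracy, 0.0625 degC steps). Per-reading error is a truncated Gaussian
#' with SD = \code{accuracy_bound_c / 2}, truncated at the bound; the noisy
#' value is then snapped to the resolution grid.
#'
#' @param true_temp_c true temperature in degrees Celsius.
#' @param accuracy_bound_c absolute error bound in degC, >= 0.
#' @param resolution_c quantization step in degC, > 0.
#' @param n number of readings.
#' @param seed integer seed.
#' @return Numeric vector of \code{n} readings, each an exact multiple of
#'   \code{resolution_c}.
#' @export
synthesize_temperature <- function(true_temp_c, accuracy_bound_c = 0.5,
                                   resolution_c = 0.0625, n = 1L, seed = 1L) {
  stopifnot(resolution_c > 0, accuracy_bound_c >= 0, n >= 1)
  if (accuracy_bound_c == 0) {
    err <- numeric(n)
  } else {
    err <- withr::with_seed(seed, {
      out <- numeric(n)
      filled <- 0L
      while (filled < n) {
        draw <- stats::rnorm(2L * (n - filled), 0, accuracy_bound_c / 2)
        keep <- draw[abs(draw) <= accuracy_bound_c]
        take <- min(length(keep), n - filled)
        if (take > 0) {
          out[filled + seq_len(take)] <- keep[seq_len(take)]
          filled <- filled + take
        }
      }
      out
    })
  }
  quantize_temperature(true_temp_c + err, resolution_c)
}

#' Write / read a dual-wavelength PPG window as CSV
#'
#' Two columns (red, ir) preceded by a comment header line carrying the
#' sampling rate. Ground-truth parameters, if attached, can be written to a
#' sidecar \code{key = value} file alongside.
#'
#' @param ppg a \code{dual_ppg}.
#' @param path output CSV path.
#' @param truth_path optional path for the ground-truth sidecar.
#' @return \code{path}, invisibly.
#' @export
write_ppg_csv <- function(ppg, path, truth_path = NULL) {
  stopifnot(inherits(ppg, "dual_ppg"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", ppg$sampling_rate_hz), con)
  utils::write.csv(data.frame(red = ppg$red, ir = ppg$ir), con, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(ppg$truth)) {
    tr <- ppg$truth
    lines <- c(
      sprintf("heart_rate_bpm = %.10g", tr$heart_rate_bpm),
      sprintf("spo2_percent = %.10g", tr$spo2_percent),
      sprintf("calibration = %s", tr$calibration$name),
      sprintf("dc_red = %.10g", tr$dc_red),
      sprintf("dc_ir = %.10g", tr$dc_ir),
      sprintf("perfusion_index_ir = %.10g", tr$perfusion_index_ir),
      sprintf("noise_sd = %.10g", tr$noise_sd),
      sprintf("sampling_rate_hz = %.10g", tr$sampling_rate_hz),
      sprintf("duration_s = %.10g", tr$duration_s),
      sprintf("seed = %d", tr$seed))
    writeLines(lines, truth_path)
  }
  invisible(path)
}

#' @rdname write_ppg_csv
#' @param path input CSV path (for \code{read_ppg_csv}).
#' @export
read_ppg_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("sampling_rate_hz=([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L)
    stop("missing '# sampling_rate_hz=' header line in ", path, call. = FALSE)
  fs <- as.numeric(m[2])
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("red", "ir") %in% names(d)))
    stop("PPG CSV must have 'red' and 'ir' columns", call. = FALSE)
  dual_ppg(d$red, d$ir, fs)
}
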