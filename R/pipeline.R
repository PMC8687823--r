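#' Configuration for an end-to-end pipeline run
#'
#' Collects everything one patient-to-clinician round trip needs: the
#' simulated subject's true vitals, the sensor model, the calibration preset,
#' the key file, the send period and the output directory. All randomness of
#' the run flows from the single \code{seed}.
#'
#' @param hr_bpm,spo2_percent,temp_c true vitals for the simulated subject.
#' @param cal calibration preset name or \code{calibration_line}.
#' @param sampling_rate_hz PPG sample rate in Hz.
#' @param duration_s PPG window length in seconds.
#' @param noise_sd additive noise SD in intensity units (DC levels are 1).
#' @param send_period_s telemetry send period in seconds, > 0 (default 5).
#' @param key_file path to a key file (32 hex chars, one line).
#' @param seed integer master seed.
#' @param out_dir directory for artifacts (created if missing).
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(hr_bpm = 75, spo2_percent = 97, temp_c = 36.6,
                       cal = "maxim", sampling_rate_hz = 100,
                       duration_s = 10, noise_sd = 0, send_period_s = 5,
                       key_file, seed = 1L, out_dir = tempfile("vitalink_run_")) {
  if (!(send_period_s > 0)) stop("send_period_s must be > 0", call. = FALSE)
  if (missing(key_file) || is.null(key_file))
    stop("configuration error: key_file is required", call. = FALSE)
  structure(list(hr_bpm = hr_bpm, spo2_percent = spo2_percent, temp_c = temp_c,
                 cal = cal, sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s, noise_sd = noise_sd,
                 send_period_s = send_period_s, key_file = key_file,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full patient-to-clinician pipeline once
#'
#' Simulate a dual-wavelength PPG window and a temperature reading, extract a
#' vital record, encrypt it, pass it through the in-process ciphertext store,
#' decrypt it on the consumer side, and score the delivered record against
#' the simulation ground truth. Every intermediate artifact (waveform CSV,
#' truth sidecar, record JSON, Base64 payload, delivered record JSON) and a
#' stage-tagged log are written to \code{config$out_dir}. Timestamps in the
#' log are virtual (seconds on the telemetry clock), so runs are byte-for-
#' byte reproducible from the seed.
#'
#' @param config a \code{\link{run_config}} (or path to a YAML config file).
#' @return Invisibly, a list with \code{record} (extracted),
#'   \code{delivered} (after the secure round trip), \code{truth},
#'   \code{hr_error_bpm}, \code{spo2_error_pp}, \code{artifacts} (named file
#'   paths) and \code{log} (character lines).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$key_file))
    stop("configuration error: key file not found: ", config$key_file,
         call. = FALSE)
  key <- read_key_file(config$key_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  clock <- 0
  say <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[t=%06.1fs] [%s] %s", clock, stage, msg))
  }
  art <- function(name) file.path(config$out_dir, name)
  fail <- function(stage, e) {
    say(stage, paste("FAILED:", conditionMessage(e)))
    writeLines(log_lines, art("run.log"))
    stop(sprintf("[%s stage] %s", stage, conditionMessage(e)), call. = FALSE)
  }

  say("config", sprintf("seed=%d cal=%s fs=%gHz duration=%gs noise_sd=%g",
                        config$seed, calibration(config$cal)$name,
                        config$sampling_rate_hz, config$duration_s,
                        config$noise_sd))
  ppg <- tryCatch({
    params <- sim_params(heart_rate_bpm = config$hr_bpm,
                         spo2_percent = config$spo2_percent,
                         cal = config$cal, noise_sd = config$noise_sd,
                         sampling_rate_hz = config$sampling_rate_hz,
                         duration_s = config$duration_s, seed = config$seed)
    synthesize_ppg(params)
  }, error = function(e) fail("simulate", e))
  write_ppg_csv(ppg, art("ppg.csv"), art("truth.txt"))
  say("simulate", sprintf("synthesized %d samples (HR=%g bpm, SpO2=%g%%)",
                          length(ppg$red), config$hr_bpm, config$spo2_percent))

  record <- tryCatch({
    temp_read <- synthesize_temperature(config$temp_c, n = 1L,
                                        seed = config$seed + 1L)
    process_window(ppg, temp_read, config$cal, subject_id = "sim-subject",
                   timestamp = 0)
  }, error = function(e) fail("extract", e))
  jsonlite::write_json(unclass(record)[c("subject_id", "timestamp",
                                         "heart_rate_bpm", "spo2_percent",
                                         "temperature_c")],
                       art("record.json"), auto_unbox = TRUE, digits = NA)
  say("extract", sprintf("HR=%.2f bpm SpO2=%.2f%% T=%.4fC",
                         record$heart_rate_bpm, record$spo2_percent,
                         record$temperature_c))

  trip <- tryCatch(
    telemetry_roundtrip(list(record), key, period_s = config$send_period_s,
                        seed = config$seed + 2L),
    error = function(e) fail("securelink", e))
  clock <- clock + config$send_period_s
  enc <- trip$store$get(1)
  writeLines(enc$ciphertext_b64, art("payload.b64"))
  say("securelink", sprintf("encrypted+stored+decrypted 1 record under key '%s' (iv %s...)",
                            key$key_id, substr(raw_to_hex(enc$iv), 1, 8)))
  if (length(trip$failed) > 0) fail("securelink", simpleError("delivery failed"))
  delivered <- trip$delivered[[1]]
  jsonlite::write_json(unclass(delivered)[c("subject_id", "timestamp",
                                            "heart_rate_bpm", "spo2_percent",
                                            "temperature_c")],
                       art("delivered.json"), auto_unbox = TRUE, digits = NA)

  hr_err <- delivered$heart_rate_bpm - config$hr_bpm
  spo2_err <- delivered$spo2_percent - config$spo2_percent
  say("validate", sprintf("HR error %+.3f bpm, SpO2 error %+.3f pp vs truth",
                          hr_err, spo2_err))
  writeLines(log_lines, art("run.log"))

  invisible(list(record = record, delivered = delivered, truth = ppg$truth,
                 hr_error_bpm = hr_err, spo2_error_pp = spo2_err,
                 artifacts = c(ppg = art("ppg.csv"), truth = art("truth.txt"),
                               record = art("record.json"),
                               payload = art("payload.b64"),
                               delivered = art("delivered.json"),
                               log = art("run.log")),
                 log = log_lines))
}
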