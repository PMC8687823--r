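test_that("detect_peaks finds sinusoid maxima at the right spacing", {
  fs <- 100
  t <- (0:799) / fs
  x <- sin(2 * pi * 1.25 * t)  # peaks every 0.8 s over 8 s
  pk <- detect_peaks(x, fs)
  expect_length(pk$peak_times, 10)
  gaps <- diff(pk$peak_times)
  expect_true(all(abs(gaps - 0.8) <= 0.01))
})

test_that("flat input yields an empty, flagged peak train", {
  pk <- detect_peaks(rep(5, 400), 100)
  expect_length(pk$peak_times, 0)
  expect_equal(pk$note, "no pulsatile activity")
  expect_error(detect_peaks(sin(1:50), 100), "2 s")
})

test_that("detected beat period matches simulator truth within one sample", {
  ppg <- synthesize_ppg(sim_params(heart_rate_bpm = 90, noise_sd = 0))
  pk <- detect_peaks(ppg$ir, ppg$sampling_rate_hz)
  expect_true(abs(median(diff(pk$peak_times)) - 60 / 90) <= 1 / 100)
})

test_that("heart rate is 60 over the median inter-peak interval", {
  expect_equal(heart_rate_from_peaks(peak_train(c(0, 1, 2, 3), 4)), 60)
  expect_equal(heart_rate_from_peaks(peak_train(c(0, 0.5, 1.0), 2)), 120)
  # a missed beat (one doubled interval) must not drag the estimate
  pk <- peak_train(c(0, 0.8, 1.6, 3.6), 4)
  expect_equal(heart_rate_from_peaks(pk), 75)
  expect_error(heart_rate_from_peaks(peak_train(c(1), 4)), "insufficient")
  # exactness for uniform trains across the admissible band
  for (p in c(0.35, 0.5, 0.8, 1.2, 1.9)) {
    pk <- peak_train(seq(0, 10, by = p), 10.1)
    expect_equal(heart_rate_from_peaks(pk), 60 / p)
  }
})

test_that("heart-rate categories use an inclusive 60-100 normal band", {
  expect_equal(classify_heart_rate(75), "normal")
  expect_equal(classify_heart_rate(59.9), "below_normal")
  expect_equal(classify_heart_rate(60), "normal")
  expect_equal(classify_heart_rate(100), "normal")
  expect_equal(classify_heart_rate(100.1), "above_normal")
})

test_that("components recover offset and amplitude of a known sinusoid", {
  t <- (0:999) / 100
  x <- 2 + 0.5 * sin(2 * pi * t)
  comps <- extract_components(dual_ppg(x, x, 100))
  expect_equal(comps$dc_red, 2.0, tolerance = 1e-3)
  expect_equal(comps$ac_red, 1.0, tolerance = 1e-2)  # peak-to-trough
  expect_equal(compute_ratio(comps), 1.0, tolerance = 1e-6)
})

test_that("a pure DC window has zero AC and an undefined ratio", {
  x <- rep(3, 400)
  comps <- extract_components(dual_ppg(x, x, 100))
  expect_equal(comps$ac_red, 0)
  expect_equal(comps$ac_ir, 0)
  expect_error(compute_ratio(comps), "undefined ratio")
})

test_that("noiseless components match the configured AC/DC ratios", {
  r_true <- ratio_for_spo2(97, "maxim")
  ppg <- synthesize_ppg(sim_params(heart_rate_bpm = 60, spo2_percent = 97,
                                   cal = "maxim", noise_sd = 0))
  comps <- extract_components(ppg)
  expect_equal(comps$ac_ir / comps$dc_ir, 0.05, tolerance = 5e-3)
  expect_equal(comps$ac_red / comps$dc_red, r_true * 0.05, tolerance = 5e-3)
  expect_equal(compute_ratio(comps), r_true, tolerance = 1e-6)
})

test_that("compute_ratio is the double ratio and is channel-scale-free", {
  c1 <- ppg_components(0.02, 1, 0.05, 1)
  expect_equal(compute_ratio(c1), 0.4)
  expect_equal(compute_ratio(ppg_components(0.03, 2, 0.03, 2)), 1.0)
  c2 <- ppg_components(0.2, 10, 0.05, 1)
  expect_equal(compute_ratio(c2), compute_ratio(c1))
})

test_that("temperature quantization snaps to the grid, ties away from zero", {
  expect_equal(quantize_temperature(36.6875), 36.6875)  # already on grid
  expect_equal(quantize_temperature(36.66), 36.6875)
  expect_equal(quantize_temperature(0.03125), 0.0625)   # tie, away from zero
  expect_equal(quantize_temperature(-0.03125), -0.0625)
  # always an exact multiple of the resolution, for any input
  x <- seq(-5, 45, by = 0.013)
  q <- quantize_temperature(x)
  expect_true(all(abs(q / 0.0625 - round(q / 0.0625)) < 1e-9))
  expect_true(all(abs(q - x) <= 0.03125 + 1e-9))
  # brute-force nearest-grid-point check on a coarse grid
  for (v in c(36.66, 33.1, 40.02)) {
    grid <- seq(30, 45, by = 0.0625)
    expect_equal(quantize_temperature(v), grid[which.min(abs(grid - v))])
  }
})

test_that("process_window composes the full chain near ground truth", {
  ppg <- synthesize_ppg(sim_params(heart_rate_bpm = 75, spo2_percent = 97,
                                   noise_sd = 0))
  rec <- process_window(ppg, 36.66, "maxim", subject_id = "p1", timestamp = 42)
  expect_s3_class(rec, "vital_record")
  expect_true(abs(rec$heart_rate_bpm - 75) <= 2)
  expect_true(abs(rec$spo2_percent - 97) <= 1)
  expect_equal(rec$temperature_c, 36.6875)
  expect_equal(rec$subject_id, "p1")
})

test_that("process_window tags the failing stage", {
  flat <- dual_ppg(rep(1, 500), rep(1, 500), 100)
  expect_error(process_window(flat, 36.6), "heart-rate stage")
})

test_that("time-shifting a periodic noiseless window leaves estimates alone", {
  p <- sim_params(heart_rate_bpm = 60, spo2_percent = 95, noise_sd = 0,
                  duration_s = 12)
  ppg <- synthesize_ppg(p)
  fs <- ppg$sampling_rate_hz
  # shift by 37 samples; keep whole-beat-aligned 10 s from each version
  n <- 10 * fs
  w1 <- dual_ppg(ppg$red[1:n], ppg$ir[1:n], fs)
  w2 <- dual_ppg(ppg$red[37 + (1:n)], ppg$ir[37 + (1:n)], fs)
  hr1 <- heart_rate_from_peaks(detect_peaks(w1$ir, fs))
  hr2 <- heart_rate_from_peaks(detect_peaks(w2$ir, fs))
  expect_equal(hr1, hr2, tolerance = 1e-3)
  s1 <- as.numeric(spo2_from_ratio(compute_ratio(extract_components(w1)), "maxim"))
  s2 <- as.numeric(spo2_from_ratio(compute_ratio(extract_components(w2)), "maxim"))
  expect_equal(s1, s2, tolerance = 0.1)
})
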