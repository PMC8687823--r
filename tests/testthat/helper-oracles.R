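# Independent brute-force evaluation of all agreement statistics, written
# with explicit per-element loops so it shares no code path with the package.
oracle_stats <- function(mes, ref) {
  K <- length(mes)
  ss <- 0; sa <- 0; sr <- 0
  for (i in seq_len(K)) {
    d <- ref[i] - mes[i]
    ss <- ss + d * d
    sa <- sa + abs(d)
    sr <- sr + abs(d) / ref[i]
  }
  mx <- 0; my <- 0
  for (i in seq_len(K)) { mx <- mx + mes[i]; my <- my + ref[i] }
  mx <- mx / K; my <- my / K
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(K)) {
    sxx <- sxx + (mes[i] - mx)^2
    syy <- syy + (ref[i] - my)^2
    sxy <- sxy + (mes[i] - mx) * (ref[i] - my)
  }
  d <- numeric(K)
  for (i in seq_len(K)) d[i] <- mes[i] - ref[i]
  md <- 0
  for (i in seq_len(K)) md <- md + d[i]
  md <- md / K
  sd2 <- 0
  for (i in seq_len(K)) sd2 <- sd2 + (d[i] - md)^2
  sdd <- sqrt(sd2 / (K - 1))
  up <- md + 1.96 * sdd
  lo <- md - 1.96 * sdd
  n_out <- 0
  for (i in seq_len(K)) if (d[i] > up || d[i] < lo) n_out <- n_out + 1
  list(rmse = sqrt(ss / K), mae = sa / K, mre = sr / K,
       slope = sxy / sxx, intercept = my - (sxy / sxx) * mx,
       r_squared = (sxy * sxy) / (sxx * syy),
       mean_diff = md, sd_diff = sdd, loa_lower = lo, loa_upper = up,
       n_outside_loa = n_out)
}

# random small paired table with positive references
random_pairs <- function(K) {
  ref <- stats::runif(K, 10, 200)
  mes <- ref + stats::rnorm(K, 0, 3)
  paired_readings(mes, ref, "random")
}

# NIST SP 800-38A known-answer material, AES-128
nist_key <- "2b7e151628aed2a6abf7158809cf4f3c"
nist_pt_blocks <- c(
  "6bc1bee22e409f96e93d7e117393172a",
  "ae2d8a571e03ac9c9eb76fac45af8e51",
  "30c81c46a35ce411e5fbc1191a0a52ef",
  "f69f2445df4f9b17ad2b417be66c3710")
nist_ecb_ct_blocks <- c(
  "3ad77bb40d7a3660a89ecaf32466ef97",
  "f5d3d58503b9699de785895a96fdbaaf",
  "43b1cd7f598ece23881b00e3ed030688",
  "7b0c785e27e8ad3f8223207104725dd4")
nist_cbc_iv <- "000102030405060708090a0b0c0d0e0f"
nist_cbc_ct <- paste0(
  "7649abac8119b246cee98e9b12e9197d",
  "5086cb9b507219ee95db113a917678b2",
  "73bed6b8e3c1743b7116e69e22229516",
  "3ff1caa1681fac09120eca307586e1a7")

# FIPS-197 appendix C.1 single-block example
fips_key <- "000102030405060708090a0b0c0d0e0f"
fips_pt <- "00112233445566778899aabbccddeeff"
fips_ct <- "69c4e0d86a7b0430d8cdb78070b4c55a"

random_record <- function() {
  vital_record(heart_rate_bpm = sample(40:180, 1),
               spo2_percent = sample(70:100, 1),
               temperature_c = quantize_temperature(stats::runif(1, 33, 40)),
               timestamp = sample.int(1e6, 1),
               subject_id = paste0("s", sample.int(999, 1)))
}

# recovery-study grid shared by the round-trip tests: 100 (HR, SpO2)
# combinations spanning the band a fingertip monitor must cover
recovery_grid <- function() {
  expand.grid(hr = round(seq(50, 180, length.out = 10)),
              sp = round(seq(85, 100, length.out = 10)))
}

recover_vitals <- function(hr, sp, noise_sd, seed, duration_s = 30) {
  p <- sim_params(heart_rate_bpm = hr, spo2_percent = sp, cal = "maxim",
                  noise_sd = noise_sd, duration_s = duration_s, seed = seed)
  ppg <- synthesize_ppg(p)
  hr_hat <- tryCatch(
    heart_rate_from_peaks(detect_peaks(ppg$ir, ppg$sampling_rate_hz)),
    error = function(e) NA_real_)
  sp_hat <- tryCatch(
    as.numeric(spo2_from_ratio(compute_ratio(extract_components(ppg)), "maxim")),
    error = function(e) NA_real_)
  c(hr = hr_hat, spo2 = sp_hat)
}
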