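# vitalink

Desk-scale computational core of a compact IoT vital-sign monitor: synthesis
and analysis of dual-wavelength photoplethysmography (PPG), secure record
encoding, and full method-comparison validation — for engineers and
researchers who need the signal chain of a pulse-oximeter + thermometer
telemetry device without the hardware.

## What it computes

**Oxygen saturation.** A pulse oximeter shines red (~660 nm) and infrared
(~880 nm) light through tissue. Each channel splits into a steady baseline
(DC, from bone and tissue reflectance) and a pulsatile component (AC, from
arterial blood volume). The dimensionless ratio of ratios

    R = (AC/DC)_red / (AC/DC)_IR

maps to saturation through an empirical calibration line
`SpO2% = intercept − slope·R`. Two presets ship: `classic` (110 − 25R, the
common literature approximation) and `maxim` (104 − 17R, the line published
by Maxim Integrated for their sensor family, the package default).

**Heart rate.** 60 divided by the median interval between consecutive PPG
peaks, in beats per minute; the normal adult resting band is 60–100 bpm.

**Temperature.** Readings snap to a 12-bit digital-thermometer grid
(0.0625 °C steps) with a ±0.5 °C accuracy bound.

**Secure payloads.** Vital records serialize canonically and are encrypted
with AES-128 in CBC mode (PKCS#7 padding, fresh random IV per message),
Base64-encoded, and passed through an in-process ciphertext store emulating
the cloud leg. The cipher core is implemented in the package and is
validated byte-exactly against published known-answer vectors (FIPS-197,
NIST SP 800-38A).

**Device agreement.** For paired measured/reference tables: RMSE, MAE, mean
relative error (fraction and percent), per-reading error %, ordinary
least-squares fit against the perfect-match line `y = x` with R² (squared
Pearson correlation), and Bland–Altman 95 % limits of agreement
`mean(d) ± 1.96·SD(d)`. Three validation tables are packaged: 50 heart-rate
pairs, 50 SpO₂ pairs and 40 body-temperature pairs from a field comparison
against commercial reference devices.

## Worked example

```r
library(vitalink)

# simulate a 10 s dual-wavelength window with known truth, extract a record
params <- sim_params(heart_rate_bpm = 80, spo2_percent = 95,
                     duration_s = 10, seed = 2L)
ppg <- synthesize_ppg(params)
rec <- process_window(ppg, temp_c = 36.66)
rec
#> <vital_record> subject=anon t=0  HR=80.0 bpm  SpO2=95.0%  T=36.6875 C

# secure round trip: encrypt -> store -> decrypt
key <- secret_key("2b7e151628aed2a6abf7158809cf4f3c", "node-1")
trip <- telemetry_roundtrip(list(rec), key, period_s = 5, seed = 1L)
trip$delivered[[1]]
#> <vital_record> subject=anon t=0  HR=80.0 bpm  SpO2=95.0%  T=36.6875 C

# validate the packaged heart-rate table
agreement_report(load_fixture("hr"))
#> Agreement report: heart_rate (K = 50)
#>   RMSE   1.44   MAE   1.12   MRE 0.012 (1.21%)   R^2 0.992
#>   fit: reference = 1.004 * measured -0.635
#>   Bland-Altman: mean diff 0.2400, SD 1.4365 (sample), LoA [-2.5756, 3.0556], 0 outside
```

The heart-rate estimate comes back at the simulated truth (80 bpm), the
saturation at 95 %, and the temperature reading lands on the 0.0625 °C
sensor grid (36.66 → 36.6875). On the packaged heart-rate table the device
errs by 1.12 bpm on average (1.44 bpm RMS, 1.2 % relative), correlates with
the reference at R² = 0.992 near the identity line, and every difference
lies inside the 95 % limits of agreement.

A thin command-line front end over the same functions lives at
`inst/cli/vitalink.R` (subcommands `simulate`, `extract`, `encrypt`,
`decrypt`, `validate`, `pipeline`).

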