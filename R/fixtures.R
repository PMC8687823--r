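# Packaged validation tables: paired device-vs-reference readings collected
# in a field comparison of the monitored vitals against commercial
# instruments (a heart-rate monitor, a fingertip pulse oximeter, and a
# medical thermometer). 50 heart-rate pairs, 50 SpO2 pairs, 40 temperature
# pairs; each row also carries the comparison's printed per-reading Error (%)
# column so recomputed errors can be checked against it.

.fixture_spec <- list(
  hr   = list(file = "table_hr.csv",   rows = 50L, parameter = "heart_rate",
              md5 = "9dd2e19a584409f97ed5b42675e94046"),
  spo2 = list(file = "table_spo2.csv", rows = 50L, parameter = "spo2",
              md5 = "cda468612a518dcf09047b69dac2bf3c"),
  temp = list(file = "table_temp.csv", rows = 40L, parameter = "temperature",
              md5 = "f6d348626fa5f55d08ab5ec686d8f3f9"))

#' Load a packaged device-validation table
#'
#' Returns one of the three paired measured/reference tables shipped with the
#' package (\code{"hr"}: 50 heart-rate pairs in bpm, \code{"spo2"}: 50
#' saturation pairs in percent, \code{"temp"}: 40 body-temperature pairs in
#' degC). The file's MD5 checksum and row count are verified at load; the
#' table's printed per-reading error column is attached as the
#' \code{printed_error_percent} attribute.
#'
#' @param name \code{"hr"}, \code{"spo2"} or \code{"temp"}.
#' @return A \code{\link{paired_readings}} object.
#' @examples
#' p <- load_fixture("hr")
#' p$pairs[1, ]  # measured 88, reference 88
#' @export
load_fixture <- function(name = c("hr", "spo2", "temp")) {
  name <- match.arg(name)
  spec <- .fixture_spec[[name]]
  path <- system.file("extdata", spec$file, package = "vitalink", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != spec$md5)
    stop("corrupted fixture: checksum mismatch for ", spec$file, call. = FALSE)
  d <- utils::read.csv(path)
  if (nrow(d) != spec$rows)
    stop(sprintf("corrupted fixture: expected %d rows in %s, found %d",
                 spec$rows, spec$file, nrow(d)), call. = FALSE)
  if (!all(c("reading_no", "measured", "reference", "error_percent") %in% names(d)))
    stop("corrupted fixture: missing columns in ", spec$file, call. = FALSE)
  p <- paired_readings(d$measured, d$reference, spec$parameter)
  attr(p, "printed_error_percent") <- d$error_percent
  p
}
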